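#' Pearson criterion and distribution type
#'
#' The Pearson system selects a density family from the first four moments
#' through the criterion
#' \deqn{\kappa = \frac{\beta_1 (\beta_2 + 3)^2}
#'   {4 (4\beta_2 - 3\beta_1)(2\beta_2 - 3\beta_1 - 6)}}
#' with \eqn{\beta_1} the squared skewness and \eqn{\beta_2} the (non-excess)
#' kurtosis. Negative kappa selects Type I (a bounded, beta-like density);
#' kappa = 0 gives the normal (beta2 = 3), Type II (beta2 < 3) or Type VII
#' (beta2 > 3); 0 < kappa < 1 Type IV; kappa = 1 Type V; kappa > 1 Type VI;
#' a vanishing denominator the Type III (gamma) boundary.
#'
#' @param skewness,kurtosis moment shape values; must satisfy
#'   `kurtosis > 1 + skewness^2`.
#' @return list with `kappa` and `type` (one of `"I"`, `"II"`, `"III"`,
#'   `"IV"`, `"V"`, `"VI"`, `"VII"`, `"normal"`).
#' @examples
#' pearson_criterion(-0.3, 3.0)  # kappa ~ -0.256, Type I
#' @export
pearson_criterion <- function(skewness, kurtosis) {
  b1 <- skewness^2; b2 <- kurtosis
  if (!is.finite(b1) || !is.finite(b2) || b2 <= 1 + b1)
    stop("infeasible moments: kurtosis must exceed 1 + skewness^2")
  den2 <- 2 * b2 - 3 * b1 - 6
  tol <- 1e-10
  if (b1 <= tol) {
    type <- if (abs(b2 - 3) <= tol) "normal" else if (b2 < 3) "II"
      else "VII"
    return(list(kappa = 0, type = type))
  }
  if (abs(den2) < tol)
    return(list(kappa = Inf, type = "III"))
  kappa <- b1 * (b2 + 3)^2 / (4 * (4 * b2 - 3 * b1) * den2)
  type <-
    if (kappa < -tol) "I"
    else if (kappa < 1 - tol) "IV"
    else if (abs(kappa - 1) <= tol) "V"
    else "VI"
  list(kappa = kappa, type = type)
}

#' Specify a Pearson-system distribution by its first four moments
#'
#' @param mean,sd location and scale (sd > 0).
#' @param skewness,kurtosis shape; `kurtosis` is non-excess (normal = 3) and
#'   must exceed `1 + skewness^2`.
#' @return list of class `pearson_spec` with the moments, `beta1`, `beta2`,
#'   `kappa` and the distribution `type` label.
#' @export
pearson_spec <- function(mean = 0, sd = 1, skewness = -0.3, kurtosis = 3.0) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive")
  cr <- pearson_criterion(skewness, kurtosis)
  structure(list(mean = mean, sd = sd, skewness = skewness,
                 kurtosis = kurtosis, beta1 = skewness^2, beta2 = kurtosis,
                 kappa = cr$kappa, type = cr$type),
            class = "pearson_spec")
}

#' @export
print.pearson_spec <- function(x, ...) {
  cat(sprintf(
    "<pearson_spec> Type %s (kappa = %.4g): mean %.4g, sd %.4g, skew %.4g, kurt %.4g\n",
    x$type, x$kappa, x$mean, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

# Quadratic coefficients of the standardized Pearson ODE
#   d log p / dy = -(c1 + y) / (c0 + c1 y + c2 y^2)
.pearson_coefs <- function(b1, b2, skew_sign) {
  D <- 10 * b2 - 12 * b1 - 18
  list(c0 = (4 * b2 - 3 * b1) / D,
       c1 = skew_sign * sqrt(b1) * (b2 + 3) / D,
       c2 = (2 * b2 - 3 * b1 - 6) / D)
}

# Type I / II: moment-matched four-parameter beta. Returns list(a1, a2,
# alpha, beta) so that y = a1 + (a2 - a1) * Beta(alpha, beta) has mean 0,
# sd 1 and the requested skewness/kurtosis.
.pearson_beta_params <- function(skewness, kurtosis) {
  b1 <- skewness^2; b2 <- kurtosis
  if (b1 <= 1e-12) {
    # symmetric beta: excess kurtosis of Beta(a, a) is -6 / (2a + 3)
    if (b2 >= 3) stop("not a Type I/II configuration")
    a <- (6 / (3 - b2) - 3) / 2
    if (a <= 0) stop("not a Type I/II configuration")
    half <- sqrt(4 * (2 * a + 1)) / 2      # scale for unit variance
    return(list(a1 = -half, a2 = half, alpha = a, beta = a))
  }
  # unnormalized Pearson quadratic; its roots do not depend on the common
  # denominator D, which can vanish inside the Type I region
  D <- 10 * b2 - 12 * b1 - 18
  C0 <- 4 * b2 - 3 * b1
  C1 <- sign(skewness) * sqrt(b1) * (b2 + 3)
  C2 <- 2 * b2 - 3 * b1 - 6
  disc <- C1^2 - 4 * C0 * C2
  if (disc <= 0 || abs(C2) < 1e-14) stop("not a Type I/II configuration")
  r <- sort(c((-C1 - sqrt(disc)) / (2 * C2), (-C1 + sqrt(disc)) / (2 * C2)))
  a1 <- r[1L]; a2 <- r[2L]
  m1 <- (C1 + D * a1) / (C2 * (a2 - a1))
  m2 <- -(C1 + D * a2) / (C2 * (a2 - a1))
  if (m1 <= -1 || m2 <= -1) stop("not a Type I/II configuration")
  list(a1 = a1, a2 = a2, alpha = m1 + 1, beta = m2 + 1)
}

# Generic fallback: numeric inversion of the Pearson density for types
# without a closed-form sampler (IV, V, VI). Builds the density from the
# Pearson ODE on an adaptive grid, integrates, and inverts the CDF.
.pearson_numeric_sampler <- function(n, b1, b2, skew_sign) {
  co <- .pearson_coefs(b1, b2, skew_sign)
  quad <- function(y) co$c0 + co$c1 * y + co$c2 * y^2
  mode <- -co$c1                     # d log p = 0
  # expand support symmetrically-ish around the mode until density decays
  lo <- mode; hi <- mode
  step <- 0.5
  logp_at <- function(grid) {
    # integrate -(c1 + y)/quad(y) from mode along the grid (trapezoid)
    dv <- -(co$c1 + grid) / quad(grid)
    c(0, cumsum(diff(grid) * (head(dv, -1) + dv[-1]) / 2))
  }
  ok <- function(y) { q <- quad(y); is.finite(q) && q > 1e-12 }
  for (it in 1:200) {
    cand <- lo - step
    if (ok(cand)) {
      g <- seq(mode, cand, length.out = 65L)
      if (rev(logp_at(g))[1L] > -40) lo <- cand else break
    } else break
    step <- step * 1.4
  }
  step <- 0.5
  for (it in 1:200) {
    cand <- hi + step
    if (ok(cand)) {
      g <- seq(mode, cand, length.out = 65L)
      if (rev(logp_at(g))[1L] > -40) hi <- cand else break
    } else break
    step <- step * 1.4
  }
  # linear resolution over the unit-scale core, log-spaced points into the
  # (possibly power-law) tails so heavy-tailed members stay resolved
  core_lo <- max(lo, mode - 12); core_hi <- min(hi, mode + 12)
  grid <- seq(core_lo, core_hi, length.out = 8193L)
  logtail <- function(from, to, n) {
    d <- abs(to - from)
    if (d < 1e-9) return(numeric(0))
    eps <- 0.01
    from + sign(to - from) * (exp(seq(log(eps), log(d + eps),
                                      length.out = n)) - eps)
  }
  grid <- sort(unique(c(logtail(core_lo, lo, 3000L), grid,
                        logtail(core_hi, hi, 3000L))))
  grid <- grid[quad(grid) > 1e-12]
  lp <- logp_at(grid)
  p <- exp(lp - max(lp))
  cdf <- c(0, cumsum(diff(grid) * (head(p, -1) + p[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  u <- stats::runif(n)
  y <- stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
  # the numeric density matches shape; re-standardize to mean 0, sd 1
  (y - mean(y)) / stats::sd(y)
}

#' Sample from a Pearson-system distribution
#'
#' Draws pseudo-random numbers whose population distribution is the Pearson
#' member matching all four moments of `spec`. Type I/II are realized as a
#' moment-matched four-parameter beta; the normal case uses `rnorm`, Type
#' III a standardized gamma, Type VII a rescaled Student t; Types IV, V and
#' VI fall back to numeric inversion of the Pearson density. Deterministic
#' for a fixed seed.
#'
#' @param n number of draws (> 0).
#' @param spec a [pearson_spec()].
#' @param seed optional integer seed (uses the current RNG state when `NULL`).
#' @return numeric vector of length `n`.
#' @export
sample_pearson <- function(n, spec = pearson_spec(), seed = NULL) {
  stopifnot(inherits(spec, "pearson_spec"))
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- switch(spec$type,
    "normal" = stats::rnorm(n),
    "I" = , "II" = {
      bp <- .pearson_beta_params(spec$skewness, spec$kurtosis)
      bp$a1 + (bp$a2 - bp$a1) * stats::rbeta(n, bp$alpha, bp$beta)
    },
    "III" = {
      shape <- 4 / spec$beta1
      sign(spec$skewness) * (stats::rgamma(n, shape = shape, rate = 1) -
                               shape) / sqrt(shape)
    },
    "VII" = {
      nu <- 4 + 6 / (spec$beta2 - 3)
      stats::rt(n, df = nu) * sqrt((nu - 2) / nu)
    },
    .pearson_numeric_sampler(n, spec$beta1, spec$beta2,
                             sign(spec$skewness)))
  spec$mean + spec$sd * y
}
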