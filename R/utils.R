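#' Sample moments of a height sample
#'
#' Mean, standard deviation, skewness (m3 / m2^1.5) and non-excess kurtosis
#' (m4 / m2^2) with population (1/n) central moments, the convention used
#' for surface height distributions.
#'
#' @param x numeric vector or matrix.
#' @return named list `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
sample_moments <- function(x) {
  x <- as.vector(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  list(mean = mu, sd = sqrt(m2),
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2)
}

# ---- zero-truncated normal with matched moments ----------------------------

# CV of a normal truncated below at 0, as a function of a = mu/sigma of the
# parent. Monotone decreasing in a; sup over a is 1 (exponential tail limit).
.tnorm_cv <- function(a) {
  lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  m <- a + lam
  v <- 1 - lam * (lam + a)
  sqrt(pmax(v, 0)) / m
}

.tnorm_cache <- new.env(parent = emptyenv())

# Parent (mu, sigma) such that the zero-truncated normal has mean m and,
# where attainable, sd s. The truncated CV is bounded above by 1, so target
# CVs at or beyond cv_cap are capped (mean still matched exactly).
.tnorm_solve <- function(m, s, cv_cap = 0.95) {
  if (m <= 0) stop("infeasible truncation: target mean must be positive")
  key <- paste0(format(m, digits = 15), "_", format(s, digits = 15))
  hit <- .tnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  cv <- min(s / m, cv_cap)
  a <- stats::uniroot(function(a) .tnorm_cv(a) - cv, c(-30, 30),
                      tol = 1e-12)$root
  lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  sigma <- m / (a + lam)
  out <- list(mu = a * sigma, sigma = sigma, capped = (s / m) > cv_cap)
  .tnorm_cache[[key]] <- out
  out
}

#' Draw from a normal distribution truncated at zero, matched to target
#' moments
#'
#' The parent parameters are solved so the truncated distribution has
#' exactly the requested mean and (where attainable) standard deviation;
#' a zero-truncated normal cannot exceed CV = 1, so higher targets are
#' capped near that bound with the mean still matched exactly. Sampling is
#' by inverse-CDF, so a fixed RNG state gives a deterministic draw.
#'
#' @param n number of draws.
#' @param mean,sd target moments of the truncated distribution (mean > 0).
#' @return numeric vector of non-negative draws.
#' @export
rtnorm_matched <- function(n, mean, sd) {
  par <- .tnorm_solve(mean, sd)
  plo <- stats::pnorm(0, par$mu, par$sigma)
  u <- plo + (1 - plo) * stats::runif(n)
  stats::qnorm(u, par$mu, par$sigma)
}
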