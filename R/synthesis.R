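#' Synthesis target for a reverse-engineered surface
#'
#' Bundles the targeted areal parameters and generator settings for
#' [synthesize_surface()]. Targets are in the units of the fabrication
#' tables: `s_a`, `s_v` in mm, `s_mr` in percent. Distribution shape
#' defaults to the values retained for the reverse-engineered surfaces
#' (skewness -0.3, kurtosis 3.0).
#'
#' @param s_a,s_v,s_mr targeted arithmetic mean height (mm), maximum pit
#'   depth (mm) and areal material ratio at the mean plane (%).
#' @param skewness,kurtosis marginal shape of the height distribution.
#' @param rows,cols grid size; `step_mm` lateral spacing (mm).
#' @param corr_mm Gaussian correlation length of the low-pass filter (mm);
#'   controls the lateral hill/dale scale.
#' @param pitch_mm pitch of the micro-patterned depression grid (mm).
#' @param depression_depth_mm flat-bottom depression depth (mm); default
#'   0.25 * `s_v`.
#' @param tail_q quantile bounding the lower-tail region to which the pit
#'   depth constant `h` is applied (default 0.01; keeping the stretched
#'   mass small leaves Sa and Smr nearly untouched by the Sv calibration).
#' @param tolerance relative tolerance on each achieved parameter (default
#'   0.05).
#' @param max_iter calibration iteration cap (default 50).
#' @param seed integer seed; replicate k of a series conventionally uses
#'   `seed + k`.
#' @return list of class `synthesis_target`.
#' @export
synthesis_target <- function(s_a, s_v, s_mr, skewness = -0.3,
                             kurtosis = 3.0, rows = 128L, cols = 128L,
                             step_mm = 0.4, corr_mm = 2.5, pitch_mm = 2,
                             depression_depth_mm = 0.25 * s_v,
                             tail_q = 0.01,
                             tolerance = 0.05, max_iter = 50L, seed = 1L) {
  if (any(c(s_a, s_v, s_mr) <= 0)) stop("targets must be positive")
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(s_a = s_a, s_v = s_v, s_mr = s_mr, skewness = skewness,
                 kurtosis = kurtosis, rows = as.integer(rows),
                 cols = as.integer(cols), step_mm = step_mm,
                 corr_mm = corr_mm, pitch_mm = pitch_mm,
                 depression_depth_mm = depression_depth_mm,
                 tail_q = tail_q,
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "synthesis_target")
}

#' Spatially correlated Pearson random field
#'
#' The raw generator stage: pseudo-random heights are drawn from the
#' Pearson-system member matching the requested skewness and kurtosis,
#' spatial correlation is imposed by Gaussian low-pass filtering (FFT,
#' periodic), and the marginal distribution is restored exactly by rank
#' re-mapping the filtered field onto the sorted draws. The sorted heights
#' of the result are therefore identical to the sorted draws, so all four
#' sample moments survive the filtering unchanged.
#'
#' @param rows,cols grid size (>= 8 each).
#' @param step lateral spacing, um.
#' @param corr_length Gaussian kernel sigma, um.
#' @param skewness,kurtosis marginal shape (defaults -0.3, 3.0).
#' @param seed integer seed.
#' @return a zero-mean [heightmap] (unit-variance heights, um-scaled later
#'   by the calibration stage), marked preprocessed.
#' @export
pearson_surface_field <- function(rows, cols, step = 100,
                                  corr_length = 2500, skewness = -0.3,
                                  kurtosis = 3.0, seed = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 8L || cols < 8L) stop("grid must be at least 8x8")
  spec <- pearson_spec(0, 1, skewness, kurtosis)
  draws <- sample_pearson(rows * cols, spec, seed = seed)
  g <- matrix(draws, rows, cols)
  fy <- c(0:floor((rows - 1) / 2), -(ceiling((rows - 1) / 2):1)) /
    (rows * step)
  fx <- c(0:floor((cols - 1) / 2), -(ceiling((cols - 1) / 2):1)) /
    (cols * step)
  H <- exp(-2 * pi^2 * corr_length^2 *
             (matrix(fy^2, rows, cols) +
                matrix(fx^2, rows, cols, byrow = TRUE)))
  sm <- Re(stats::fft(stats::fft(g) * H, inverse = TRUE)) / (rows * cols)
  out <- numeric(rows * cols)
  out[order(as.vector(sm))] <- sort(draws)
  z <- matrix(out, rows, cols)
  z <- z - mean(z)
  hm <- heightmap(z, step, step,
                  origin_note = sprintf(
                    "pearson field type %s, corr %g um, seed %s", spec$type,
                    corr_length, if (is.null(seed)) "-" else seed))
  hm$preprocessed <- TRUE
  hm
}

#' Apply a micro-patterned depression grid
#'
#' Cuts flat-bottomed square depressions arranged on a regular pitch into
#' the surface, covering `area_fraction` of the evaluation area. Depressing
#' above-mean material lowers the areal material ratio monotonically, which
#' is the knob the synthesis loop uses to reach a targeted Smr. Block sizes
#' are mixed deterministically between the two integer sizes bracketing the
#' requested fraction so coverage is continuous in `area_fraction`.
#'
#' @param hm a [heightmap].
#' @param pitch depression grid pitch, um (>= 2 samples).
#' @param depth depression depth, um.
#' @param area_fraction fraction of the area depressed, in \[0, 1\].
#' @return a [heightmap]; `area_fraction = 0` returns the input unchanged.
#' @export
apply_depressions <- function(hm, pitch, depth, area_fraction) {
  stopifnot(inherits(hm, "heightmap"))
  if (area_fraction < 0 || area_fraction > 1)
    stop("area_fraction must be in [0, 1]")
  if (area_fraction == 0) return(hm)
  nr <- nrow(hm$z); nc <- ncol(hm$z)
  cpp <- round(pitch / min(hm$step_x, hm$step_y))
  if (cpp < 2) stop("pitch smaller than 2 samples")
  cpp <- as.integer(min(cpp, min(nr, nc)))
  s_real <- sqrt(area_fraction) * cpp
  k <- floor(s_real)
  frac_hi <- if (k >= cpp) 1 else
    (area_fraction - (k / cpp)^2) / (((k + 1) / cpp)^2 - (k / cpp)^2)
  nbr <- ceiling(nr / cpp); nbc <- ceiling(nc / cpp)
  nblocks <- nbr * nbc
  # deterministic scramble of block order (no RNG involved)
  bi <- rep(seq_len(nbr), times = nbc); bj <- rep(seq_len(nbc), each = nbr)
  ordblk <- order((bi * 7919L + bj * 104729L) %% 65521L, bi, bj)
  hi_blocks <- logical(nblocks)
  hi_blocks[ordblk[seq_len(round(frac_hi * nblocks))]] <- TRUE
  mask <- matrix(FALSE, nr, nc)
  for (b in seq_len(nblocks)) {
    side <- if (hi_blocks[b]) k + 1L else k
    if (side <= 0L) next
    r0 <- (bi[b] - 1L) * cpp + 1L; c0 <- (bj[b] - 1L) * cpp + 1L
    off <- (cpp - side) %/% 2L
    rr <- (r0 + off):min(r0 + off + side - 1L, nr)
    cc <- (c0 + off):min(c0 + off + side - 1L, nc)
    if (rr[1L] <= nr && cc[1L] <= nc) mask[rr, cc] <- TRUE
  }
  hm$z <- hm$z - depth * mask
  hm
}

# re-level a matrix to zero mean (plane removal is not redone; the
# synthesis field is already mean-plane-free)
.relevel0 <- function(hm) { hm$z <- hm$z - mean(hm$z); hm }

#' Synthesize a pseudo-random surface with targeted Sa, Sv and Smr
#'
#' The full reverse-engineering pipeline: (1) a Pearson-system height field
#' with the targeted skewness/kurtosis and imposed spatial correlation
#' ([pearson_surface_field()]); (2) amplitude calibration: the field is
#' scaled to the targeted Sa by setting its standard deviation, and the
#' maximum pit depth is steered to the targeted Sv by applying a constant
#' `h` to the lower height tail (below the 5% quantile), since Sv/Sa of a
#' fixed marginal cannot be set independently by pure scaling; (3)
#' micro-patterned depressions whose area fraction is solved by bisection
#' to reach the targeted Smr; (4) the achieved parameters are re-measured
#' on the final surface with the areal-parameter functions (never cached
#' from the generator) and steps 2-3 iterate with multiplicative correction
#' until every parameter is within `target$tolerance` or `max_iter` is hit.
#'
#' @param target a [synthesis_target()].
#' @return list with `heightmap` (heights in um), `report` (a
#'   [validate_surface()] data.frame in target units), `spec` (the
#'   [pearson_spec()] used), `achieved` (list, mm / %), `converged`,
#'   `iterations`, `depression_fraction`. Non-convergence returns
#'   `converged = FALSE` with the best surface, never a silent success.
#'   Different seeds give different surfaces with self-similar parameter
#'   values.
#' @export
synthesize_surface <- function(target) {
  stopifnot(inherits(target, "synthesis_target"))
  step_um <- target$step_mm * 1000
  sa_t <- target$s_a * 1000; sv_t <- target$s_v * 1000   # um
  smr_t <- target$s_mr
  depth_um <- target$depression_depth_mm * 1000
  pitch_um <- target$pitch_mm * 1000
  field <- pearson_surface_field(target$rows, target$cols, step = step_um,
                                 corr_length = target$corr_mm * 1000,
                                 skewness = target$skewness,
                                 kurtosis = target$kurtosis,
                                 seed = target$seed)
  base <- field$z
  adj_sa <- sa_t; adj_sv <- sv_t
  best <- NULL; best_err <- Inf
  converged <- FALSE; iter <- 0L; f_used <- 0
  make_surface <- function(adj_sa, adj_sv, f) {
    g <- base * (adj_sa / mean(abs(base)))
    qc <- stats::quantile(g, target$tail_q, names = FALSE)
    gmin <- min(g)
    if (-adj_sv < qc && gmin < qc) {
      h <- (-adj_sv - qc) / (gmin - qc)
      low <- g < qc
      g[low] <- qc + h * (g[low] - qc)
      g <- g - mean(g)
    }
    hm <- field; hm$z <- g
    if (f > 0)
      hm <- .relevel0(apply_depressions(hm, pitch_um, depth_um, f))
    hm
  }
  solve_fraction <- function(adj_sa, adj_sv) {
    smr0 <- smr(make_surface(adj_sa, adj_sv, 0))
    if (smr_t > smr0 + 1)
      stop(sprintf(
        "infeasible S_mr target %.1f%%: undepressed surface has %.1f%% and depressions can only lower it",
        smr_t, smr0))
    if (smr_t >= smr0) return(0)
    # the response can be non-monotone when the depression depth is
    # comparable to the surface spread, so scan a coarse grid first and
    # refine around the best point
    fg <- seq(0, 0.95, by = 0.05)
    err <- vapply(fg, function(f)
      abs(smr(make_surface(adj_sa, adj_sv, f)) - smr_t), numeric(1))
    k <- which.min(err)
    lo <- fg[max(1L, k - 1L)]; hi <- fg[min(length(fg), k + 1L)]
    for (it in 1:12) {
      mids <- lo + (hi - lo) * c(1, 2) / 3
      e <- vapply(mids, function(f)
        abs(smr(make_surface(adj_sa, adj_sv, f)) - smr_t), numeric(1))
      if (e[1L] < e[2L]) hi <- mids[2L] else lo <- mids[1L]
    }
    (lo + hi) / 2
  }
  measure <- function(adj_sa, adj_sv, f) {
    hm <- make_surface(adj_sa, adj_sv, f)
    hp <- height_params(hm)
    ach <- list(S_a = hp$S_a / 1000, S_v = hp$S_v / 1000, S_mr = smr(hm))
    err <- c(abs(ach$S_a - target$s_a) / target$s_a,
             abs(ach$S_v - target$s_v) / target$s_v,
             abs(ach$S_mr - target$s_mr) / target$s_mr)
    list(hm = hm, ach = ach, err = err, f = f,
         adj_sa = adj_sa, adj_sv = adj_sv)
  }
  n_fp <- min(target$max_iter, 10L)
  for (iter in seq_len(n_fp)) {
    f <- solve_fraction(adj_sa, adj_sv)
    m <- measure(adj_sa, adj_sv, f)
    if (max(m$err) < best_err) { best <- m; best_err <- max(m$err) }
    if (all(m$err <= target$tolerance)) { converged <- TRUE; break }
    adj_sa <- adj_sa * target$s_a / m$ach$S_a
    adj_sv <- adj_sv * target$s_v / m$ach$S_v
  }
  if (!converged && iter < target$max_iter) {
    # the Sa/Smr pair can deadlock when the depression pattern both carries
    # amplitude and competes with the base-field blur; refine base
    # amplitude, tail depth and depression fraction jointly
    evals <- 0L
    obj <- function(par) {
      evals <<- evals + 1L
      m <- measure(exp(par[1L]), exp(par[2L]), stats::plogis(par[3L]))
      if (max(m$err) < best_err) { best <<- m; best_err <<- max(m$err) }
      max(m$err)
    }
    suppressWarnings(stats::optim(
      c(log(best$adj_sa), log(best$adj_sv),
        stats::qlogis(min(max(best$f, 1e-3), 0.99))),
      obj, method = "Nelder-Mead",
      control = list(maxit = 40L * (target$max_iter - iter),
                     abstol = target$tolerance * 0.5)))
    iter <- iter + evals %/% 40L
    converged <- best_err <= target$tolerance
  }
  if (!converged)
    warning(sprintf(
      "synthesis did not converge in %d iterations (worst relative error %.3f)",
      iter, best_err))
  report <- validate_surface(
    c(S_a = best$ach$S_a, S_v = best$ach$S_v, S_mr = best$ach$S_mr),
    target)
  list(heightmap = best$hm, report = report,
       spec = pearson_spec(0, 1, target$skewness, target$kurtosis),
       achieved = best$ach, converged = converged, iterations = iter,
       depression_fraction = best$f)
}

#' Targeted-versus-achieved validation report
#'
#' Per-parameter percent error, `100 * |achieved - targeted| / targeted`,
#' the figure of merit used when checking fabricated or modeled surfaces
#' against their design targets.
#'
#' @param achieved named numeric vector or list of achieved values (any
#'   subset of `S_a`, `S_v`, `S_mr`, in the target's units).
#' @param target a [synthesis_target()], or a named vector/list of targeted
#'   values with the same names as `achieved`.
#' @return data.frame with `parameter`, `targeted`, `actual`,
#'   `percent_error`. A zero targeted value yields `NA` with a warning.
#' @examples
#' validate_surface(c(S_a = 2.8), synthesis_target(2.1, 8.4, 52))
#' @export
validate_surface <- function(achieved, target) {
  ach <- unlist(achieved)
  if (inherits(target, "synthesis_target"))
    tgt <- c(S_a = target$s_a, S_v = target$s_v, S_mr = target$s_mr)
  else tgt <- unlist(target)
  common <- intersect(names(ach), names(tgt))
  if (!length(common)) stop("no overlapping parameter names")
  t <- tgt[common]; a <- ach[common]
  pe <- ifelse(t == 0, NA_real_, 100 * abs(a - t) / abs(t))
  if (anyNA(pe)) warning("zero targeted value: percent error undefined")
  data.frame(parameter = common, targeted = unname(t), actual = unname(a),
             percent_error = unname(pe), row.names = NULL)
}
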