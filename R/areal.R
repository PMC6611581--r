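#' @name areal-parameters
#' @title Areal surface texture parameters
#' @description
#' The parameter families of ISO 25178-2 computed on a leveled height map:
#' height parameters (Sq, Ssk, Sku, Sp, Sv, Sz, Sa), functional parameters
#' on the areal material ratio curve (Smr, Smc, Sxp), spatial parameters
#' from the areal autocorrelation (Sal, Str, Std), functional volume
#' parameters (Vm, Vv, Vmp, Vmc, Vvc, Vvv), stratified parameters
#' (Sk, Spk, Svk, Smr1, Smr2) and, via the feature-segmentation module,
#' feature parameters (S10z, S5v, S5p). Heights are um; areas use the cell
#' area step_x * step_y.
NULL

.check_pre <- function(hm) {
  stopifnot(inherits(hm, "heightmap"))
  if (!all(hm$valid_mask))
    stop("height map has invalid points; run preprocess() first")
  invisible(hm)
}

#' Height parameters of a leveled surface
#'
#' Sa is the arithmetic mean of |z| over the evaluation area (the discrete
#' mean of absolute heights), Sq the RMS height, Ssk/Sku the standardized
#' third and fourth moments, Sp the maximum peak height, Sv the maximum pit
#' depth (absolute value of the lowest point), Sz = Sp + Sv.
#'
#' @param hm a preprocessed (zero-mean) [heightmap].
#' @return named list with `S_q, S_sk, S_ku, S_p, S_v, S_z, S_a` (um except
#'   the dimensionless `S_sk`, `S_ku`). A zero-variance surface yields
#'   `S_sk = S_ku = NaN` with a warning rather than a silent zero.
#' @export
height_params <- function(hm) {
  .check_pre(hm)
  z <- as.vector(hm$z)
  m2 <- mean(z^2)
  if (m2 == 0) {
    warning("zero-variance surface: S_sk and S_ku are undefined")
    ssk <- NaN; sku <- NaN
  } else {
    ssk <- mean(z^3) / m2^1.5
    sku <- mean(z^4) / m2^2
  }
  sp <- max(z); sv <- -min(z)
  list(S_q = sqrt(m2), S_sk = ssk, S_ku = sku,
       S_p = sp, S_v = sv, S_z = sp + sv, S_a = mean(abs(z)))
}

#' Areal material ratio (Abbott-Firestone) curve
#'
#' `mr(c)` is the percentage of the evaluation area whose height is at or
#' above the section height `c` (material counted at `z >= c`, so a flat
#' surface sectioned at its own height has mr = 100%). The curve is sampled
#' at `n_levels` section heights spanning \[min, max\]; its inverse (height
#' at a given material ratio) is linearly interpolated.
#'
#' @param hm a preprocessed [heightmap].
#' @param n_levels number of section heights (>= 2; default 1024).
#' @return object of class `mr_curve`: `levels` (um, decreasing), `mr` (%,
#'   non-decreasing along the vector), mean height `m`, and the exact sorted
#'   heights used for inversion.
#' @export
material_ratio_curve <- function(hm, n_levels = 1024L) {
  .check_pre(hm)
  if (n_levels < 2L) stop("n_levels must be at least 2")
  z <- sort(as.vector(hm$z))           # ascending
  n <- length(z)
  lv <- seq(z[n], z[1L], length.out = n_levels)  # decreasing sections
  # count of points with z >= c  (z sorted ascending)
  cnt <- n - findInterval(lv, z, left.open = TRUE)
  structure(list(levels = lv, mr = 100 * cnt / n, m = mean(z),
                 sorted_z = z, n = n),
            class = "mr_curve")
}

#' @export
print.mr_curve <- function(x, ...) {
  cat(sprintf("<mr_curve> %d levels over [%.4g, %.4g] um, mean height %.4g um\n",
              length(x$levels), min(x$levels), max(x$levels), x$m))
  invisible(x)
}

# Inverse material ratio: height at material ratio p (%): the height below
# which (100-p)% of points lie. Continuous in p via linear interpolation on
# the empirical quantile function of the heights.
.inverse_mr <- function(curve, p) {
  stopifnot(inherits(curve, "mr_curve"))
  p <- pmin(pmax(p, 0), 100)
  # mr(c) = % of z >= c; height at ratio p is the (1 - p/100) quantile
  as.numeric(stats::quantile(curve$sorted_z, probs = 1 - p / 100,
                             names = FALSE, type = 7))
}

#' Areal material ratio at the mean height
#'
#' Smr = 100 * A(m) / A(N): the percentage of the evaluation area A(N) whose
#' material lies at or above the mean section height m.
#'
#' @param hm a preprocessed [heightmap].
#' @return Smr in percent.
#' @export
smr <- function(hm) {
  .check_pre(hm)
  m <- mean(hm$z)
  100 * mean(hm$z >= m)
}

#' Functional parameters from the material ratio curve
#'
#' `S_xp` is the peak-extreme section height difference between the material
#' ratios `p` and `q` (defaults 2.5% and 50%); `S_mc` is the inverse areal
#' material ratio: the section height at material ratio `mc_p` (default 10%).
#'
#' @param curve an `mr_curve`.
#' @param p,q material ratios in percent for `S_xp`; require `p < q`.
#' @param mc_p material ratio in percent for `S_mc`.
#' @return list with `S_mc`, `S_xp` (um).
#' @export
functional_params <- function(curve, p = 2.5, q = 50, mc_p = 10) {
  stopifnot(inherits(curve, "mr_curve"))
  if (p >= q) stop("`p` must be smaller than `q`")
  list(S_mc = .inverse_mr(curve, mc_p),
       S_xp = .inverse_mr(curve, p) - .inverse_mr(curve, q))
}

# Normalized areal autocorrelation of the (zero-mean) height grid, periodic
# FFT estimate, centered with lag (0,0) at element [cy, cx].
.acf_grid <- function(z) {
  z <- z - mean(z)
  f <- stats::fft(z)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))
  ac <- ac / ac[1L, 1L]
  nr <- nrow(z); nc <- ncol(z)
  # re-center: lag 0 at position (floor(nr/2)+1, floor(nc/2)+1)
  ac[c((floor(nr / 2) + 1L):nr, seq_len(floor(nr / 2))),
     c((floor(nc / 2) + 1L):nc, seq_len(floor(nc / 2)))]
}

#' Spatial parameters: autocorrelation length, texture aspect ratio and
#' texture direction
#'
#' From the normalized areal autocorrelation function (FFT estimate):
#' `S_al` is the shortest distance over which the ACF first decays to `s`;
#' `S_tr = S_al / (longest such distance)` lies in \[0, 1\]; `S_td` is the
#' dominant texture (lay) direction from the angular power spectrum,
#' measured in degrees counterclockwise from the positive x axis, reported
#' modulo 180 (a surface varying only along x, i.e. ridges running along y,
#' has `S_td` = 90).
#'
#' @param hm a preprocessed [heightmap] of at least 3 x 3 points.
#' @param s ACF decay threshold (default 0.2).
#' @param n_angles number of ray directions scanned over \[0, 180).
#' @return list with `S_al` (um), `S_tr` (dimensionless), `S_td` (degrees).
#' @export
spatial_params <- function(hm, s = 0.2, n_angles = 180L) {
  .check_pre(hm)
  nr <- nrow(hm$z); nc <- ncol(hm$z)
  if (nr < 3L || nc < 3L) stop("grid too small for spatial parameters")
  ac <- .acf_grid(hm$z)
  cy <- floor(nr / 2) + 1L; cx <- floor(nc / 2) + 1L
  rmax <- min((nr - 1) / 2 * hm$step_y, (nc - 1) / 2 * hm$step_x)
  rstep <- min(hm$step_x, hm$step_y) / 4
  rr <- seq(0, rmax, by = rstep)
  ang <- seq(0, 180, length.out = n_angles + 1L)[-(n_angles + 1L)] * pi / 180
  bilin <- function(y, x) {
    # interpolate ac at fractional (row, col) offsets from center
    i <- cy + y / hm$step_y; j <- cx + x / hm$step_x
    i0 <- floor(i); j0 <- floor(j); di <- i - i0; dj <- j - j0
    i0 <- pmin(pmax(i0, 1L), nr - 1L); j0 <- pmin(pmax(j0, 1L), nc - 1L)
    ac[cbind(i0, j0)] * (1 - di) * (1 - dj) +
      ac[cbind(i0 + 1L, j0)] * di * (1 - dj) +
      ac[cbind(i0, j0 + 1L)] * (1 - di) * dj +
      ac[cbind(i0 + 1L, j0 + 1L)] * di * dj
  }
  decay <- vapply(ang, function(a) {
    v <- bilin(rr * sin(a), rr * cos(a))
    k <- which(v < s)
    if (!length(k)) return(rmax)
    k <- k[1L]
    if (k == 1L) return(rr[1L])
    # linear crossing between rr[k-1] and rr[k]
    r0 <- rr[k - 1L]; r1 <- rr[k]; v0 <- v[k - 1L]; v1 <- v[k]
    r0 + (v0 - s) / (v0 - v1) * (r1 - r0)
  }, numeric(1))
  s_al <- min(decay); s_max <- max(decay)
  # texture direction: dominant angle of the angular power spectrum
  f <- stats::fft(hm$z - mean(hm$z))
  pw <- Mod(f)^2
  fy <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / (nr * hm$step_y)
  fx <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / (nc * hm$step_x)
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  th <- (atan2(FY, FX) * 180 / pi) %% 180
  pw[1L, 1L] <- 0                       # drop DC
  bins <- floor(th) %% 180
  pow <- vapply(split(as.vector(pw), as.vector(bins)), sum, numeric(1))
  spec_dir <- as.numeric(names(pow)[which.max(pow)]) + 0.5
  list(S_al = s_al, S_tr = s_al / s_max,
       S_td = (spec_dir + 90) %% 180)
}

#' Functional volume parameters
#'
#' Material and void volumes per unit area (um, since heights are um)
#' computed from the inverse material ratio curve zeta(mr):
#' `Vm(p) = (1/100) * integral_0^p (zeta(q') - zeta(p)) dq'` and
#' `Vv(p) = (1/100) * integral_p^100 (zeta(p) - zeta(q')) dq'`.
#' `V_mp = Vm(p)`, `V_vv = Vv(q)`, `V_mc = Vm(q) - Vm(p)`,
#' `V_vc = Vv(p) - Vv(q)` with ISO default ratios p = 10%, q = 80%.
#'
#' @param curve an `mr_curve`.
#' @param p,q material ratios in percent, `p < q`.
#' @return list with `V_m`, `V_v`, `V_mp`, `V_mc`, `V_vc`, `V_vv` (um).
#' @export
volume_params <- function(curve, p = 10, q = 80) {
  stopifnot(inherits(curve, "mr_curve"))
  if (p >= q) stop("`p` must be smaller than `q`")
  qs <- seq(0, 100, length.out = 2001L)
  zeta <- .inverse_mr(curve, qs)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  vm <- function(pp) {
    sel <- qs <= pp
    zp <- .inverse_mr(curve, pp)
    trap(qs[sel], zeta[sel] - zp) / 100
  }
  vv <- function(pp) {
    sel <- qs >= pp
    zp <- .inverse_mr(curve, pp)
    trap(qs[sel], zp - zeta[sel]) / 100
  }
  vmp <- vm(p); vmq <- vm(q); vvp <- vv(p); vvq <- vv(q)
  list(V_m = vmp, V_v = vvp, V_mp = vmp, V_mc = vmq - vmp,
       V_vc = vvp - vvq, V_vv = vvq)
}

#' Stratified (core/peak/valley) parameters
#'
#' Graphical construction on the areal material ratio curve: the secant over
#' a 40%-material-ratio-wide window with the smallest absolute slope defines
#' the equivalent core line; its intercepts at mr = 0 and mr = 100 give the
#' core limits. `S_k` is the core height, `S_mr1`/`S_mr2` the material
#' ratios where the curve crosses the core limits, and `S_pk`/`S_vk` the
#' reduced peak/valley heights from area-equivalent triangles above/below
#' the core.
#'
#' @param curve an `mr_curve`.
#' @param window secant window width in material-ratio percent (default 40).
#' @return list with `S_k`, `S_pk`, `S_vk` (um), `S_mr1`, `S_mr2` (%). A
#'   degenerate flat curve returns all-zero heights with `S_mr1 = 0`,
#'   `S_mr2 = 100`.
#' @export
stratified_params <- function(curve, window = 40) {
  stopifnot(inherits(curve, "mr_curve"))
  rng <- diff(range(curve$sorted_z))
  if (rng <= .Machine$double.eps * max(1, abs(curve$m))) {
    return(list(S_k = 0, S_pk = 0, S_vk = 0, S_mr1 = 0, S_mr2 = 100))
  }
  starts <- seq(0, 100 - window, by = 0.25)
  z0 <- .inverse_mr(curve, starts)
  z1 <- .inverse_mr(curve, starts + window)
  slope <- (z1 - z0) / window          # um per % (negative)
  k <- which.min(abs(slope))
  sl <- slope[k]
  h0 <- z0[k] - sl * starts[k]          # core line at mr = 0
  h100 <- h0 + sl * 100                 # core line at mr = 100
  s_k <- h0 - h100
  qs <- seq(0, 100, length.out = 2001L)
  zeta <- .inverse_mr(curve, qs)
  # S_mr1: material ratio where the curve crosses the upper core limit
  cross <- function(hh) {
    below <- zeta <= hh
    if (!any(below)) return(100)
    i <- which(below)[1L]
    if (i == 1L) return(0)
    q0 <- qs[i - 1L]; q1 <- qs[i]; v0 <- zeta[i - 1L]; v1 <- zeta[i]
    if (v0 == v1) return(q0)
    q0 + (v0 - hh) / (v0 - v1) * (q1 - q0)
  }
  smr1 <- cross(h0); smr2 <- cross(h100)
  trap <- function(x, y) if (length(x) < 2L) 0 else
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  sel1 <- qs <= smr1
  a1 <- trap(qs[sel1], pmax(zeta[sel1] - h0, 0))
  sel2 <- qs >= smr2
  a2 <- trap(qs[sel2], pmax(h100 - zeta[sel2], 0))
  s_pk <- if (smr1 > 0) 2 * a1 / smr1 else 0
  s_vk <- if (smr2 < 100) 2 * a2 / (100 - smr2) else 0
  list(S_k = s_k, S_pk = s_pk, S_vk = s_vk, S_mr1 = smr1, S_mr2 = smr2)
}

#' Compute the full 26-parameter set
#'
#' All six parameter families on one preprocessed height map; feature
#' parameters `S_10z` and `S_5v` are delegated to the watershed/Wolf-pruning
#' segmentation ([feature_params()]).
#'
#' @param hm a preprocessed [heightmap].
#' @param seg_cfg a [segmentation_config()] for the feature parameters.
#' @return named list of 26 parameters (class `parameter_set`). Values that
#'   are undefined for the input (e.g. `S_sk` on a flat surface, feature
#'   parameters when no feature survives pruning) are `NaN`/`NA`, never a
#'   silent zero.
#' @export
compute_all <- function(hm, seg_cfg = segmentation_config()) {
  .check_pre(hm)
  hp <- height_params(hm)
  curve <- material_ratio_curve(hm)
  fp <- functional_params(curve)
  sp <- spatial_params(hm)
  vp <- volume_params(curve)
  st <- stratified_params(curve)
  fe <- feature_params(hm, seg_cfg)
  out <- c(hp, list(S_mr = smr(hm)), fp, sp, vp, st,
           fe[c("S_10z", "S_5v")])
  class(out) <- "parameter_set"
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  v <- unlist(x)
  cat("<parameter_set> 26 areal surface texture parameters\n")
  print(round(v, 4))
  invisible(x)
}
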