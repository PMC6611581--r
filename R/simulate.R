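#' Study configuration for the synthetic-data generators
#'
#' Collects the statistical structure the generators emulate: group moments
#' of the screened parameters for colonized versus bare dales (the three
#' parameters found significant, with the remaining 23 generated with no
#' group difference so screening specificity is testable), dale counts per
#' group, per-level hill/dale attribute means of the fabricated designs,
#' biomass level moments and the balanced floway layout (3 trials x 4 lanes
#' x 6 tiles, three of each level per lane per trial), and the
#' hill-placement bias of early colonization sites.
#'
#' @param seed master seed; every generator defaults to it.
#' @param n_colonized,n_bare dale counts (defaults 21 / 21).
#' @param sv_colonized,sv_bare,sa_colonized,sa_bare,smr_colonized,smr_bare
#'   `c(mean, sd)` pairs for the three group-different parameters (um for
#'   Sv/Sa; the Smr group statistics are carried verbatim as configured,
#'   opaque to the generator's unit bookkeeping).
#' @param biomass_level1,biomass_level2 `c(mean, sd)` dry biomass (mg/cm^2).
#' @param replicates_per_trial,trials,lanes floway design (12, 3, 4).
#' @param hill_height_level1,hill_height_level2 mean fabricated hill heights
#'   (mm); `dale_depth_level1`, `dale_depth_level2` mean dale depths (mm).
#' @param hill_bias probability that an early colonization site lands on a
#'   hill-class point.
#' @param null_params named list of `c(mean, sd)` for the remaining
#'   parameters (shared between groups); the built-in defaults cover the
#'   full 26-parameter set.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_colonized = 21L, n_bare = 21L,
                         sv_colonized = c(203.94, 49.14),
                         sv_bare = c(163.63, 55.86),
                         sa_colonized = c(46.63, 12.09),
                         sa_bare = c(38.24, 10.94),
                         smr_colonized = c(0.001, 0.001),
                         smr_bare = c(0.004, 0.002),
                         biomass_level1 = c(0.50, 0.16),
                         biomass_level2 = c(1.86, 0.40),
                         replicates_per_trial = 12L, trials = 3L,
                         lanes = 4L,
                         hill_height_level1 = 2.58,
                         hill_height_level2 = 8.29,
                         dale_depth_level1 = 6.64,
                         dale_depth_level2 = 8.35,
                         hill_bias = 0.99,
                         null_params = NULL) {
  defaults <- list(
    S_q = c(58, 15), S_sk = c(-0.3, 0.2), S_ku = c(3.0, 0.4),
    S_p = c(250, 60), S_z = c(450, 90), S_mc = c(70, 18), S_xp = c(90, 25),
    S_al = c(120, 30), S_tr = c(0.6, 0.15), S_td = c(90, 40),
    V_m = c(2.5, 0.8), V_v = c(60, 15), V_mp = c(2.5, 0.8),
    V_mc = c(50, 12), V_vc = c(55, 14), V_vv = c(7, 2),
    S_k = c(110, 25), S_pk = c(45, 15), S_vk = c(60, 20),
    S_mr1 = c(10, 3), S_mr2 = c(88, 5), S_10z = c(380, 80),
    S_5v = c(180, 45))
  if (!is.null(null_params)) defaults[names(null_params)] <- null_params
  stopifnot(n_colonized >= 2L, n_bare >= 2L, hill_bias >= 0, hill_bias <= 1,
            all(vapply(defaults, function(p) p[2L] > 0, logical(1))))
  structure(list(
    seed = as.integer(seed),
    n_colonized = as.integer(n_colonized), n_bare = as.integer(n_bare),
    group_params = list(S_v = list(colonized = sv_colonized, bare = sv_bare),
                        S_a = list(colonized = sa_colonized, bare = sa_bare),
                        S_mr = list(colonized = smr_colonized,
                                    bare = smr_bare)),
    null_params = defaults,
    biomass = list(level1 = biomass_level1, level2 = biomass_level2,
                   replicates_per_trial = as.integer(replicates_per_trial),
                   trials = as.integer(trials), lanes = as.integer(lanes)),
    design_attributes = list(
      hill_height_mm = c(level1 = hill_height_level1,
                         level2 = hill_height_level2),
      dale_depth_mm = c(level1 = dale_depth_level1,
                        level2 = dale_depth_level2)),
    hill_bias = hill_bias),
    class = "study_config")
}

#' Generate a per-feature parameter observation table
#'
#' Emulates the sampling frame of the rock-surface screen: `n_colonized`
#' plus `n_bare` dales (each rock specimen contributing about two of each),
#' with all 26 areal parameters drawn per feature. The three
#' group-different parameters use their configured group moments; all
#' others share one distribution across groups. Parameters with positive
#' means are drawn from moment-matched zero-truncated normals (depths,
#' amplitudes and ratios cannot be negative); the skewness column, which is
#' signed, uses a plain normal.
#'
#' @param cfg a [study_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return data.frame: `specimen`, `group` (factor colonized/bare) and 26
#'   numeric parameter columns. Deterministic per seed.
#' @export
gen_feature_table <- function(cfg = study_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(as.integer(seed))
  n1 <- cfg$n_colonized; n2 <- cfg$n_bare
  group <- factor(rep(c("colonized", "bare"), c(n1, n2)),
                  levels = c("colonized", "bare"))
  draw <- function(n, ms) {
    if (ms[1L] > 0) rtnorm_matched(n, ms[1L], ms[2L])
    else stats::rnorm(n, ms[1L], ms[2L])
  }
  out <- data.frame(
    specimen = c(rep_len(1:10, n1)[order(rep_len(1:10, n1))],
                 rep_len(1:10, n2)[order(rep_len(1:10, n2))]),
    group = group)
  for (pn in names(cfg$group_params)) {
    gp <- cfg$group_params[[pn]]
    out[[pn]] <- c(draw(n1, gp$colonized), draw(n2, gp$bare))
  }
  for (pn in setdiff(names(cfg$null_params), names(cfg$group_params)))
    out[[pn]] <- draw(n1 + n2, cfg$null_params[[pn]])
  out
}

#' Generate a rock-like surface with registered dales
#'
#' A flat, gently tilted base with small-scale measurement-like noise and
#' `n_dales` embedded smooth cosine-bell pits at registered, non-overlapping
#' locations, with depths drawn from a moment-matched zero-truncated normal.
#' The returned registry (true count, centres, depths) is the ground truth
#' against which segmentation and attribute recovery are checked.
#'
#' @param cfg a [study_config()] (supplies the default depth moments from
#'   the colonized-dale statistics).
#' @param n_dales number of pits (0 gives a tilted-noise surface with no
#'   significant dale).
#' @param depth_mean,depth_sd pit depth moments, um.
#' @param seed integer seed.
#' @param rows,cols,step grid geometry (step in um).
#' @param pit_radius pit radius, um.
#' @param noise_sd measurement-scale roughness, um.
#' @param tilt plane slope in um per um along x.
#' @return list: `heightmap` (not yet preprocessed), `registry` data.frame
#'   (`dale`, `row`, `col`, `depth`).
#' @export
gen_rock_surface <- function(cfg = study_config(), n_dales = 8L,
                             depth_mean = cfg$group_params$S_v$colonized[1L],
                             depth_sd = cfg$group_params$S_v$colonized[2L],
                             seed = cfg$seed, rows = 200L, cols = 200L,
                             step = 5, pit_radius = 80, noise_sd = 2,
                             tilt = 0.01) {
  stopifnot(inherits(cfg, "study_config"), n_dales >= 0L)
  set.seed(as.integer(seed))
  rows <- as.integer(rows); cols <- as.integer(cols)
  r_px <- pit_radius / step
  margin <- ceiling(r_px) + 2L
  if (n_dales > 0L && (rows - 2L * margin < 1L || cols - 2L * margin < 1L))
    stop("grid too small for the requested pit radius")
  centers <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(centers) < n_dales) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop("overcrowded placement: could not fit ", n_dales,
           " non-overlapping dales")
    cand <- c(sample(margin:(rows - margin), 1L),
              sample(margin:(cols - margin), 1L))
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1L] - cand[1L])^2 +
                   (centers[, 2L] - cand[2L])^2) > 2 * r_px + 2))
      centers <- rbind(centers, cand)
  }
  depths <- if (n_dales > 0L) rtnorm_matched(n_dales, depth_mean, depth_sd)
    else numeric(0)
  xs <- (seq_len(cols) - 1) * step
  z <- matrix(stats::rnorm(rows * cols, 0, noise_sd), rows, cols) +
    matrix(tilt * xs, rows, cols, byrow = TRUE)
  for (k in seq_len(n_dales)) {
    ri <- centers[k, 1L]; ci <- centers[k, 2L]
    rr <- max(1L, ri - ceiling(r_px)):min(rows, ri + ceiling(r_px))
    cc <- max(1L, ci - ceiling(r_px)):min(cols, ci + ceiling(r_px))
    d <- sqrt(outer((rr - ri)^2, (cc - ci)^2, `+`))
    bump <- ifelse(d <= r_px, 0.5 * (1 + cos(pi * d / r_px)), 0)
    z[rr, cc] <- z[rr, cc] - depths[k] * bump
  }
  hm <- heightmap(z, step, step,
                  origin_note = sprintf("synthetic rock surface, seed %d",
                                        as.integer(seed)))
  registry <- data.frame(dale = seq_len(n_dales),
                         row = centers[seq_len(n_dales), 1L],
                         col = centers[seq_len(n_dales), 2L],
                         depth = depths)
  list(heightmap = hm, registry = registry)
}

#' Generate a biomass dataset with the floway layout
#'
#' Balanced design: `trials` trials, `lanes` flow lanes, six tiles per lane
#' per trial placed alternately so each lane carries three tiles of each
#' treatment level, giving `replicates_per_trial` tiles per level per trial
#' (36 per level overall at the defaults). Biomass is drawn from
#' moment-matched zero-truncated normals at the configured level moments.
#'
#' @param cfg a [study_config()].
#' @param seed integer seed.
#' @return data.frame: `biomass` (mg/cm^2), `level` (factor "1"/"2"),
#'   `lane`, `trial`, `position`.
#' @export
gen_biomass <- function(cfg = study_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(as.integer(seed))
  b <- cfg$biomass
  tiles_per_lane <- 2L * b$replicates_per_trial / b$lanes  # 6 at defaults
  layout <- expand.grid(position = seq_len(tiles_per_lane),
                        lane = seq_len(b$lanes), trial = seq_len(b$trials))
  layout$level <- factor(ifelse(layout$position %% 2L == 1L, "1", "2"))
  n1 <- sum(layout$level == "1"); n2 <- sum(layout$level == "2")
  layout$biomass <- NA_real_
  layout$biomass[layout$level == "1"] <-
    rtnorm_matched(n1, b$level1[1L], b$level1[2L])
  layout$biomass[layout$level == "2"] <-
    rtnorm_matched(n2, b$level2[1L], b$level2[2L])
  layout[, c("biomass", "level", "lane", "trial", "position")]
}

#' Generate early-colonization sites biased to hills
#'
#' Each site lands on a hill-class point (height at or above the hill
#' threshold) with probability `hill_bias`, otherwise uniformly on a
#' non-hill point, emulating the observed localization of initial algal
#' attachment on the elevated features of the surface.
#'
#' @param hm a [heightmap].
#' @param n_sites number of sites (> 0).
#' @param hill_bias hill-placement probability (defaults to the configured
#'   study value).
#' @param cfg a [site_classification_config()].
#' @param seed integer seed.
#' @return data.frame `row`, `col`. Deterministic per seed.
#' @export
gen_colonization_map <- function(hm, n_sites = 300L,
                                 hill_bias = 0.99,
                                 cfg = site_classification_config(),
                                 seed = 1L) {
  stopifnot(inherits(hm, "heightmap"),
            inherits(cfg, "site_classification_config"), n_sites > 0L)
  set.seed(as.integer(seed))
  hill <- which(hm$z >= cfg$hill_height_min)
  nonhill <- which(hm$z < cfg$hill_height_min)
  if (!length(hill) && hill_bias > 0)
    stop("no hill-class points on this map but hill_bias > 0")
  if (!length(nonhill) && hill_bias < 1)
    stop("no non-hill points on this map but hill_bias < 1")
  on_hill <- stats::runif(n_sites) < hill_bias
  idx <- integer(n_sites)
  if (any(on_hill))
    idx[on_hill] <- hill[sample.int(length(hill), sum(on_hill),
                                    replace = TRUE)]
  if (any(!on_hill))
    idx[!on_hill] <- nonhill[sample.int(length(nonhill), sum(!on_hill),
                                        replace = TRUE)]
  nr <- nrow(hm$z)
  data.frame(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}
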