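#' Screen areal parameters between colonized and bare features
#'
#' Per-parameter one-way ANOVA between the two feature groups (for two
#' groups the F statistic is the square of the two-sample pooled-variance t
#' statistic, with 1 and N - 2 degrees of freedom). Reporting follows the
#' screening-table layout: group means and SDs, F, p, and a significance
#' flag at `alpha`. Tests are per-parameter with no multiple-testing
#' correction by default (`p_adjust = "none"`); pass a `p.adjust` method to
#' change that.
#'
#' @param tbl data.frame with a `group` column (two levels, each with at
#'   least 2 observations) and one numeric column per parameter; columns
#'   named `group` or `specimen` are treated as metadata.
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return data.frame, one row per parameter: means/SDs per group, `n` per
#'   group, `F`, `df1`, `df2`, `p_value`, `significant`. A within-group
#'   constant parameter (zero pooled variance) gets `NA` F and p, flagged
#'   by the `degenerate` column, never a silent zero.
#' @export
screen_parameters <- function(tbl, alpha = 0.05, p_adjust = "none") {
  tbl <- as.data.frame(tbl)
  if (!"group" %in% names(tbl)) stop("`tbl` needs a `group` column")
  g <- factor(tbl$group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  n1 <- sum(g == levels(g)[1L]); n2 <- sum(g == levels(g)[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  params <- setdiff(names(tbl), c("group", "specimen"))
  params <- params[vapply(tbl[params], is.numeric, logical(1))]
  if (!length(params)) stop("no numeric parameter columns found")
  rows <- lapply(params, function(pn) {
    x1 <- tbl[[pn]][g == levels(g)[1L]]
    x2 <- tbl[[pn]][g == levels(g)[2L]]
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    if (!is.finite(sp2) || sp2 <= 0) {
      Fv <- NA_real_; p <- NA_real_; degen <- TRUE
    } else {
      tstat <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      Fv <- tstat^2
      p <- stats::pf(Fv, 1, n1 + n2 - 2, lower.tail = FALSE)
      degen <- FALSE
    }
    data.frame(parameter = pn,
               mean_1 = mean(x1), sd_1 = stats::sd(x1), n_1 = n1,
               mean_2 = mean(x2), sd_2 = stats::sd(x2), n_2 = n2,
               F = Fv, df1 = 1, df2 = n1 + n2 - 2, p_value = p,
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 5)] <- paste0("mean_", levels(g))
  names(out)[c(3, 6)] <- paste0("sd_", levels(g))
  names(out)[c(4, 7)] <- paste0("n_", levels(g))
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Compare biomass accrual between treatment levels
#'
#' One-way ANOVA of dry biomass on treatment level, with the supporting
#' checks reported alongside: the ratio of level means, a Tukey HSD test of
#' lane differences within each level (the flow lanes should not differ),
#' and an Anderson-Darling normality test on the ANOVA residuals (reported,
#' never used to gate the ANOVA).
#'
#' @param ds data.frame with columns `biomass` (mg/cm^2, >= 0), `level`
#'   (two or more treatment levels), `lane`, and optionally `trial`.
#' @param alpha significance level used for the `significant` flag.
#' @return list of class `biomass_comparison`: `level_summary` (mean, sd, n
#'   per level), `ratio_of_means` (highest/lowest level mean), `F`, `df`,
#'   `p_value`, `significant`, `tukey_lanes` (per-level data.frame of lane
#'   pair contrasts), `anderson_darling` (statistic and p).
#' @export
compare_biomass <- function(ds, alpha = 0.05) {
  ds <- as.data.frame(ds)
  need <- c("biomass", "level", "lane")
  if (!all(need %in% names(ds)))
    stop("`ds` needs columns ", paste(need, collapse = ", "))
  if (any(ds$biomass < 0)) stop("biomass must be non-negative")
  ds$level <- droplevels(factor(ds$level))
  ds$lane <- droplevels(factor(ds$lane))
  if (nlevels(ds$level) < 2L) stop("need at least two treatment levels")
  cnt <- table(ds$level)
  if (any(cnt < 2L)) stop("every level needs at least 2 tiles")
  fit <- stats::aov(biomass ~ level, data = ds)
  an <- stats::anova(fit)
  mu <- tapply(ds$biomass, ds$level, mean)
  level_summary <- data.frame(level = names(mu), mean = as.numeric(mu),
                              sd = as.numeric(tapply(ds$biomass, ds$level,
                                                     stats::sd)),
                              n = as.integer(cnt), row.names = NULL)
  tukey <- lapply(split(ds, ds$level), function(d) {
    d$lane <- droplevels(d$lane)
    if (nlevels(d$lane) < 2L || any(table(d$lane) < 2L)) return(NULL)
    tk <- stats::TukeyHSD(stats::aov(biomass ~ lane, data = d))$lane
    data.frame(contrast = rownames(tk), diff = tk[, "diff"],
               lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = tk[, "p adj"], row.names = NULL)
  })
  res <- stats::residuals(fit)
  ad <- nortest::ad.test(res)
  structure(list(
    level_summary = level_summary,
    ratio_of_means = max(mu) / min(mu),
    F = an$`F value`[1L],
    df = c(an$Df[1L], an$Df[2L]),
    p_value = an$`Pr(>F)`[1L],
    significant = an$`Pr(>F)`[1L] < alpha,
    tukey_lanes = tukey,
    anderson_darling = list(statistic = unname(ad$statistic),
                            p_value = ad$p.value)),
    class = "biomass_comparison")
}

#' @export
print.biomass_comparison <- function(x, ...) {
  cat("<biomass_comparison>\n")
  print(x$level_summary)
  cat(sprintf("  ratio of level means: %.2f\n", x$ratio_of_means))
  cat(sprintf("  one-way ANOVA: F[%d, %d] = %.2f, p = %.3g\n",
              x$df[1L], x$df[2L], x$F, x$p_value))
  cat(sprintf("  Anderson-Darling on residuals: A = %.3f, p = %.3g\n",
              x$anderson_darling$statistic, x$anderson_darling$p_value))
  invisible(x)
}

#' Fraction of early-colonization sites on hills
#'
#' Classifies each observed colonization site by the height thresholds of
#' [classify_sites()] and reports the percentage that fall on hills (the
#' primary quantity); as a secondary output, when a pruned hill
#' [watershed_segment()] feature set is supplied, the ratio of hill
#' features containing at least one site to those containing none.
#'
#' @param hm a [heightmap].
#' @param sites data.frame with `row`, `col` site coordinates (non-empty).
#' @param cfg a [site_classification_config()].
#' @param hill_features optional pruned `feature_set` of kind `"hill"` for
#'   the per-feature attract ratio.
#' @return list: `fraction_on_hills` (%), `site_labels` (the
#'   [classify_sites()] table), and `hill_attract_ratio` (`NA` unless
#'   `hill_features` is given; `Inf` when every hill attracts).
#' @export
hill_localization <- function(hm, sites, cfg = site_classification_config(),
                              hill_features = NULL) {
  labs <- classify_sites(hm, sites, cfg)
  ratio <- NA_real_
  if (!is.null(hill_features)) {
    stopifnot(inherits(hill_features, "feature_set"))
    if (hill_features$kind != "hill") stop("hill_features must be hills")
    ids <- setdiff(unique(as.vector(hill_features$labels)), 0L)
    hit <- unique(hill_features$labels[cbind(labs$row, labs$col)])
    n_attract <- length(intersect(ids, hit))
    n_not <- length(ids) - n_attract
    ratio <- if (n_not == 0L) Inf else n_attract / n_not
  }
  list(fraction_on_hills = attr(labs, "hill_fraction"),
       site_labels = labs, hill_attract_ratio = ratio)
}
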