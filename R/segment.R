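#' Segmentation configuration
#'
#' @param prune_fraction Wolf-pruning threshold as a fraction of Sz, the
#'   maximum height of the surface (default 0.10, the recommended setting).
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @param kind `"dale"` (catchment basins of z) or `"hill"` (basins of -z).
#' @param border_saddle treat the map border as an escape route: a feature
#'   whose lowest escape lies over the border is pruned into the unassigned
#'   background (label 0) when below threshold (default `TRUE`). With
#'   `FALSE`, features merge only across internal saddles.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(prune_fraction = 0.10, connectivity = 8L,
                                kind = c("dale", "hill"),
                                border_saddle = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(prune_fraction) || prune_fraction <= 0 ||
      prune_fraction >= 1)
    stop("prune_fraction must be in (0, 1)")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(prune_fraction = prune_fraction,
                 connectivity = as.integer(connectivity), kind = kind,
                 border_saddle = isTRUE(border_saddle)),
            class = "segmentation_config")
}

#' Site classification thresholds
#'
#' Height thresholds used to classify map locations in the early-colonization
#' analysis: points at `hill_height_min` (default 3000 um) or higher are
#' hills, points at `dale_height_max` (default 0 um) or below are dales,
#' everything between is neither.
#'
#' @param hill_height_min hill threshold, um.
#' @param dale_height_max dale threshold, um; must be below `hill_height_min`.
#' @return list of class `site_classification_config`.
#' @export
site_classification_config <- function(hill_height_min = 3000,
                                       dale_height_max = 0) {
  if (hill_height_min <= dale_height_max)
    stop("hill_height_min must exceed dale_height_max")
  structure(list(hill_height_min = hill_height_min,
                 dale_height_max = dale_height_max),
            class = "site_classification_config")
}

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

# Deterministic watershed by lexicographic steepest descent. Every cell
# drains to the neighbour with the smallest (height, row, col) key if that
# key is below its own; cells without a lower-keyed neighbour are local
# minima and seed basins. Ties on height resolve by (row, col), making
# plateaus deterministic.
.watershed_basins <- function(z, connectivity) {
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  off <- .neighbor_offsets(connectivity)
  ord <- order(as.vector(z), row(z), col(z))
  rank <- integer(n); rank[ord] <- seq_len(n)
  rankm <- matrix(rank, nr, nc)
  # best (lowest-rank) neighbour of each cell, vectorized over offsets
  bestrank <- rankm
  bestidx <- matrix(seq_len(n), nr, nc)
  idxm <- matrix(seq_len(n), nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]; dc <- off[k, 2L]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)   # rows with in-range neighbour
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    nb_rank <- rankm[rs + dr, cs + dc, drop = FALSE]
    cur <- bestrank[rs, cs, drop = FALSE]
    take <- nb_rank < cur
    if (any(take)) {
      bi <- bestidx[rs, cs, drop = FALSE]
      ni <- idxm[rs + dr, cs + dc, drop = FALSE]
      bi[take] <- ni[take]
      cur[take] <- nb_rank[take]
      bestidx[rs, cs] <- bi
      bestrank[rs, cs] <- cur
    }
  }
  drain <- as.vector(bestidx)
  labels <- integer(n)
  nlab <- 0L
  for (p in ord) {
    d <- drain[p]
    if (d == p) { nlab <- nlab + 1L; labels[p] <- nlab }
    else labels[p] <- labels[d]      # drain has lower rank: already labeled
  }
  matrix(labels, nr, nc)
}

# Saddle structure of a labeling on the working surface w (features are
# minima of w): for every adjacent pair of labels the minimum over boundary
# cross-pairs of max(w_p, w_q), plus each label's border escape (min w over
# its map-border cells). Vectorized construction.
.build_saddles <- function(w, labels, connectivity) {
  nr <- nrow(w); nc <- ncol(w)
  off <- .neighbor_offsets(connectivity)
  av <- integer(0); bv <- integer(0); hv <- numeric(0)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]; dc <- off[k, 2L]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- labels[rs, cs, drop = FALSE]
    b <- labels[rs + dr, cs + dc, drop = FALSE]
    sel <- a != b
    if (any(sel)) {
      h <- pmax(w[rs, cs, drop = FALSE],
                w[rs + dr, cs + dc, drop = FALSE])[sel]
      av <- c(av, a[sel]); bv <- c(bv, b[sel]); hv <- c(hv, h)
    }
  }
  if (length(hv)) {
    lo <- pmin(av, bv); hi <- pmax(av, bv)
    key <- paste0(lo, "|", hi)
    agg <- tapply(hv, key, min)
    pairs <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  } else {
    agg <- numeric(0)
    pairs <- matrix(character(0), 0L, 2L)
  }
  nmax <- max(labels)
  border <- rep(Inf, nmax)
  bsel <- rbind(cbind(1L, seq_len(nc)), cbind(nr, seq_len(nc)),
                cbind(seq_len(nr), 1L), cbind(seq_len(nr), nc))
  blab <- labels[bsel]; bw <- w[bsel]
  keep <- blab > 0L
  if (any(keep)) {
    bm <- tapply(bw[keep], blab[keep], min)
    border[as.integer(names(bm))] <- pmin(border[as.integer(names(bm))], bm)
  }
  list(a = as.integer(pairs[, 1L]), b = as.integer(pairs[, 2L]),
       h = as.numeric(agg), border = border)
}

#' Watershed segmentation of a height map into hills or dales
#'
#' Dales are the catchment basins of the height function (every point drains
#' along steepest descent to a local minimum); hills are the basins of the
#' negated surface. Plateaus and ties are resolved lexicographically by
#' (height, row, column) so the segmentation is deterministic.
#'
#' @param hm a preprocessed [heightmap], at least 3 x 3.
#' @param kind `"dale"` or `"hill"`.
#' @param connectivity 4 or 8 (default 8).
#' @return object of class `feature_set`: integer `labels` matrix (a basin
#'   id per point; ids partition the grid), `kind`, the pruning threshold
#'   used (`NA` until [wolf_prune()]), and the generating map's Sz.
#' @export
watershed_segment <- function(hm, kind = c("dale", "hill"),
                              connectivity = 8L) {
  .check_pre(hm)
  kind <- match.arg(kind)
  if (nrow(hm$z) < 3L || ncol(hm$z) < 3L) stop("grid smaller than 3x3")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  z <- if (kind == "dale") hm$z else -hm$z
  labels <- .watershed_basins(z, as.integer(connectivity))
  hp <- suppressWarnings(height_params(hm))
  structure(list(labels = labels, kind = kind,
                 connectivity = as.integer(connectivity),
                 prune_threshold = NA_real_, s_z = hp$S_z,
                 pruned = FALSE),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<feature_set> %d %s feature(s)%s\n", length(ids), x$kind,
              if (x$pruned)
                sprintf(", Wolf-pruned at %.4g um", x$prune_threshold)
              else " (unpruned)"))
  invisible(x)
}

#' Wolf-prune a watershed segmentation
#'
#' Iteratively merges insignificant features. The Wolf height of a feature
#' is the absolute difference between its local extreme and the lowest
#' saddle on its boundary; any feature whose Wolf height is below
#' `prune_fraction * Sz` is merged into the neighbour across that saddle,
#' smallest Wolf height first, until every retained feature is significant.
#' When `border_saddle` is set and a feature's lowest escape is over the map
#' border, pruning moves it to the unassigned background (label 0), which is
#' how a featureless tilted plane ends with zero significant features.
#'
#' @param fs a `feature_set` from [watershed_segment()].
#' @param hm the generating [heightmap].
#' @param cfg a [segmentation_config()]; its `kind` must match `fs`.
#' @return a pruned `feature_set` (labels renumbered 1..n in order of
#'   decreasing feature magnitude; 0 = background). Idempotent at a fixed
#'   threshold; the retained count is non-increasing in `prune_fraction`.
#' @export
wolf_prune <- function(fs, hm, cfg = segmentation_config(kind = fs$kind)) {
  stopifnot(inherits(fs, "feature_set"), inherits(hm, "heightmap"),
            inherits(cfg, "segmentation_config"))
  if (!identical(dim(fs$labels), dim(hm$z)))
    stop("feature set and height map shapes differ")
  if (cfg$kind != fs$kind)
    stop("config kind (", cfg$kind, ") does not match feature set (",
         fs$kind, ")")
  w <- if (fs$kind == "dale") hm$z else -hm$z
  threshold <- cfg$prune_fraction * fs$s_z
  labels <- fs$labels
  nmax <- max(labels)
  if (nmax > 0L) {
    mins <- rep(NA_real_, nmax)
    mtab <- tapply(as.vector(w), as.vector(labels), min)
    mids <- as.integer(names(mtab))
    pos <- mids > 0L
    mins[mids[pos]] <- mtab[pos]
    sd0 <- .build_saddles(w, labels, fs$connectivity)
    # adjacency as per-feature neighbour/saddle vectors
    nb <- vector("list", nmax); sv <- vector("list", nmax)
    for (e in seq_along(sd0$h)) {
      a <- sd0$a[e]; b <- sd0$b[e]; h <- sd0$h[e]
      if (a > 0L) { nb[[a]] <- c(nb[[a]], b); sv[[a]] <- c(sv[[a]], h) }
      if (b > 0L) { nb[[b]] <- c(nb[[b]], a); sv[[b]] <- c(sv[[b]], h) }
    }
    border <- sd0$border
    alive <- !is.na(mins)
    # union-find over merged labels so stale neighbour ids resolve
    parent <- seq_len(nmax)
    findrt <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    low_sad <- rep(Inf, nmax); tgt <- rep(NA_integer_, nmax)
    refresh <- function(f) {
      # recompute lowest escape of live feature f from its lists
      if (!length(nb[[f]])) { ls_ <- Inf; tg <- NA_integer_ }
      else {
        roots <- vapply(nb[[f]], function(x) if (x == 0L) 0L else findrt(x),
                        integer(1))
        keep <- roots != f & roots > 0L
        keep[keep] <- alive[roots[keep]]
        nb[[f]] <<- roots[keep]; sv[[f]] <<- sv[[f]][keep]
        if (length(nb[[f]])) {
          # collapse duplicate neighbours to their min saddle
          o <- order(nb[[f]], sv[[f]])
          nn <- nb[[f]][o]; ss <- sv[[f]][o]
          first <- !duplicated(nn)
          nb[[f]] <<- nn[first]; sv[[f]] <<- ss[first]
          k <- which.min(sv[[f]])
          ls_ <- sv[[f]][k]; tg <- nb[[f]][k]
        } else { ls_ <- Inf; tg <- NA_integer_ }
      }
      if (cfg$border_saddle && border[f] < ls_) { ls_ <- border[f]; tg <- 0L }
      low_sad[f] <<- ls_; tgt[f] <<- tg
    }
    for (f in which(alive)) refresh(f)
    repeat {
      wolf <- ifelse(alive, low_sad - mins, Inf)
      v <- which.min(wolf)
      if (!is.finite(wolf[v]) || wolf[v] >= threshold) break
      t <- tgt[v]
      if (is.na(t)) break
      if (t == 0L) {
        # escape over the border: feature dissolves into background; its
        # neighbours may now escape through it at their mutual saddle
        rts <- if (length(nb[[v]]))
          vapply(nb[[v]], findrt, integer(1)) else integer(0)
        for (ii in seq_along(rts)) {
          x <- rts[ii]
          if (x != v && alive[x] && sv[[v]][ii] < border[x])
            border[x] <- sv[[v]][ii]
        }
        alive[v] <- FALSE
        labels[labels == v] <- 0L
        for (x in unique(rts)) if (x != v && alive[x]) refresh(x)
      } else {
        t <- findrt(t)
        parent[v] <- t
        mins[t] <- min(mins[t], mins[v])
        border[t] <- min(border[t], border[v])
        nb[[t]] <- c(nb[[t]], nb[[v]]); sv[[t]] <- c(sv[[t]], sv[[v]])
        nb[[v]] <- integer(0); sv[[v]] <- numeric(0)
        alive[v] <- FALSE
        touched <- unique(c(t, nb[[t]]))
        for (x in touched) if (x > 0L && alive[x]) refresh(x)
      }
    }
    # write merged labels back and renumber by decreasing magnitude
    if (any(!alive)) {
      remap <- vapply(seq_len(nmax), function(x)
        if (parent[x] == x) x else findrt(x), integer(1))
      sel <- labels > 0L
      labels[sel] <- remap[labels[sel]]
      labels[sel][!alive[labels[sel]]] <- 0L   # dissolved features
    }
    ids <- setdiff(sort(unique(as.vector(labels))), 0L)
    if (length(ids)) {
      newid <- integer(nmax)
      newid[ids[order(mins[ids], ids)]] <- seq_along(ids)
      sel <- labels > 0L
      labels[sel] <- newid[labels[sel]]
    }
  }
  fs$labels <- labels
  fs$prune_threshold <- threshold
  fs$pruned <- TRUE
  fs
}

#' Per-feature attribute table
#'
#' @param fs a (typically pruned) `feature_set`.
#' @param hm the generating [heightmap].
#' @return data.frame with one row per feature: `feature` id, `kind`,
#'   `extreme` (signed height of the local extreme, um, relative to the
#'   mean plane), `magnitude` (depth for dales, height for hills, um),
#'   `area_mm2`, `mean_magnitude` (mean depth/height over the feature, um),
#'   `saddle` (lowest boundary saddle on the original surface, um) and
#'   `n_points`. An empty feature set gives an empty table.
#' @export
feature_attributes <- function(fs, hm) {
  stopifnot(inherits(fs, "feature_set"), inherits(hm, "heightmap"))
  if (!identical(dim(fs$labels), dim(hm$z)))
    stop("feature set and height map shapes differ")
  ids <- setdiff(sort(unique(as.vector(fs$labels))), 0L)
  empty <- data.frame(feature = integer(), kind = character(),
                      extreme = numeric(), magnitude = numeric(),
                      area_mm2 = numeric(), mean_magnitude = numeric(),
                      saddle = numeric(), n_points = integer())
  if (!length(ids)) return(empty)
  sgn <- if (fs$kind == "dale") 1 else -1
  w <- sgn * hm$z
  sd0 <- .build_saddles(w, fs$labels, fs$connectivity)
  low_sad <- rep(Inf, max(ids))
  for (e in seq_along(sd0$h)) {
    a <- sd0$a[e]; b <- sd0$b[e]; h <- sd0$h[e]
    if (a > 0L && h < low_sad[a]) low_sad[a] <- h
    if (b > 0L && h < low_sad[b]) low_sad[b] <- h
  }
  low_sad <- pmin(low_sad, sd0$border[seq_along(low_sad)])
  cell_mm2 <- hm$step_x * hm$step_y / 1e6
  rows <- lapply(ids, function(l) {
    sel <- fs$labels == l
    wmin <- min(w[sel])
    data.frame(feature = l, kind = fs$kind,
               extreme = sgn * wmin,
               magnitude = -wmin,
               area_mm2 = sum(sel) * cell_mm2,
               mean_magnitude = mean(pmax(-w[sel], 0)),
               saddle = sgn * low_sad[l],
               n_points = sum(sel))
  })
  do.call(rbind, rows)
}

#' Feature parameters S5p, S5v, S10z
#'
#' `S_5p` is the mean height of the five highest significant hill peaks,
#' `S_5v` the mean depth of the five deepest significant dale pits (both
#' after watershed segmentation and Wolf pruning at `cfg$prune_fraction` of
#' Sz), and `S_10z = S_5p + S_5v`. If fewer than five significant features
#' of a kind exist, all are used and the result is flagged; with none at
#' all the corresponding value is `NA`.
#'
#' @param hm a preprocessed [heightmap].
#' @param cfg a [segmentation_config()] (its `kind` field is ignored; both
#'   kinds are segmented).
#' @return list with `S_10z`, `S_5v`, `S_5p` (um) and logical
#'   `fewer_than_five`.
#' @export
feature_params <- function(hm, cfg = segmentation_config()) {
  .check_pre(hm)
  vals <- lapply(c("dale", "hill"), function(kind) {
    cfgk <- segmentation_config(cfg$prune_fraction, cfg$connectivity,
                                kind, cfg$border_saddle)
    fs <- wolf_prune(watershed_segment(hm, kind, cfg$connectivity), hm, cfgk)
    feature_attributes(fs, hm)$magnitude
  })
  top5 <- function(x) {
    if (!length(x)) return(NA_real_)
    mean(sort(x, decreasing = TRUE)[seq_len(min(5L, length(x)))])
  }
  s5v <- top5(vals[[1L]]); s5p <- top5(vals[[2L]])
  list(S_10z = s5p + s5v, S_5v = s5v, S_5p = s5p,
       fewer_than_five = length(vals[[1L]]) < 5L || length(vals[[2L]]) < 5L)
}

#' Classify map locations as hill, dale or neither by height thresholds
#'
#' @param hm a [heightmap] (heights relative to the mean plane).
#' @param sites data.frame or matrix with columns `row`, `col` (1-based grid
#'   indices).
#' @param cfg a [site_classification_config()].
#' @return data.frame `row`, `col`, `z`, `label` (factor hill/dale/neither),
#'   with attribute `hill_fraction` = percentage of sites labeled hill.
#' @export
classify_sites <- function(hm, sites, cfg = site_classification_config()) {
  stopifnot(inherits(hm, "heightmap"),
            inherits(cfg, "site_classification_config"))
  sites <- as.data.frame(sites)
  if (!all(c("row", "col") %in% names(sites)))
    stop("`sites` must have columns row, col")
  if (!nrow(sites)) stop("empty site list")
  if (any(sites$row < 1L | sites$row > nrow(hm$z) |
          sites$col < 1L | sites$col > ncol(hm$z)))
    stop("site out of bounds")
  z <- hm$z[cbind(sites$row, sites$col)]
  label <- ifelse(z >= cfg$hill_height_min, "hill",
                  ifelse(z <= cfg$dale_height_max, "dale", "neither"))
  out <- data.frame(row = sites$row, col = sites$col, z = z,
                    label = factor(label,
                                   levels = c("hill", "dale", "neither")))
  attr(out, "hill_fraction") <- 100 * mean(label == "hill")
  out
}
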