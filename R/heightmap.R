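#' Construct a height map
#'
#' A `heightmap` is the package's central container: a rectangular grid of
#' surface heights in micrometres (rows indexed along y, columns along x),
#' with lateral sample spacings `step_x`, `step_y` (um) and a per-point
#' validity mask marking non-measured (dropout) points.
#'
#' @param z numeric matrix of heights (um). `NA` entries are treated as
#'   invalid points.
#' @param step_x,step_y lateral sample spacing in um; both must be > 0.
#' @param valid_mask optional logical matrix, same shape as `z`; defaults to
#'   `!is.na(z)`.
#' @param origin_note free-text provenance string.
#' @return An object of class `heightmap` with fields `z`, `step_x`,
#'   `step_y`, `valid_mask`, `origin_note`, `preprocessed`.
#' @examples
#' hm <- heightmap(matrix(rnorm(64), 8, 8), step_x = 5, step_y = 5)
#' missing_fraction(hm)
#' @export
heightmap <- function(z, step_x, step_y, valid_mask = NULL,
                      origin_note = "") {
  if (!is.matrix(z) || !is.numeric(z) || length(z) == 0L)
    stop("`z` must be a non-empty numeric matrix")
  if (!is.numeric(step_x) || length(step_x) != 1L || !is.finite(step_x) ||
      step_x <= 0)
    stop("`step_x` must be a single positive number (um)")
  if (!is.numeric(step_y) || length(step_y) != 1L || !is.finite(step_y) ||
      step_y <= 0)
    stop("`step_y` must be a single positive number (um)")
  if (is.null(valid_mask)) valid_mask <- !is.na(z)
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(z)))
    stop("`valid_mask` must be a logical matrix with the same shape as `z`")
  valid_mask <- valid_mask & !is.na(z)
  structure(
    list(z = z, step_x = step_x, step_y = step_y, valid_mask = valid_mask,
         origin_note = as.character(origin_note)[1L], preprocessed = FALSE),
    class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d points, step %g x %g um\n",
              nrow(x$z), ncol(x$z), x$step_x, x$step_y))
  cat(sprintf("  heights [%.6g, %.6g] um, %.2f%% invalid points%s\n",
              suppressWarnings(min(x$z[x$valid_mask])),
              suppressWarnings(max(x$z[x$valid_mask])),
              100 * missing_fraction(x),
              if (x$preprocessed) ", preprocessed" else ""))
  if (nzchar(x$origin_note)) cat("  note:", x$origin_note, "\n")
  invisible(x)
}

#' @export
plot.heightmap <- function(x, ..., main = "height map (um)") {
  # image() draws x along rows, so transpose and flip for map orientation
  z <- t(x$z[nrow(x$z):1, , drop = FALSE])
  graphics::image(
    x = seq_len(nrow(z)) * x$step_x, y = seq_len(ncol(z)) * x$step_y,
    z = z, xlab = "x (um)", ylab = "y (um)", main = main,
    col = grDevices::hcl.colors(64, "Terrain"), useRaster = TRUE, ...)
  invisible(x)
}

#' Fraction of invalid (missing) points
#' @param hm a [heightmap].
#' @return proportion in \[0, 1\].
#' @export
missing_fraction <- function(hm) {
  stopifnot(inherits(hm, "heightmap"))
  mean(!hm$valid_mask)
}

# ---- file I/O --------------------------------------------------------------

# Plain-text grid dialect ("ascii-grid"): 3 header lines then the matrix,
# whitespace-separated.
#   line 1: <nrow> <ncol>
#   line 2: <step_x> <step_y>
#   line 3: <units> <sentinel>
# Invalid points are stored as the sentinel value. "csv-matrix" is a bare
# CSV of heights; step metadata travels in a sidecar "<path>.meta" file of
# key=value lines (step_x, step_y, units, sentinel).

.default_sentinel <- -999999

.read_meta_sidecar <- function(path) {
  mp <- paste0(path, ".meta")
  if (!file.exists(mp))
    stop("configuration error: csv-matrix needs a sidecar file ", mp,
         " with step_x/step_y")
  lines <- readLines(mp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  vals
}

#' Read a height map from a text file
#'
#' @param path file path.
#' @param format `"ascii-grid"` (3-line header, whitespace-separated matrix)
#'   or `"csv-matrix"` (bare CSV plus a `<path>.meta` sidecar supplying
#'   `step_x`/`step_y`).
#' @return a [heightmap]; sentinel cells become invalid points.
#' @seealso [write_heightmap()]
#' @export
read_heightmap <- function(path, format = c("ascii-grid", "csv-matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ascii-grid") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 4L) stop("format error: truncated ascii-grid file")
    hdr1 <- scan(text = lines[1L], quiet = TRUE)
    hdr2 <- scan(text = lines[2L], quiet = TRUE)
    hdr3 <- strsplit(trimws(lines[3L]), "[[:space:]]+")[[1L]]
    if (length(hdr1) != 2L || length(hdr2) != 2L)
      stop("configuration error: ascii-grid header must give rows/cols and ",
           "step_x/step_y")
    nr <- as.integer(hdr1[1L]); nc <- as.integer(hdr1[2L])
    sentinel <- if (length(hdr3) >= 2L) as.numeric(hdr3[2L]) else
      .default_sentinel
    rows <- lapply(lines[-(1:3)][seq_len(nr)], function(l)
      scan(text = l, quiet = TRUE))
    if (any(lengths(rows) != nc))
      stop("format error: ragged rows in ", path)
    z <- do.call(rbind, rows)
    step_x <- hdr2[1L]; step_y <- hdr2[2L]
  } else {
    z <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(z) <- NULL
    if (!is.numeric(z)) stop("format error: non-numeric csv matrix")
    meta <- .read_meta_sidecar(path)
    if (is.na(meta["step_x"]) || is.na(meta["step_y"]))
      stop("configuration error: sidecar missing step_x/step_y")
    step_x <- as.numeric(meta[["step_x"]]); step_y <- as.numeric(meta[["step_y"]])
    sentinel <- if (!is.na(meta["sentinel"])) as.numeric(meta[["sentinel"]])
      else .default_sentinel
  }
  mask <- z != sentinel
  z[!mask] <- NA_real_
  heightmap(z, step_x, step_y, valid_mask = mask,
            origin_note = paste0("read from ", basename(path)))
}

#' Write a height map to a text file
#'
#' Inverse of [read_heightmap()]: `read_heightmap(write_heightmap(hm, p))`
#' reproduces the grid to the stored precision. Invalid points are written
#' as the sentinel value.
#'
#' @param hm a [heightmap].
#' @param path output file path.
#' @param format see [read_heightmap()].
#' @param sentinel numeric sentinel written at invalid points.
#' @param digits significant digits stored.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(hm, path, format = c("ascii-grid", "csv-matrix"),
                            sentinel = .default_sentinel, digits = 10L) {
  stopifnot(inherits(hm, "heightmap"))
  format <- match.arg(format)
  if (length(hm$z) == 0L) stop("empty grid")
  z <- hm$z
  z[!hm$valid_mask] <- sentinel
  fmt_row <- function(r) paste(formatC(r, digits = digits, format = "g"),
                               collapse = " ")
  if (format == "ascii-grid") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(paste(nrow(z), ncol(z)),
                 paste(format(hm$step_x), format(hm$step_y)),
                 paste("um", format(sentinel)),
                 apply(z, 1L, fmt_row)), con)
  } else {
    utils::write.table(format(z, digits = digits, trim = TRUE,
                              scientific = FALSE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines(c(paste0("step_x=", format(hm$step_x)),
                 paste0("step_y=", format(hm$step_y)),
                 "units=um",
                 paste0("sentinel=", format(sentinel))),
               paste0(path, ".meta"))
  }
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

# Fill invalid points by linear interpolation along rows (nearest valid value
# at row ends), then along columns for rows with no valid point at all, then
# the grid mean as a last resort.
.fill_missing <- function(z, mask) {
  nr <- nrow(z); nc <- ncol(z)
  for (i in seq_len(nr)) {
    good <- mask[i, ]
    if (all(good)) next
    if (any(good)) {
      if (sum(good) == 1L) {
        z[i, !good] <- z[i, good]
      } else {
        z[i, !good] <- stats::approx(which(good), z[i, good], xout = which(!good),
                                     rule = 2)$y
      }
      mask[i, ] <- TRUE
    }
  }
  if (!all(mask)) {
    for (j in seq_len(nc)) {
      good <- mask[, j]
      if (all(good) || !any(good)) next
      if (sum(good) == 1L) z[!good, j] <- z[good, j]
      else z[!good, j] <- stats::approx(which(good), z[good, j],
                                        xout = which(!good), rule = 2)$y
      mask[, j] <- TRUE
    }
  }
  if (!all(mask)) z[!mask] <- mean(z[mask])
  z
}

# Least-squares plane fit; returns coefficients c(intercept, bx, by) on the
# physical coordinates (um).
.fit_plane <- function(hm) {
  xs <- (seq_len(ncol(hm$z)) - 1) * hm$step_x
  ys <- (seq_len(nrow(hm$z)) - 1) * hm$step_y
  X <- cbind(1, rep(xs, each = nrow(hm$z)), rep(ys, times = ncol(hm$z)))
  stats::lsfit(X[, -1L], as.vector(hm$z), intercept = TRUE)$coefficients
}

#' Preprocess a height map: dropout filling and plane leveling
#'
#' Mirrors the standard profilometry workflow: scans whose missing-point
#' fraction exceeds `max_missing_fraction` are rejected outright (the
#' retention rule applied to the rock scans); remaining dropouts are filled
#' by interpolation from valid neighbours; a least-squares mean plane is
#' subtracted so the leveled surface has zero mean, the reference for all
#' areal parameters.
#'
#' @param hm a [heightmap].
#' @param max_missing_fraction maximum tolerated proportion of invalid
#'   points (default 0.10).
#' @param level subtract the least-squares plane (default `TRUE`).
#' @return a fully valid, (optionally) leveled [heightmap] with
#'   `preprocessed = TRUE`. Idempotent.
#' @export
preprocess <- function(hm, max_missing_fraction = 0.10, level = TRUE) {
  stopifnot(inherits(hm, "heightmap"))
  mf <- missing_fraction(hm)
  if (mf > max_missing_fraction)
    stop(sprintf(
      "scan rejected: %.1f%% missing points exceeds the %.0f%% retention rule",
      100 * mf, 100 * max_missing_fraction))
  z <- .fill_missing(hm$z, hm$valid_mask)
  out <- heightmap(z, hm$step_x, hm$step_y,
                   valid_mask = matrix(TRUE, nrow(z), ncol(z)),
                   origin_note = hm$origin_note)
  if (level) {
    cf <- .fit_plane(out)
    xs <- (seq_len(ncol(z)) - 1) * hm$step_x
    ys <- (seq_len(nrow(z)) - 1) * hm$step_y
    fitted <- cf[1L] + outer(ys, xs, function(y, x) cf[2L] * x + cf[3L] * y)
    out$z <- out$z - fitted
    out$z <- out$z - mean(out$z)   # guard rounding; exact zero mean
  }
  out$preprocessed <- TRUE
  out
}

# ---- mesh export -----------------------------------------------------------

#' Export a height map as a watertight triangle mesh
#'
#' Builds a printable solid: the height grid as the top surface, a flat base
#' `base_thickness_mm` below the lowest point, and closing side walls. All
#' mesh coordinates are in millimetres (`unit_scale` converts the um heights
#' and steps; default 1e-3).
#'
#' @param hm a preprocessed [heightmap].
#' @param base_thickness_mm base slab thickness in mm (> 0); bounding-box
#'   height equals (max - min height) + base.
#' @param unit_scale multiplicative conversion from um to mesh units.
#' @return object of class `mesh3t`: `vertices` (n x 3 matrix, mm) and
#'   `triangles` (m x 3 integer matrix of vertex indices, counterclockwise
#'   seen from outside).
#' @seealso [write_stl()], [mesh_is_watertight()]
#' @export
export_mesh <- function(hm, base_thickness_mm = 7, unit_scale = 1e-3) {
  stopifnot(inherits(hm, "heightmap"))
  if (!is.numeric(base_thickness_mm) || base_thickness_mm <= 0)
    stop("base thickness must be positive")
  nr <- nrow(hm$z); nc <- ncol(hm$z)
  if (nr < 2L || nc < 2L) stop("grid must be at least 2x2 to mesh")
  xs <- (seq_len(nc) - 1) * hm$step_x * unit_scale
  ys <- (seq_len(nr) - 1) * hm$step_y * unit_scale
  ztop <- hm$z * unit_scale
  zbase <- min(ztop) - base_thickness_mm
  idx <- function(i, j, layer) (layer - 1L) * nr * nc + (j - 1L) * nr + i
  verts <- unname(rbind(
    cbind(rep(xs, each = nr), rep(ys, times = nc), as.vector(ztop)),
    cbind(rep(xs, each = nr), rep(ys, times = nc), rep(zbase, nr * nc))))
  tri <- vector("list", 4L)
  i <- rep(seq_len(nr - 1L), times = nc - 1L)
  j <- rep(seq_len(nc - 1L), each = nr - 1L)
  # top: normals +z
  tri[[1L]] <- rbind(cbind(idx(i, j, 1L), idx(i, j + 1L, 1L), idx(i + 1L, j, 1L)),
                     cbind(idx(i + 1L, j, 1L), idx(i, j + 1L, 1L),
                           idx(i + 1L, j + 1L, 1L)))
  # bottom: reversed winding
  tri[[2L]] <- rbind(cbind(idx(i, j, 2L), idx(i + 1L, j, 2L), idx(i, j + 1L, 2L)),
                     cbind(idx(i + 1L, j, 2L), idx(i + 1L, j + 1L, 2L),
                           idx(i, j + 1L, 2L)))
  wall <- function(a_top, b_top) {
    # a,b consecutive boundary points following the top-surface boundary
    # orientation; wall triangles run opposite so directed edges pair up
    a_bot <- a_top + nr * nc; b_bot <- b_top + nr * nc
    rbind(cbind(b_top, a_top, a_bot), cbind(b_top, a_bot, b_bot))
  }
  e1 <- idx(1L, seq_len(nc - 1L), 1L);       e1b <- idx(1L, 2:nc, 1L)
  e2 <- idx(seq_len(nr - 1L), nc, 1L);       e2b <- idx(2:nr, nc, 1L)
  e3 <- idx(nr, rev(2:nc), 1L);              e3b <- idx(nr, rev(seq_len(nc - 1L)), 1L)
  e4 <- idx(rev(2:nr), 1L, 1L);              e4b <- idx(rev(seq_len(nr - 1L)), 1L, 1L)
  tri[[3L]] <- rbind(wall(e1, e1b), wall(e2, e2b), wall(e3, e3b), wall(e4, e4b))
  tri[[4L]] <- NULL
  mesh <- structure(list(vertices = verts,
                         triangles = do.call(rbind, tri)),
                    class = "mesh3t")
  mesh
}

#' Check that a triangle mesh is a closed orientable surface
#'
#' Every directed edge must occur exactly once (equivalently each undirected
#' edge is shared by exactly two consistently oriented triangles).
#'
#' @param mesh a `mesh3t` from [export_mesh()].
#' @return `TRUE`/`FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "mesh3t"))
  tr <- mesh$triangles
  ed <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(ed[, 1L], ed[, 2L])
  rkey <- paste(ed[, 2L], ed[, 1L])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Write a mesh as binary STL
#'
#' @param mesh a `mesh3t`.
#' @param path output path (`.stl`).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3t"))
  tr <- mesh$triangles; v <- mesh$vertices
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(formatC("perisurf binary STL", width = -80)), con)
  writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
  for (k in seq_len(nrow(tr))) {
    p1 <- v[tr[k, 1L], ]; p2 <- v[tr[k, 2L], ]; p3 <- v[tr[k, 3L], ]
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}
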