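# Independent brute-force oracles, written from the definitions with
# explicit loops; deliberately naive and separate from the package's
# vectorized code paths.

# wrap a matrix as a preprocessed height map without touching the values
hm_fixture <- function(z, step = 5) {
  hm <- heightmap(z, step, step)
  hm$preprocessed <- TRUE
  hm
}

oracle_height_params <- function(z) {
  n <- length(z)
  s <- 0
  for (v in z) s <- s + v
  mu <- s / n
  m2 <- m3 <- m4 <- sa <- 0
  zmax <- -Inf; zmin <- Inf
  for (v in z) {
    d <- v - mu
    m2 <- m2 + d^2 / n; m3 <- m3 + d^3 / n; m4 <- m4 + d^4 / n
    sa <- sa + abs(v) / n
    if (v > zmax) zmax <- v
    if (v < zmin) zmin <- v
  }
  list(S_q = sqrt(m2), S_sk = m3 / m2^1.5, S_ku = m4 / m2^2,
       S_p = zmax, S_v = -zmin, S_z = zmax - zmin, S_a = sa)
}

oracle_smr <- function(z) {
  mu <- mean(z)
  cnt <- 0
  for (v in z) if (v >= mu) cnt <- cnt + 1
  100 * cnt / length(z)
}

# material ratio at one section height
oracle_mr_at <- function(z, c) {
  cnt <- 0
  for (v in z) if (v >= c) cnt <- cnt + 1
  100 * cnt / length(z)
}

# height at material ratio p (%): type-7 quantile of the heights at
# probability 1 - p/100, written out explicitly
oracle_inverse_mr <- function(z, p) {
  zs <- sort(as.vector(z))
  n <- length(zs)
  pr <- 1 - p / 100
  h <- (n - 1) * pr
  lo <- floor(h) + 1
  hi <- min(lo + 1, n)
  zs[lo] + (h - (lo - 1)) * (zs[hi] - zs[lo])
}

oracle_functional <- function(z, p = 2.5, q = 50, mc_p = 10) {
  list(S_mc = oracle_inverse_mr(z, mc_p),
       S_xp = oracle_inverse_mr(z, p) - oracle_inverse_mr(z, q))
}

oracle_volume <- function(z, p = 10, q = 80) {
  qs <- seq(0, 100, length.out = 2001)
  zeta <- vapply(qs, function(pp) oracle_inverse_mr(z, pp), numeric(1))
  trap <- function(x, y) {
    s <- 0
    for (i in seq_len(length(x) - 1))
      s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
    s
  }
  vm <- function(pp) {
    sel <- qs <= pp
    trap(qs[sel], zeta[sel] - oracle_inverse_mr(z, pp)) / 100
  }
  vv <- function(pp) {
    sel <- qs >= pp
    trap(qs[sel], oracle_inverse_mr(z, pp) - zeta[sel]) / 100
  }
  list(V_m = vm(p), V_v = vv(p), V_mp = vm(p), V_mc = vm(q) - vm(p),
       V_vc = vv(p) - vv(q), V_vv = vv(q))
}

oracle_stratified <- function(z, window = 40) {
  starts <- seq(0, 100 - window, by = 0.25)
  best <- Inf; bk <- 1
  for (i in seq_along(starts)) {
    sl <- (oracle_inverse_mr(z, starts[i] + window) -
             oracle_inverse_mr(z, starts[i])) / window
    if (abs(sl) < best) { best <- abs(sl); bk <- i }
  }
  sl <- (oracle_inverse_mr(z, starts[bk] + window) -
           oracle_inverse_mr(z, starts[bk])) / window
  h0 <- oracle_inverse_mr(z, starts[bk]) - sl * starts[bk]
  h100 <- h0 + sl * 100
  qs <- seq(0, 100, length.out = 2001)
  zeta <- vapply(qs, function(pp) oracle_inverse_mr(z, pp), numeric(1))
  cross <- function(hh) {
    for (i in seq_along(qs)) {
      if (zeta[i] <= hh) {
        if (i == 1) return(0)
        if (zeta[i - 1] == zeta[i]) return(qs[i - 1])
        return(qs[i - 1] + (zeta[i - 1] - hh) / (zeta[i - 1] - zeta[i]) *
                 (qs[i] - qs[i - 1]))
      }
    }
    100
  }
  smr1 <- cross(h0); smr2 <- cross(h100)
  a1 <- a2 <- 0
  for (i in seq_len(length(qs) - 1)) {
    if (qs[i + 1] <= smr1)
      a1 <- a1 + (qs[i + 1] - qs[i]) *
        (max(zeta[i] - h0, 0) + max(zeta[i + 1] - h0, 0)) / 2
    if (qs[i] >= smr2)
      a2 <- a2 + (qs[i + 1] - qs[i]) *
        (max(h100 - zeta[i], 0) + max(h100 - zeta[i + 1], 0)) / 2
  }
  list(S_k = h0 - h100,
       S_pk = if (smr1 > 0) 2 * a1 / smr1 else 0,
       S_vk = if (smr2 < 100) 2 * a2 / (100 - smr2) else 0,
       S_mr1 = smr1, S_mr2 = smr2)
}

# watershed by per-cell steepest-descent walking (lexicographic keys)
oracle_watershed <- function(z, connectivity = 8) {
  nr <- nrow(z); nc <- ncol(z)
  off <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  less <- function(i1, j1, i2, j2) {
    if (z[i1, j1] != z[i2, j2]) return(z[i1, j1] < z[i2, j2])
    if (i1 != i2) return(i1 < i2)
    j1 < j2
  }
  sink_of <- function(i, j) {
    repeat {
      bi <- i; bj <- j
      for (o in off) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            less(ii, jj, bi, bj)) { bi <- ii; bj <- jj }
      }
      if (bi == i && bj == j) return(c(i, j))
      i <- bi; j <- bj
    }
  }
  sink_id <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- sink_of(i, j)
    sink_id[i, j] <- paste(s[1], s[2])
  }
  matrix(as.integer(factor(sink_id, levels = unique(as.vector(sink_id)))),
         nr, nc)
}

# naive Wolf pruning: full recomputation every merge, smallest Wolf height
# first (ties by smaller feature id), merge across the lowest saddle,
# border escape dissolves to label 0
oracle_wolf_prune <- function(labels, w, threshold, connectivity = 8,
                              border_saddle = TRUE) {
  nr <- nrow(w); nc <- ncol(w)
  off <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    ids <- setdiff(sort(unique(as.vector(labels))), 0)
    if (length(ids) == 0) break
    mins <- sapply(ids, function(l) min(w[labels == l]))
    # collect every cross-boundary pair, then resolve each feature's
    # lowest internal saddle (ties to the smallest neighbour id) and
    # lowest border escape (map border or background regions); the border
    # wins only when strictly lower
    av <- c(); bv <- c(); hv <- c()
    bor <- rep(Inf, length(ids)); names(bor) <- ids
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      a <- labels[i, j]
      if (a == 0) next
      ca <- as.character(a)
      for (o in off) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        b <- labels[ii, jj]
        if (a == b) next
        h <- max(w[i, j], w[ii, jj])
        if (b == 0) bor[ca] <- min(bor[ca], h)
        else { av <- c(av, a); bv <- c(bv, b); hv <- c(hv, h) }
      }
      if (border_saddle && (i == 1 || i == nr || j == 1 || j == nc))
        bor[ca] <- min(bor[ca], w[i, j])
    }
    lowsad <- rep(Inf, length(ids)); tgt <- rep(NA, length(ids))
    names(lowsad) <- names(tgt) <- ids
    for (k in seq_along(av)) {
      ca <- as.character(av[k])
      if (hv[k] < lowsad[ca] ||
          (hv[k] == lowsad[ca] && bv[k] < tgt[ca])) {
        lowsad[ca] <- hv[k]; tgt[ca] <- bv[k]
      }
    }
    for (ca in names(bor)) {
      if (bor[ca] < lowsad[ca]) { lowsad[ca] <- bor[ca]; tgt[ca] <- 0 }
    }
    wolf <- lowsad - mins
    cand <- which(is.finite(wolf) & wolf < threshold)
    if (!length(cand)) break
    v <- names(cand)[order(wolf[cand], as.integer(names(cand)))][1]
    labels[labels == as.integer(v)] <- tgt[[v]]
  }
  labels
}

# compare two labelings as partitions (invariant to label renumbering)
same_partition <- function(a, b) {
  fa <- as.integer(factor(as.vector(a), levels = unique(as.vector(a))))
  fb <- as.integer(factor(as.vector(b), levels = unique(as.vector(b))))
  # zero (background) must match exactly, not just as a block
  if (!identical(as.vector(a) == 0L, as.vector(b) == 0L)) return(FALSE)
  identical(tapply(fb, fa, function(x) length(unique(x))) == 1,
            tapply(fa, fb, function(x) length(unique(x))) == 1) &&
    all(tapply(fb, fa, function(x) length(unique(x))) == 1) &&
    all(tapply(fa, fb, function(x) length(unique(x))) == 1)
}

# closed-form moments of a1 + (a2 - a1) * Beta(al, be)
beta4_moments <- function(a1, a2, al, be) {
  mB <- al / (al + be)
  vB <- al * be / ((al + be)^2 * (al + be + 1))
  skB <- 2 * (be - al) * sqrt(al + be + 1) /
    ((al + be + 2) * sqrt(al * be))
  kuB <- 3 * (al + be + 1) * (2 * (al + be)^2 + al * be * (al + be - 6)) /
    (al * be * (al + be + 2) * (al + be + 3))
  list(mean = a1 + (a2 - a1) * mB, sd = (a2 - a1) * sqrt(vB),
       skewness = skB, kurtosis = kuB)
}
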