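# Independent oracles, written from first principles and kept separate from
# the package's code paths.

# Admixture-set selection, recomputed from raw coordinates: individual point
# x (K-vector), centroid coordinate matrix cents (P x K), candidate count s.
# Nearest population always kept; each of the next s - 1 nearest candidates j
# is kept iff the individual is strictly closer to centroid j than the
# nearest centroid is.
oracle_select_from_points <- function(x, cents, s) {
  P <- nrow(cents)
  d <- numeric(P)
  for (j in seq_len(P)) d[j] <- sqrt(sum((x - cents[j, ])^2))
  ord <- order(d)
  c1 <- ord[1L]
  keep <- c1
  for (j in ord[-1L][seq_len(min(s, P) - 1L)]) {
    centroid_gap <- sqrt(sum((cents[c1, ] - cents[j, ])^2))
    if (centroid_gap > d[j]) keep <- c(keep, j)
  }
  keep
}

# Full per-individual inference recomputed step by step from the kernel
# definitions (power / exponential, optional eigenvalue weighting of the
# squared coordinate differences). Returns a full-width proportion row.
oracle_infer_row <- function(x, cents, ev, scheme, alpha, s, eps = 1e-12) {
  P <- nrow(cents)
  wts <- if (scheme == "EVD") ev / sum(ev) else rep(1, ncol(cents))
  d <- numeric(P)
  for (j in seq_len(P)) d[j] <- sqrt(sum((x - cents[j, ])^2 * wts))
  cd <- matrix(0, P, P)
  for (a in seq_len(P)) for (b in seq_len(P))
    cd[a, b] <- sqrt(sum((cents[a, ] - cents[b, ])^2 * wts))
  ord <- order(d)
  c1 <- ord[1L]
  keep <- c1
  for (j in ord[-1L][seq_len(min(s, P) - 1L)])
    if (cd[c1, j] > d[j]) keep <- c(keep, j)
  row <- numeric(P)
  dk <- d[keep]
  if (any(dk < eps)) {
    row[keep[dk < eps]] <- 1 / sum(dk < eps)
  } else {
    k <- if (scheme == "ED") exp(-alpha * dk) else dk^(-alpha)
    row[keep] <- k / sum(k)
  }
  row
}

# Weir & Cockerham (1984) FST estimator ("ratio of averages") from genotype
# dosages and population assignments; diploid, biallelic.
oracle_wc_fst <- function(dosages, pops) {
  pops <- as.factor(pops)
  r <- nlevels(pops)
  num <- den <- 0
  for (snp in seq_len(ncol(dosages))) {
    g <- dosages[, snp]
    ok <- !is.na(g)
    n_i <- tapply(ok, pops, sum)
    if (any(n_i < 2)) next
    p_i <- tapply(g[ok], pops[ok], sum) / (2 * n_i)
    h_i <- tapply(g[ok] == 1, pops[ok], sum) / n_i
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Hotelling T^2 computed the long way: pooled covariance, explicit quadratic
# form, F conversion.
oracle_hotelling_f <- function(a, b) {
  na <- nrow(a); nb <- nrow(b); n <- na + nb; K <- ncol(a)
  d <- colMeans(a) - colMeans(b)
  S <- ((na - 1) * stats::cov(a) + (nb - 1) * stats::cov(b)) / (n - 2)
  t2 <- (na * nb / n) * drop(t(d) %*% solve(S) %*% d)
  t2 * (n - K - 1) / (K * (n - 2))
}
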