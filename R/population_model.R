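#' Compute reference population centroids in score space
#'
#' The centroid of a population is the unweighted per-component mean of the
#' scores of its labelled members. Populations are kept in label-file
#' (first-appearance) order.
#'
#' @param scores a score matrix (samples x K) with sample row names.
#' @param labels a [population_labels()] object (or coercible).
#' @return an object of class `"population_reference"`: list with
#'   `populations`, `centroids` (P x K), `eigenvalues` (carried from the
#'   score matrix, or `NULL`), `counts`.
#' @export
compute_centroids <- function(scores, labels) {
  labels <- as_population_labels(labels)
  s <- unclass(as.matrix(scores))
  if (is.null(rownames(s)))
    stop("score matrix must carry sample identifiers as row names")
  pops <- labels$populations
  cent <- matrix(NA_real_, nrow = length(pops), ncol = ncol(s),
                 dimnames = list(pops, colnames(s)))
  counts <- integer(length(pops))
  for (j in seq_along(pops)) {
    members <- labels$sample[labels$population == pops[j]]
    members <- members[members %in% rownames(s)]
    if (length(members) == 0L)
      stop("population '", pops[j], "' has no labelled sample in the scores")
    cent[j, ] <- colMeans(s[members, , drop = FALSE])
    counts[j] <- length(members)
  }
  structure(list(populations = pops, centroids = cent,
                 eigenvalues = attr(scores, "eigenvalues"),
                 counts = stats::setNames(counts, pops)),
            class = "population_reference")
}

#' @export
print.population_reference <- function(x, digits = 4, ...) {
  cat("Population reference: ", length(x$populations), " centroids in ",
      ncol(x$centroids), " dimensions\n", sep = "")
  print(round(x$centroids, digits))
  invisible(x)
}

# internal: P x P centroid-centroid distance matrix under the plain or
# eigenvalue-weighted metric. Deliberately computed with pop_distances(), the
# same arithmetic used for individual-to-centroid distances, so that an
# individual sitting exactly on a centroid sees bitwise-equal distances and
# the strict-inequality selection rule excludes ties deterministically.
centroid_distance_matrix <- function(ref, scheme = c("plain", "evd")) {
  scheme <- match.arg(scheme)
  P <- length(ref$populations)
  d <- matrix(0, P, P, dimnames = list(ref$populations, ref$populations))
  for (j in seq_len(P))
    d[j, ] <- pop_distances(ref$centroids[j, ], ref, scheme)
  d
}

#' Pairwise centroid distances and closeness ranks
#'
#' Euclidean distances between all population centroid pairs, plus a rank
#' table of pairs sorted by closeness. These geogenetic ranks are the basis
#' for collapsing many subpopulations into broader clusters. Ties are broken
#' by the pair's population names, lexicographically.
#'
#' @param ref a `"population_reference"`.
#' @param scheme `"plain"` (Euclidean over the K score dimensions) or
#'   `"evd"` (coordinates weighted by normalized eigenvalues).
#' @return an object of class `"centroid_distances"`: list with `matrix`
#'   (P x P, symmetric, zero diagonal) and `ranks` (data frame `pop1`,
#'   `pop2`, `distance`, `rank` over the P(P-1)/2 pairs, ascending).
#' @export
centroid_distances <- function(ref, scheme = c("plain", "evd")) {
  scheme <- match.arg(scheme)
  d <- centroid_distance_matrix(ref, scheme)
  P <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  tab <- data.frame(pop1 = ref$populations[pairs[, 1L]],
                    pop2 = ref$populations[pairs[, 2L]],
                    distance = d[pairs], stringsAsFactors = FALSE)
  ord <- order(tab$distance, tab$pop1, tab$pop2)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(matrix = d, ranks = tab), class = "centroid_distances")
}

#' @export
print.centroid_distances <- function(x, digits = 4, ...) {
  cat("Centroid distances over ", nrow(x$matrix), " populations; closest pairs:\n",
      sep = "")
  print(utils::head(transform(x$ranks, distance = round(distance, digits)), 10L))
  invisible(x)
}

#' Two-sample Hotelling's T-squared test with permutation p-value
#'
#' Tests equality of two multivariate mean vectors (e.g. two population
#' centroids in score space) using the pooled covariance. The statistic is
#' reported on the F scale, `F = T2 * (n - K - 1) / (K * (n - 2))` with
#' `n = n_a + n_b`, with a parametric p-value from `F(K, n - K - 1)` and a
#' permutation p-value from label shuffling (add-one estimator, so the
#' smallest attainable p is `1 / (1 + n_perm)`).
#'
#' @param scores_a,scores_b numeric matrices (rows = samples, columns = the K
#'   score dimensions).
#' @param n_perm number of label permutations (default 10000; 0 skips the
#'   permutation test).
#' @param seed integer seed for the permutation draw.
#' @return object of class `"hotelling_test"`: list with `statistic` (F
#'   scale), `t2`, `df1`, `df2`, `p_parametric`, `p_permutation`, `n_perm`,
#'   sample sizes.
#' @export
hotelling_t2 <- function(scores_a, scores_b, n_perm = 10000L, seed = 1L) {
  a <- as.matrix(scores_a); b <- as.matrix(scores_b)
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  if (ncol(a) != ncol(b))
    stop("the two score sets have different dimensions")
  K <- ncol(a)
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  if (n < K + 2L)
    stop("need n_a + n_b >= K + 2 (", K + 2L, "), got ", n)

  d <- colMeans(a) - colMeans(b)
  Sa <- crossprod(sweep(a, 2L, colMeans(a)))
  Sb <- crossprod(sweep(b, 2L, colMeans(b)))
  S <- (Sa + Sb) / (n - 2L)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; use fewer components (smaller K)",
         call. = FALSE))
  cc <- na * nb / n
  t2 <- cc * drop(t(d) %*% Sinv %*% d)
  f <- t2 * (n - K - 1L) / (K * (n - 2L))
  p_par <- stats::pf(f, K, n - K - 1L, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0L) {
    # exact identity: with T the total scatter and u = d' T^-1 d,
    # T2 = c (n-2) u / (1 - c u); only group-A column sums change per
    # permutation, so each draw costs one small matrix product
    X <- rbind(a, b)
    Xc <- sweep(X, 2L, colMeans(X))
    Tinv <- tryCatch(solve(crossprod(Xc)), error = function(e)
      stop("total scatter is singular; use fewer components (smaller K)",
           call. = FALSE))
    tot <- colSums(X)
    set.seed(seed)
    f_perm <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      ia <- sample.int(n, na)
      sa <- colSums(X[ia, , drop = FALSE])
      dd <- sa / na - (tot - sa) / nb
      u <- drop(t(dd) %*% Tinv %*% dd)
      t2p <- cc * (n - 2L) * u / (1 - cc * u)
      f_perm[r] <- t2p * (n - K - 1L) / (K * (n - 2L))
    }
    p_perm <- (1 + sum(f_perm >= f)) / (1 + n_perm)
  }
  structure(list(statistic = f, t2 = t2, df1 = K, df2 = n - K - 1L,
                 p_parametric = p_par, p_permutation = p_perm,
                 n_perm = n_perm, n_a = na, n_b = nb),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat("Two-sample Hotelling's T-squared test\n")
  cat(sprintf("  T2 = %.4g, F(%d, %d) = %.4g\n", x$t2, x$df1, x$df2,
              x$statistic))
  cat(sprintf("  parametric p = %.4g\n", x$p_parametric))
  if (!is.na(x$p_permutation))
    cat(sprintf("  permutation p = %.4g  (%d permutations)\n",
                x$p_permutation, x$n_perm))
  invisible(x)
}

#' Pairwise Hotelling's tests between all reference populations
#'
#' Runs [hotelling_t2()] for every pair of labelled populations, mirroring a
#' table of centroid-separation tests. P-values are reported raw.
#'
#' @param scores score matrix with sample row names.
#' @param labels a [population_labels()] object (or coercible).
#' @param K number of score dimensions to use (default: all columns).
#' @param n_perm,seed passed to [hotelling_t2()]; each pair uses a seed
#'   offset so pairs are independent but reproducible.
#' @return data frame with one row per population pair: `pop1`, `pop2`,
#'   `statistic` (F scale), `t2`, `p_parametric`, `p_permutation`.
#' @export
hotelling_pairwise <- function(scores, labels, K = NULL, n_perm = 10000L,
                               seed = 1L) {
  labels <- as_population_labels(labels)
  s <- unclass(as.matrix(scores))
  if (!is.null(K)) s <- s[, seq_len(K), drop = FALSE]
  pops <- labels$populations
  rows <- list()
  idx <- 0L
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq((i + 1L), length(pops))) {
      idx <- idx + 1L
      mi <- labels$sample[labels$population == pops[i]]
      mj <- labels$sample[labels$population == pops[j]]
      h <- hotelling_t2(s[intersect(mi, rownames(s)), , drop = FALSE],
                        s[intersect(mj, rownames(s)), , drop = FALSE],
                        n_perm = n_perm, seed = seed + idx)
      rows[[idx]] <- data.frame(pop1 = pops[i], pop2 = pops[j],
                                statistic = h$statistic, t2 = h$t2,
                                p_parametric = h$p_parametric,
                                p_permutation = h$p_permutation,
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
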