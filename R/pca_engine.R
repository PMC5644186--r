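#' Impute missing genotypes and standardize SNP columns
#'
#' Missing calls are replaced by the per-SNP mean of the observed dosages, so
#' an imputed entry becomes exactly 0 after centering. Each column is then
#' centered to mean 0 and scaled to unit sample standard deviation (divisor
#' `n - 1`, computed after imputation). SNPs with zero variance (monomorphic
#' after imputation) carry no ancestry information and are dropped.
#'
#' @param g a [genotype_matrix()] or plain dosage matrix.
#' @return a list with elements
#'   \describe{
#'     \item{std}{n x p' standardized matrix over the retained SNPs}
#'     \item{stats}{data frame with per-retained-SNP `mean`, `sd` (the values
#'       later reused to standardize projected samples) and `n_obs`}
#'     \item{kept}{identifiers of retained SNPs}
#'     \item{dropped}{identifiers of zero-variance SNPs that were removed}
#'   }
#' @export
impute_and_standardize <- function(g) {
  x <- unclass(as.matrix(g))
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples to standardize, got ", n)
  snps <- colnames(x)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(x)))

  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L))
    stop("SNP '", snps[which(n_obs == 0L)[1L]], "' has no observed genotypes")
  mu <- colMeans(x, na.rm = TRUE)
  miss <- which(is.na(x))
  if (length(miss))
    x[miss] <- mu[((miss - 1L) %/% n) + 1L]
  x <- sweep(x, 2L, mu, "-")
  # sample SD after imputation; imputed entries are exactly 0 here
  sd <- sqrt(colSums(x^2) / (n - 1L))
  keep <- sd > 0
  dropped <- snps[!keep]
  if (!any(keep)) stop("all SNPs are monomorphic; nothing to standardize")
  x <- sweep(x[, keep, drop = FALSE], 2L, sd[keep], "/")
  colnames(x) <- snps[keep]
  rownames(x) <- rownames(g)
  list(std = x,
       stats = data.frame(snp = snps[keep], mean = unname(mu[keep]),
                          sd = unname(sd[keep]), n_obs = unname(n_obs[keep]),
                          stringsAsFactors = FALSE),
       kept = snps[keep],
       dropped = dropped)
}

#' Fit P-mode PCA: eigendecomposition of the SNP correlation matrix
#'
#' The P-mode route decomposes the p' x p' correlation matrix between markers
#' (equivalently `crossprod(std) / (n - 1)` for a standardized matrix). Its
#' eigenvectors are per-SNP loadings ("SNP weights") that any cohort genotyped
#' on the same AIMs can reuse to compute scores, which is what makes the
#' weights portable across a consortium. Each loading column's sign is fixed
#' so that its largest-magnitude entry is positive.
#'
#' @param std standardized matrix from [impute_and_standardize()].
#' @param K number of components to retain (default 5).
#' @param stats optional per-SNP statistics (the `stats` element of
#'   [impute_and_standardize()]); stored for projection of new samples.
#' @return an object of class `"snp_weights"`: list with `snps`, `loadings`
#'   (p' x K, orthonormal columns), `eigenvalues` (length K, nonincreasing),
#'   `stats`, `K`, `n_train`.
#' @export
fit_pmode_pca <- function(std, K = 5L, stats = NULL) {
  std <- as.matrix(std)
  n <- nrow(std)
  p <- ncol(std)
  kmax <- min(n - 1L, p)
  if (K > kmax)
    stop("K = ", K, " exceeds the attainable maximum min(n - 1, p) = ", kmax)
  if (p > 25000L)
    warning("correlation matrix over ", p,
            " SNPs; P-mode PCA is intended for panels under ~25,000 markers")
  if (n <= p)
    warning("fewer samples (", n, ") than markers (", p,
            "); projected scores for new samples may be shrunk toward zero")
  R <- crossprod(std) / (n - 1L)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-|entry| positive per column
  for (k in seq_len(K)) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  snps <- colnames(std)
  if (is.null(snps)) snps <- paste0("snp", seq_len(p))
  rownames(L) <- snps
  colnames(L) <- paste0("PC", seq_len(K))
  if (is.null(stats))
    stats <- data.frame(snp = snps, mean = NA_real_, sd = NA_real_,
                        n_obs = n, stringsAsFactors = FALSE)
  if (!identical(stats$snp, snps))
    stop("stats rows do not match the columns of the standardized matrix")
  structure(list(snps = snps, loadings = L, eigenvalues = ev[seq_len(K)],
                 stats = stats, K = K, n_train = n),
            class = "snp_weights")
}

#' @export
print.snp_weights <- function(x, ...) {
  cat("SNP weights: ", length(x$snps), " SNPs x ", x$K,
      " components (trained on ", x$n_train, " samples)\n", sep = "")
  cat("Eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Project samples into score space using fitted SNP weights
#'
#' New samples are imputed, centered and scaled with the *training* per-SNP
#' means and standard deviations stored in the weights — never their own —
#' then multiplied by the loadings. A sample whose genotypes all sit at the
#' training means (including an entirely missing sample) therefore projects
#' to the origin.
#'
#' @param g a [genotype_matrix()] containing every SNP in `w$snps` (missing
#'   entries allowed).
#' @param w a `"snp_weights"` object from [fit_pmode_pca()].
#' @return an n x K `score_matrix`: numeric matrix with the component
#'   eigenvalues attached as attribute `"eigenvalues"`.
#' @export
project_scores <- function(g, w) {
  stopifnot(inherits(w, "snp_weights"))
  x <- unclass(as.matrix(g))
  absent <- setdiff(w$snps, colnames(x))
  if (length(absent))
    stop(length(absent), " SNP(s) required by the weights are absent from ",
         "the genotypes: ", paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ...")
  x <- x[, w$snps, drop = FALSE]
  storage.mode(x) <- "double"
  n <- nrow(x)
  miss <- which(is.na(x))
  if (length(miss))
    x[miss] <- w$stats$mean[((miss - 1L) %/% n) + 1L]
  x <- sweep(x, 2L, w$stats$mean, "-")
  x <- sweep(x, 2L, w$stats$sd, "/")
  s <- x %*% w$loadings
  rownames(s) <- rownames(g)
  structure(s, eigenvalues = w$eigenvalues,
            class = c("score_matrix", class(matrix())))
}

#' @export
print.score_matrix <- function(x, digits = 4, ...) {
  cat("Scores: ", nrow(x), " samples x ", ncol(x), " components\n", sep = "")
  print(utils::head(round(unclass(x), digits)))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Eigenvalue scree table
#'
#' Per-component eigenvalues and variance fractions (over the components
#' actually computed). Plotting these indicates how many top-ranked
#' components to keep; the customary default is 5.
#'
#' @param w a `"snp_weights"` object.
#' @return data frame with columns `component`, `eigenvalue`,
#'   `variance_fraction`; attribute `"suggested_K"` holds the default
#'   component count (5, capped at the number computed).
#' @export
scree_table <- function(w) {
  stopifnot(inherits(w, "snp_weights"))
  ev <- w$eigenvalues
  out <- data.frame(component = seq_along(ev), eigenvalue = ev,
                    variance_fraction = ev / sum(ev))
  attr(out, "suggested_K") <- min(5L, length(ev))
  out
}
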