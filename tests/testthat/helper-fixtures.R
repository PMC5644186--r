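# Small fixture builders shared across test files.

make_genotypes <- function(n = 6, p = 8, missing = 0, seed = 11) {
  set.seed(seed)
  dat <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (missing > 0) dat[sample(length(dat), missing)] <- NA
  genotype_matrix(dat,
                  samples = sprintf("FAM%d_IND%d", seq_len(n), seq_len(n)),
                  snps = sprintf("rs%03d", seq_len(p)))
}

make_reference <- function(cents, ev = NULL) {
  cents <- as.matrix(cents)
  if (is.null(rownames(cents)))
    rownames(cents) <- sprintf("POP%d", seq_len(nrow(cents)))
  structure(list(populations = rownames(cents), centroids = cents,
                 eigenvalues = ev,
                 counts = stats::setNames(rep(1L, nrow(cents)),
                                          rownames(cents))),
            class = "population_reference")
}

random_simplex_row <- function(P) {
  x <- stats::rexp(P)
  x / sum(x)
}
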