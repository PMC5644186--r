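test_that("impute_and_standardize centers, scales, imputes to exact zero", {
  g <- genotype_matrix(cbind(a = c(0, 1, 2), b = c(1, 1, 1),
                             c = c(0, NA, 2)))
  out <- impute_and_standardize(g)
  expect_identical(out$kept, c("a", "c"))
  expect_identical(out$dropped, "b")
  expect_equal(mean(out$std[, "a"]), 0, tolerance = 1e-12)
  expect_equal(sd(out$std[, "a"]), 1, tolerance = 1e-12)
  # observed mean of column c is 1; the imputed middle entry standardizes to 0
  expect_identical(out$std[2, "c"], 0)
  expect_equal(out$stats$mean[out$stats$snp == "c"], 1)

  expect_error(impute_and_standardize(genotype_matrix(matrix(0, 1, 2))),
               "at least 2")
  g2 <- genotype_matrix(cbind(a = c(0, 1), b = c(NA, NA)))
  expect_error(impute_and_standardize(g2), "'b'")
})

test_that("fit_pmode_pca solves the 2x2 perfectly correlated case", {
  std <- impute_and_standardize(
    genotype_matrix(cbind(a = c(0, 1, 2), b = c(0, 1, 2))))$std
  w <- fit_pmode_pca(std, K = 1)
  expect_equal(w$eigenvalues, 2, tolerance = 1e-12)
  expect_equal(unname(w$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("loadings are orthonormal and eigenvalues match an SVD oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    p <- sample(10:40, 1)
    std <- impute_and_standardize(
      genotype_matrix(matrix(sample(0:2, n * p, TRUE), n, p)))$std
    K <- min(5, ncol(std), n - 1)
    w <- fit_pmode_pca(std, K = K)
    expect_equal(crossprod(w$loadings), diag(K), tolerance = 1e-8,
                 ignore_attr = TRUE)
    sv <- svd(std)
    expect_equal(w$eigenvalues, sv$d[1:K]^2 / (n - 1), tolerance = 1e-8)
    # loadings match right singular vectors up to column sign
    for (k in 1:K) {
      expect_equal(abs(sum(w$loadings[, k] * sv$v[, k])), 1,
                   tolerance = 1e-8)
    }
    expect_true(all(diff(w$eigenvalues) <= 1e-10))
  }
})

test_that("eigenvalues of independent SNPs concentrate near 1 at large n", {
  set.seed(31)
  n <- 8000; p <- 40
  raw <- matrix(rbinom(n * p, 2, 0.4), n, p)
  std <- impute_and_standardize(genotype_matrix(raw))$std
  w <- fit_pmode_pca(std, K = 10)
  # null spectrum: eigenvalues within a few times sqrt(p/n) of 1
  expect_true(all(abs(w$eigenvalues - 1) < 5 * sqrt(p / n)))
})

test_that("K beyond the attainable rank errors with the maximum stated", {
  std <- impute_and_standardize(make_genotypes(n = 4, p = 10))$std
  expect_error(fit_pmode_pca(std, K = 5), "maximum min\\(n - 1, p\\) = 3")
})

test_that("projection reproduces training scores and respects training stats", {
  g <- make_genotypes(n = 30, p = 20, missing = 8, seed = 13)
  prep <- impute_and_standardize(g)
  w <- fit_pmode_pca(prep$std, K = 4, stats = prep$stats)
  s <- project_scores(g, w)
  expect_equal(unclass(s), unname(prep$std) %*% w$loadings,
               ignore_attr = TRUE, tolerance = 1e-12)

  # sample sitting at the training means projects to the origin,
  # as does an entirely missing sample
  at_mean <- matrix(w$stats$mean, nrow = 1,
                    dimnames = list("m", w$snps))
  s0 <- project_scores(structure(at_mean, class = class(g)), w)
  expect_equal(unname(unclass(s0))[1, ], rep(0, 4), tolerance = 1e-12)
  all_na <- genotype_matrix(matrix(NA_real_, 1, length(w$snps),
                                   dimnames = list("na", w$snps)))
  expect_equal(unname(unclass(project_scores(all_na, w)))[1, ], rep(0, 4),
               tolerance = 1e-12)

  g_missing_snp <- subset_to_aims(g, w$snps[-1])
  expect_error(project_scores(g_missing_snp, w), "absent")
})

test_that("dropping a monomorphic SNP does not perturb the others' scores", {
  g <- make_genotypes(n = 15, p = 10, seed = 17)
  gm <- unclass(g)
  gm <- cbind(gm, mono = 1)
  g2 <- genotype_matrix(gm)
  p1 <- impute_and_standardize(g)
  p2 <- impute_and_standardize(g2)
  expect_identical(p2$dropped, "mono")
  w1 <- fit_pmode_pca(p1$std, K = 3, stats = p1$stats)
  w2 <- fit_pmode_pca(p2$std, K = 3, stats = p2$stats)
  expect_equal(unclass(project_scores(g, w1)),
               unclass(project_scores(g2, w2)), tolerance = 1e-10)
})

test_that("scree_table fractions are normalized and report the default K", {
  w <- structure(list(snps = c("a", "b"), loadings = diag(2),
                      eigenvalues = c(4, 1),
                      stats = data.frame(snp = c("a", "b"), mean = 0, sd = 1,
                                         n_obs = 10),
                      K = 2L, n_train = 10L), class = "snp_weights")
  tab <- scree_table(w)
  expect_equal(tab$variance_fraction, c(0.8, 0.2))
  expect_equal(sum(tab$variance_fraction), 1, tolerance = 1e-12)
  expect_identical(attr(tab, "suggested_K"), 2L)

  w$eigenvalues <- 3; w$K <- 1L
  expect_equal(scree_table(w)$variance_fraction, 1)
})

test_that("SNP weights and scores survive TSV serialization", {
  g <- make_genotypes(n = 12, p = 8, missing = 2, seed = 19)
  prep <- impute_and_standardize(g)
  w <- fit_pmode_pca(prep$std, K = 3, stats = prep$stats)
  dir <- withr::local_tempdir()
  wf <- file.path(dir, "w.tsv")
  write_snp_weights(w, wf)
  w2 <- read_snp_weights(wf)
  expect_equal(w2$loadings, w$loadings, tolerance = 1e-9)
  expect_equal(w2$eigenvalues, w$eigenvalues, tolerance = 1e-9)
  expect_equal(w2$stats$mean, w$stats$mean, tolerance = 1e-9)
  s <- project_scores(g, w)
  s2 <- project_scores(g, w2)
  expect_equal(unclass(s2), unclass(s), tolerance = 1e-8)

  sf <- file.path(dir, "s.tsv")
  write_scores(s, sf)
  s3 <- read_scores(sf)
  expect_equal(unclass(s3), unclass(s), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(s3, "eigenvalues"), w$eigenvalues, tolerance = 1e-9)
})
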