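test_that("pop_distances: identity point, hand-computed EVD, equal-EV scaling", {
  ref <- make_reference(rbind(P1 = c(1, 2), P2 = c(4, 6)), ev = c(1, 1))
  d <- pop_distances(c(1, 2), ref, "plain")
  expect_equal(unname(d), c(0, 5))
  expect_equal(unname(pop_distances(c(1, 2), ref, "evd")), c(0, 5) / sqrt(2))

  # diff (3,4) with equal eigenvalues: plain 5, EVD sqrt((9+16)/2)
  expect_equal(unname(pop_distances(c(1, 2), ref, "evd"))[2],
               sqrt((9 + 16) / 2), tolerance = 1e-12)

  # equal eigenvalues make EVD = plain / sqrt(K) for every centroid
  set.seed(71)
  ref3 <- make_reference(matrix(rnorm(12), 4, 3), ev = c(2, 2, 2))
  x <- rnorm(3)
  expect_equal(pop_distances(x, ref3, "evd"),
               pop_distances(x, ref3, "plain") / sqrt(3), tolerance = 1e-12)

  expect_error(pop_distances(c(1, 2, 3), ref, "plain"), "dimensions")
})

test_that("admixture selection follows the 1-D worked geometry", {
  cents <- matrix(c(0, 10, 30), ncol = 1,
                  dimnames = list(c("P1", "P2", "P3"), NULL))
  ref <- make_reference(cents)
  cd <- centroid_distances(ref)$matrix
  sel <- function(x, s = 2) {
    d <- pop_distances(x, ref, "plain")
    select_admixture_set(d, cd, s)
  }
  # individual at 4: nearest P1 (d=4), candidate P2 at d=6 < gap 10 -> kept
  expect_identical(sel(4), c(1L, 2L))
  # at 1: candidate P2 d=9 < 10 -> kept; at 0.5: d=9.5 < 10 -> kept
  expect_identical(sel(1), c(1L, 2L))
  expect_identical(sel(0.5), c(1L, 2L))
  # at -5: candidate P2 d=15 > 10 -> excluded
  expect_identical(sel(-5), 1L)
  # individual exactly on a centroid keeps only that population (strict test)
  expect_identical(sel(10, s = 3), 2L)
})

test_that("admixture selection agrees with a brute-force oracle on random geometry", {
  set.seed(73)
  for (rep in 1:300) {
    P <- sample(2:8, 1)
    K <- sample(1:6, 1)
    cents <- matrix(rnorm(P * K), P, K,
                    dimnames = list(sprintf("P%d", 1:P), NULL))
    # mix in exact ties: occasionally place the individual on a centroid or
    # reflect a centroid to create equidistant candidates
    x <- if (rep %% 7 == 0) cents[sample(P, 1), ] else rnorm(K)
    if (rep %% 11 == 0 && P >= 3) cents[2, ] <- 2 * x - cents[1, ]
    ref <- make_reference(cents)
    cd <- centroid_distances(ref)$matrix
    s <- sample(1:P, 1)
    got <- select_admixture_set(pop_distances(x, ref, "plain"), cd, s)
    expect_identical(got, as.integer(oracle_select_from_points(x, cents, s)))
  }
})

test_that("idw_proportions matches hand-evaluated kernels", {
  expect_equal(unname(idw_proportions(c(1, 2), "PD", alpha = 2)),
               c(0.8, 0.2), tolerance = 1e-12)
  # equal distances split evenly under every scheme and rate
  for (sch in c("PD", "ED", "EVD"))
    for (al in c(0.5, 1, 2))
      expect_equal(unname(idw_proportions(c(3, 3), sch, al)), c(0.5, 0.5))
  # ED with alpha -> 0 tends to uniform (kernel constant)
  expect_equal(unname(idw_proportions(c(1, 5, 9), "ED", alpha = 1e-12)),
               rep(1 / 3, 3), tolerance = 1e-9)
  # exact hit takes all mass; two exact hits split it
  expect_equal(unname(idw_proportions(c(0, 2), "PD", 2)), c(1, 0))
  expect_equal(unname(idw_proportions(c(0, 1e-15, 3), "ED", 1)),
               c(0.5, 0.5, 0))
  # ED hand case: distances (0.5, 1.5), alpha 1 -> weights e^-0.5, e^-1.5
  w <- exp(-c(0.5, 1.5))
  expect_equal(unname(idw_proportions(c(0.5, 1.5), "ED", 1)), w / sum(w),
               tolerance = 1e-12)
  expect_error(idw_proportions(c(Inf, Inf), "PD", 2), "infinite")
  expect_error(idw_proportions(c(-1, 2), "PD", 2), "negative")
})

test_that("infer_ancestry composes the steps exactly as the oracle does", {
  set.seed(79)
  P <- 6; K <- 5
  cents <- matrix(rnorm(P * K, sd = 3), P, K,
                  dimnames = list(sprintf("P%d", 1:P), NULL))
  ev <- sort(rexp(K) + 0.2, decreasing = TRUE)
  ref <- make_reference(cents, ev = ev)
  scores <- matrix(rnorm(100 * K, sd = 3), 100, K,
                   dimnames = list(sprintf("s%03d", 1:100), NULL))
  for (scheme in c("PD", "ED", "EVD")) {
    cfg <- inference_config(scheme, s = 3)
    q <- infer_ancestry(scores, ref, cfg)
    for (i in seq_len(nrow(scores))) {
      expect_equal(unname(unclass(q)[i, ]),
                   oracle_infer_row(scores[i, ], cents, ev, scheme,
                                    cfg$alpha, cfg$s),
                   tolerance = 1e-12)
    }
  }
})

test_that("individuals at centroids get unit rows; s = 1 always does", {
  set.seed(83)
  cents <- matrix(rnorm(8), 4, 2, dimnames = list(LETTERS[1:4], NULL))
  ref <- make_reference(cents, ev = c(2, 1))
  q <- infer_ancestry(cents, ref, inference_config("PD", s = 3))
  expect_equal(unclass(q), diag(4), ignore_attr = TRUE)

  scores <- matrix(rnorm(20), 10, 2)
  q1 <- infer_ancestry(scores, ref, inference_config("ED", s = 1))
  expect_true(all(rowSums(unclass(q1) == 1) == 1))
})

test_that("Q rows are simplex rows with nearest-population dominance", {
  set.seed(89)
  for (rep in 1:40) {
    P <- sample(2:8, 1); K <- sample(2:6, 1)
    cents <- matrix(rnorm(P * K), P, K,
                    dimnames = list(sprintf("P%d", 1:P), NULL))
    ref <- make_reference(cents, ev = sort(rexp(K), decreasing = TRUE) + 0.1)
    scheme <- sample(c("PD", "ED", "EVD"), 1)
    cfg <- inference_config(scheme, s = sample(1:P, 1))
    scores <- matrix(rnorm(5 * K), 5, K)
    q <- unclass(infer_ancestry(scores, ref, cfg))
    expect_true(all(abs(rowSums(q) - 1) <= 1e-9))
    expect_true(all(q >= 0 & q <= 1))
    metric <- if (scheme == "EVD") "evd" else "plain"
    for (i in 1:5) {
      d <- pop_distances(scores[i, ], ref, metric)
      expect_identical(which.max(q[i, ]), which.min(d))
      # smaller distance within the selected set implies larger proportion
      sel <- which(q[i, ] > 0)
      if (length(sel) > 1) {
        o <- order(d[sel])
        expect_true(all(diff(q[i, sel][o]) < 0))
      }
    }
  }
})

test_that("PD/EVD proportions are scale-invariant; ED's are not", {
  set.seed(97)
  cents <- matrix(rnorm(10), 5, 2, dimnames = list(LETTERS[1:5], NULL))
  ref <- make_reference(cents, ev = c(3, 1))
  scores <- matrix(rnorm(12), 6, 2)
  base <- list(PD = infer_ancestry(scores, ref, inference_config("PD")),
               ED = infer_ancestry(scores, ref, inference_config("ED")),
               EVD = infer_ancestry(scores, ref, inference_config("EVD")))
  for (cc in c(0.1, 10)) {
    refc <- make_reference(cents * cc, ev = c(3, 1))
    expect_equal(unclass(infer_ancestry(scores * cc, refc,
                                        inference_config("PD"))),
                 unclass(base$PD), tolerance = 1e-10)
    expect_equal(unclass(infer_ancestry(scores * cc, refc,
                                        inference_config("EVD"))),
                 unclass(base$EVD), tolerance = 1e-10)
    qed <- unclass(infer_ancestry(scores * cc, refc,
                                  inference_config("ED")))
    expect_gt(max(abs(qed - unclass(base$ED))), 1e-4)
  }
})

test_that("EVD equals PD exactly when all eigenvalues are equal", {
  set.seed(101)
  cents <- matrix(rnorm(12), 4, 3, dimnames = list(LETTERS[1:4], NULL))
  scores <- matrix(rnorm(15), 5, 3)
  q_pd <- infer_ancestry(scores, make_reference(cents),
                         inference_config("PD"))
  q_evd <- infer_ancestry(scores, make_reference(cents, ev = c(7, 7, 7)),
                          inference_config("EVD"))
  expect_equal(unclass(q_evd), unclass(q_pd), tolerance = 1e-12)
})

test_that("permuting reference populations permutes Q columns identically", {
  set.seed(103)
  cents <- matrix(rnorm(10), 5, 2, dimnames = list(LETTERS[1:5], NULL))
  ref <- make_reference(cents, ev = c(2, 1))
  scores <- matrix(rnorm(8), 4, 2)
  q <- unclass(infer_ancestry(scores, ref, inference_config("PD")))
  perm <- c(3, 1, 5, 2, 4)
  refp <- make_reference(cents[perm, ], ev = c(2, 1))
  qp <- unclass(infer_ancestry(scores, refp, inference_config("PD")))
  expect_equal(qp, q[, perm], tolerance = 1e-12)
})

test_that("inference_config validates and applies scheme-specific defaults", {
  expect_equal(inference_config("PD")$alpha, 2)
  expect_equal(inference_config("EVD")$alpha, 2)
  expect_equal(inference_config("ED")$alpha, 1)
  expect_error(inference_config("PD", alpha = -1), "positive")
  expect_error(inference_config("PD", s = 0), ">= 1")
})
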