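#' Mean inferred-proportion confusion table
#'
#' Cross-tabulates true population labels against inferred ancestry
#' proportions: cell (a, b) is the mean, over samples truly in population a,
#' of the inferred proportion assigned to population b. Rows are therefore
#' means of simplex rows and sum to 1. Samples present in the Q matrix but
#' absent from the labels are summarized in a separate `"Unknown"` row,
#' which does not enter the accuracy scalar.
#'
#' @param q a [q_matrix()].
#' @param labels a [population_labels()] object (or coercible); every
#'   labelled sample must be present in `q` and every label population must
#'   be among the Q columns.
#' @return object of class `"accuracy_table"`: list with `table` (rows =
#'   true populations, in label order, plus `"Unknown"` if applicable;
#'   columns = Q populations), `counts` (per-row sample counts) and
#'   `avg_percent_correct` (macro average over labelled populations).
#' @export
proportion_confusion <- function(q, labels) {
  labels <- as_population_labels(labels)
  qm <- unclass(q)
  absent <- setdiff(labels$sample, rownames(qm))
  if (length(absent))
    stop("labelled sample '", absent[1L], "' is missing from the Q matrix")
  extra <- setdiff(labels$populations, colnames(qm))
  if (length(extra))
    stop("label population '", extra[1L], "' is not a Q matrix column")
  pops <- labels$populations
  tab <- matrix(NA_real_, nrow = length(pops), ncol = ncol(qm),
                dimnames = list(pops, colnames(qm)))
  counts <- integer(length(pops))
  for (a in seq_along(pops)) {
    members <- labels$sample[labels$population == pops[a]]
    tab[a, ] <- colMeans(qm[members, , drop = FALSE])
    counts[a] <- length(members)
  }
  names(counts) <- pops
  unlabeled <- setdiff(rownames(qm), labels$sample)
  if (length(unlabeled)) {
    tab <- rbind(tab, Unknown = colMeans(qm[unlabeled, , drop = FALSE]))
    counts <- c(counts, Unknown = length(unlabeled))
  }
  diag_vals <- tab[cbind(seq_along(pops), match(pops, colnames(qm)))]
  structure(list(table = tab, counts = counts,
                 avg_percent_correct = mean(diag_vals)),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, digits = 2, ...) {
  cat("Mean inferred proportion by true population (n per row):\n")
  out <- cbind(round(x$table, digits), n_p = x$counts)
  print(out)
  cat(sprintf("Avg%%Correct (macro over %d populations): %.2f\n",
              sum(names(x$counts) != "Unknown"), x$avg_percent_correct))
  invisible(x)
}

#' Macro-averaged correctly inferred proportion
#'
#' For each labelled individual, the "correct" proportion is the Q entry at
#' the individual's true population. These are averaged within each
#' population and the population means are then averaged with equal weight
#' (division by the number of populations p), so small populations count as
#' much as large ones:
#' `Avg%Correct = (1/p) * sum_j (1/n_j) * sum_{i in j} Q[i, j]`.
#' This macro average differs from a pooled per-sample mean whenever
#' population sizes vary.
#'
#' @inheritParams proportion_confusion
#' @return scalar in \[0, 1\].
#' @export
avg_percent_correct <- function(q, labels) {
  proportion_confusion(q, labels)$avg_percent_correct
}
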