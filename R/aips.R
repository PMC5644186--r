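#' Fit the AIPS ancestry-inference model
#'
#' One-call interface to the full workflow: standardize the genotype panel
#' (optionally restricted to an AIMs list), fit P-mode PCA to obtain portable
#' SNP weights, project all samples into score space, build centroids of the
#' labelled reference populations, and assign ancestry membership proportions
#' to every sample by inverse-distance-weighted interpolation.
#'
#' The returned object supports the usual modelling verbs: `print`,
#' `summary`, `coef` (SNP loadings), `fitted` (the Q matrix of the fitted
#' samples), `predict` (scores or proportions for new genotypes on the same
#' AIMs), `screeplot` and `plot`.
#'
#' @param genotypes a [genotype_matrix()] (or coercible dosage matrix)
#'   containing reference and, optionally, unlabelled samples.
#' @param labels a [population_labels()] object (or two-column data frame /
#'   named vector) labelling the reference samples. Samples absent from the
#'   labels are treated as of unknown ancestry and still receive a Q row.
#' @param K number of principal components (default 5).
#' @param scheme,alpha,s,zero_distance_epsilon see [inference_config()].
#' @param aims optional SNP-ID list passed to [subset_to_aims()].
#' @return an object of class `"aips"` with components `weights`
#'   (`"snp_weights"`), `scores`, `reference` (`"population_reference"`),
#'   `q` ([q_matrix()]), `config`, `labels`, `dropped_snps`.
#' @examples
#' panel <- simulate_structured_panel(n_pops = 3, n_snps = 300, n_ref = 20,
#'                                    n_test = 5, seed = 42)
#' fit <- aips(panel$genotypes, panel$labels, K = 3)
#' fit
#' head(fitted(fit))
#' avg_percent_correct(fitted(fit), panel$labels)
#' @export
aips <- function(genotypes, labels, K = 5L, scheme = c("PD", "ED", "EVD"),
                 alpha = NULL, s = 3L, zero_distance_epsilon = 1e-12,
                 aims = NULL) {
  if (!inherits(genotypes, "genotype_matrix"))
    genotypes <- genotype_matrix(genotypes)
  labels <- as_population_labels(labels)
  config <- inference_config(scheme = scheme, alpha = alpha, s = s,
                             zero_distance_epsilon = zero_distance_epsilon)
  if (!is.null(aims)) genotypes <- subset_to_aims(genotypes, aims)
  prep <- impute_and_standardize(genotypes)
  w <- fit_pmode_pca(prep$std, K = K, stats = prep$stats)
  scores <- project_scores(genotypes, w)
  ref <- compute_centroids(scores, labels)
  q <- infer_ancestry(scores, ref, config)
  structure(list(weights = w, scores = scores, reference = ref, q = q,
                 config = config, labels = labels,
                 dropped_snps = prep$dropped,
                 call = match.call()),
            class = "aips")
}

#' @export
print.aips <- function(x, ...) {
  cat("AIPS ancestry inference\n")
  cat("  ", nrow(x$scores), " samples, ", length(x$weights$snps),
      " SNPs, K = ", x$weights$K, " components\n", sep = "")
  cat("  ", length(x$reference$populations), " reference populations (",
      sum(x$reference$counts), " labelled samples)\n", sep = "")
  cat("  scheme = ", x$config$scheme, ", alpha = ", x$config$alpha,
      ", max admixtures s = ", x$config$s, "\n", sep = "")
  if (length(x$dropped_snps))
    cat("  ", length(x$dropped_snps), " monomorphic SNP(s) dropped\n", sep = "")
  invisible(x)
}

#' @export
summary.aips <- function(object, ...) {
  structure(list(fit = object,
                 scree = scree_table(object$weights),
                 cdist = centroid_distances(object$reference),
                 accuracy = proportion_confusion(object$q, object$labels)),
            class = "summary.aips")
}

#' @export
print.summary.aips <- function(x, ...) {
  print(x$fit)
  cat("\nEigenvalue scree:\n")
  print(transform(x$scree, eigenvalue = signif(eigenvalue, 4),
                  variance_fraction = signif(variance_fraction, 3)))
  cat("\nClosest centroid pairs:\n")
  print(utils::head(transform(x$cdist$ranks, distance = signif(distance, 4)), 5L))
  cat("\n")
  print(x$accuracy)
  invisible(x)
}

#' @export
coef.aips <- function(object, ...) object$weights$loadings

#' @export
fitted.aips <- function(object, ...) object$q

#' Predict scores or ancestry proportions for new samples
#'
#' Projects new genotypes (on the same AIMs panel) into the fitted score
#' space with the training SNP weights and, for `type = "proportions"`,
#' assigns ancestry memberships against the fitted reference centroids.
#'
#' @param object an `"aips"` fit.
#' @param newdata a [genotype_matrix()] with the fitted SNPs (missing calls
#'   allowed), or `NULL` for the fitted samples.
#' @param type `"proportions"` (a [q_matrix()]) or `"scores"`.
#' @param ... unused.
#' @export
predict.aips <- function(object, newdata = NULL,
                         type = c("proportions", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(if (type == "scores") object$scores else object$q)
  if (!inherits(newdata, "genotype_matrix"))
    newdata <- genotype_matrix(newdata)
  scores <- project_scores(newdata, object$weights)
  if (type == "scores") return(scores)
  infer_ancestry(scores, object$reference, object$config)
}

#' @importFrom stats screeplot
#' @export
screeplot.aips <- function(x, ...) {
  tab <- scree_table(x$weights)
  graphics::barplot(tab$eigenvalue, names.arg = tab$component,
                    xlab = "Component", ylab = "Eigenvalue",
                    main = "Eigenvalue scree", ...)
  invisible(tab)
}

#' Plot fitted score space
#'
#' Scatter of two principal-component scores with reference centroids
#' overplotted; labelled samples are coloured by population.
#'
#' @param x an `"aips"` fit.
#' @param components length-2 integer vector of score columns to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.aips <- function(x, components = c(1L, 2L), ...) {
  s <- unclass(x$scores)[, components, drop = FALSE]
  pops <- x$reference$populations
  col <- rep(1L, nrow(s))
  lab <- match(rownames(s), x$labels$sample)
  known <- !is.na(lab)
  col[known] <- 1L + match(x$labels$population[lab[known]], pops)
  graphics::plot(s, col = col, pch = ifelse(known, 19L, 1L),
                 xlab = paste0("PC", components[1L]),
                 ylab = paste0("PC", components[2L]), ...)
  cent <- x$reference$centroids[, components, drop = FALSE]
  graphics::points(cent, pch = 8L, cex = 1.5)
  graphics::text(cent, labels = pops, pos = 3L)
  invisible(x)
}
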