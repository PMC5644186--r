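#' Construct a genotype matrix
#'
#' A genotype matrix holds additive-coded dosages (0, 1, 2 copies of the
#' counted allele, or `NA` for missing calls) for `n` samples at `p` SNPs.
#' It is an ordinary numeric matrix with sample identifiers as row names and
#' SNP identifiers as column names, carrying class `"genotype_matrix"`.
#'
#' @param data numeric matrix, samples in rows, SNPs in columns; entries must
#'   be 0, 1, 2 or `NA`.
#' @param samples character vector of unique sample identifiers (defaults to
#'   `rownames(data)`).
#' @param snps character vector of unique SNP identifiers (defaults to
#'   `colnames(data)`).
#' @return a `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(rbind(a = c(0, 1), b = c(2, NA)), snps = c("rs1", "rs2"))
#' dim(g)
#' @export
genotype_matrix <- function(data, samples = rownames(data), snps = colnames(data)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(data)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(data)))
  samples <- as.character(samples)
  snps <- as.character(snps)
  if (length(samples) != nrow(data))
    stop("number of sample identifiers (", length(samples),
         ") does not match row count (", nrow(data), ")")
  if (length(snps) != ncol(data))
    stop("number of SNP identifiers (", length(snps),
         ") does not match column count (", ncol(data), ")")
  if (anyDuplicated(samples))
    stop("duplicate sample identifier: ", samples[duplicated(samples)][1L])
  if (anyDuplicated(snps))
    stop("duplicate SNP identifier: ", snps[duplicated(snps)][1L])
  bad <- !is.na(data) & !(data %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("genotype entry at sample '", samples[idx[1L]], "', SNP '",
         snps[idx[2L]], "' is ", data[idx[1L], idx[2L]],
         "; dosages must be 0, 1, 2 or NA")
  }
  dimnames(data) <- list(samples, snps)
  class(data) <- c("genotype_matrix", class(matrix()))
  data
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x), " samples x ", ncol(x), " SNPs, ",
      sum(is.na(x)), " missing calls\n", sep = "")
  invisible(x)
}

#' Construct reference population labels
#'
#' Maps reference sample identifiers to population names. Population order is
#' first-appearance order and is preserved throughout (centroid tables,
#' Q-matrix columns).
#'
#' @param samples character vector of sample identifiers (unique).
#' @param populations character vector of population names, parallel to
#'   `samples`.
#' @return an object of class `"population_labels"`: a list with elements
#'   `sample`, `population` (parallel vectors) and `populations` (unique
#'   names, first-appearance order).
#' @export
population_labels <- function(samples, populations) {
  samples <- as.character(samples)
  populations <- as.character(populations)
  if (length(samples) != length(populations))
    stop("samples and populations must have equal length")
  if (anyDuplicated(samples))
    stop("duplicate labelled sample: ", samples[duplicated(samples)][1L])
  pops <- unique(populations)
  if (length(pops) < 2L)
    stop("need at least 2 populations, got ", length(pops))
  structure(list(sample = samples, population = populations,
                 populations = pops),
            class = "population_labels")
}

#' @export
print.population_labels <- function(x, ...) {
  cat("Population labels: ", length(x$sample), " samples in ",
      length(x$populations), " populations\n", sep = "")
  print(table(factor(x$population, levels = x$populations)))
  invisible(x)
}

#' Construct an ancestry proportion (Q) matrix
#'
#' Rows are samples, columns reference populations; each row lies on the
#' simplex (entries in \[0, 1\] summing to 1). Populations excluded from an
#' individual's admixture set carry exactly 0.
#'
#' @param proportions numeric n x P matrix.
#' @param samples,populations row/column identifiers (default taken from
#'   `dimnames`).
#' @return a `q_matrix` (numeric matrix subclass).
#' @export
q_matrix <- function(proportions, samples = rownames(proportions),
                     populations = colnames(proportions)) {
  proportions <- as.matrix(proportions)
  storage.mode(proportions) <- "double"
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(proportions)))
  if (is.null(populations))
    stop("population names are required for a Q matrix")
  if (length(samples) != nrow(proportions) ||
      length(populations) != ncol(proportions))
    stop("dimnames do not match Q matrix dimensions")
  if (any(proportions < -1e-9) || any(proportions > 1 + 1e-9))
    stop("Q entries must lie in [0, 1]")
  if (nrow(proportions) > 0L) {
    rs <- rowSums(proportions)
    if (any(abs(rs - 1) > 1e-9))
      stop("Q row for sample '", samples[which.max(abs(rs - 1))],
           "' sums to ", rs[which.max(abs(rs - 1))], ", not 1")
  }
  dimnames(proportions) <- list(as.character(samples), as.character(populations))
  class(proportions) <- c("q_matrix", class(matrix()))
  proportions
}

#' @export
print.q_matrix <- function(x, digits = 4, ...) {
  cat("Ancestry proportions: ", nrow(x), " samples x ", ncol(x),
      " populations\n", sep = "")
  y <- unclass(x)
  print(utils::head(round(y, digits)))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# internal: coerce a labels argument (population_labels, data.frame or named
# vector) to population_labels
as_population_labels <- function(labels) {
  if (inherits(labels, "population_labels")) return(labels)
  if (is.data.frame(labels) && ncol(labels) >= 2L)
    return(population_labels(labels[[1L]], labels[[2L]]))
  if (!is.null(names(labels)))
    return(population_labels(names(labels), as.character(labels)))
  stop("cannot interpret 'labels' as population labels")
}
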