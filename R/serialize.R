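# TSV serialization of fitted objects: the portable artefacts a consortium
# shares (SNP weights) and the per-cohort score files.

#' Write fitted SNP weights to TSV
#'
#' Layout: `#`-prefixed header lines carrying the eigenvalues and training
#' sample count, then one row per SNP with its training mean, standard
#' deviation and K loading columns. This file is the portable object that
#' lets another cohort genotyped on the same AIMs compute comparable scores
#' without refitting.
#'
#' @param w a `"snp_weights"` object.
#' @param path output path.
#' @param comments optional extra `#` header lines.
#' @return invisibly, `path`.
#' @export
write_snp_weights <- function(w, path, comments = NULL) {
  stopifnot(inherits(w, "snp_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste0("# eigenvalues\t",
                    paste(sprintf("%.10g", w$eigenvalues), collapse = "\t")), con)
  writeLines(paste0("# n_train\t", w$n_train), con)
  cols <- c("snp", "mean", "sd", paste0("loading_", seq_len(w$K)))
  writeLines(paste(cols, collapse = "\t"), con)
  body <- cbind(sprintf("%.10g", w$stats$mean), sprintf("%.10g", w$stats$sd),
                matrix(sprintf("%.10g", w$loadings), ncol = w$K))
  writeLines(paste(w$snps, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read SNP weights written by [write_snp_weights()]
#'
#' @param path file path.
#' @return a `"snp_weights"` object.
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  evline <- grep("^# eigenvalues\t", lines, value = TRUE)
  if (length(evline) != 1L) stop("weights file lacks an eigenvalue header")
  ev <- as.numeric(strsplit(evline, "\t")[[1L]][-1L])
  ntline <- grep("^# n_train\t", lines, value = TRUE)
  n_train <- if (length(ntline)) as.integer(strsplit(ntline, "\t")[[1L]][2L]) else NA_integer_
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  K <- sum(grepl("^loading_", header))
  body <- fields[-1L]
  snps <- vapply(body, `[`, character(1L), 1L)
  num <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(K + 2L)))
  L <- num[, 3:(K + 2L), drop = FALSE]
  dimnames(L) <- list(snps, paste0("PC", seq_len(K)))
  structure(list(snps = snps, loadings = L, eigenvalues = ev,
                 stats = data.frame(snp = snps, mean = num[, 1L],
                                    sd = num[, 2L], n_obs = n_train,
                                    stringsAsFactors = FALSE),
                 K = K, n_train = n_train),
            class = "snp_weights")
}

#' Write a score matrix to TSV
#'
#' @param scores a `score_matrix` (or any matrix with sample row names).
#' @param path output path.
#' @param comments optional `#` header lines.
#' @return invisibly, `path`.
#' @export
write_scores <- function(scores, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  ev <- attr(scores, "eigenvalues")
  if (!is.null(ev))
    writeLines(paste0("# eigenvalues\t",
                      paste(sprintf("%.10g", ev), collapse = "\t")), con)
  s <- unclass(as.matrix(scores))
  writeLines(paste(c("sample", paste0("PC", seq_len(ncol(s)))),
                   collapse = "\t"), con)
  body <- apply(s, 1L, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(paste(rownames(s), body, sep = "\t"), con)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#'
#' @param path file path.
#' @return a `score_matrix` (eigenvalues attached when present in the file).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  evline <- grep("^# eigenvalues\t", lines, value = TRUE)
  ev <- if (length(evline)) as.numeric(strsplit(evline[1L], "\t")[[1L]][-1L]) else NULL
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  K <- length(fields[[1L]]) - 1L
  body <- fields[-1L]
  s <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(K)))
  dimnames(s) <- list(vapply(body, `[`, character(1L), 1L),
                      paste0("PC", seq_len(K)))
  structure(s, eigenvalues = ev, class = c("score_matrix", class(matrix())))
}
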