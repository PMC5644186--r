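#' Read a PLINK binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (PLINK 1 binary, v1.00 SNP-major).
#' Dosages count copies of the A1 allele of the `.bim` file; the PLINK
#' missing-genotype code (binary `01`) maps to `NA`. Sample identifiers are
#' formed as `FID_IID` so they stay unique across families.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return a [genotype_matrix()].
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))

  fam <- utils::read.table(paths[3L], header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2L) stop(".fam file needs at least FID and IID columns")
  samples <- paste(fam[[1L]], fam[[2L]], sep = "_")

  bim <- utils::read.table(paths[2L], header = FALSE,
                           colClasses = "character")
  if (ncol(bim) < 2L) stop(".bim file needs at least 2 columns")
  snps <- bim[[2L]]
  if (anyDuplicated(snps))
    stop("duplicate SNP ID in .bim: ", snps[duplicated(snps)][1L])

  n <- length(samples)
  p <- length(snps)
  bpr <- ceiling(n / 4)  # bytes per SNP record

  raw <- readBin(paths[1L], what = "raw", n = 3L + bpr * p + 1L)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic bytes 6c 1b not found): ", paths[1L])
  if (raw[3L] != as.raw(0x01))
    stop(".bed is not v1.00 SNP-major (mode byte ",
         sprintf("%02x", as.integer(raw[3L])),
         "); sample-major files are not supported")
  body <- raw[-(1:3)]
  if (length(body) != bpr * p)
    stop(".bed payload has ", length(body), " bytes; expected ", bpr * p,
         " for ", n, " samples x ", p, " SNPs")

  v <- matrix(as.integer(body), nrow = bpr, ncol = p)
  # each byte packs 4 genotypes, lowest-order bit pair first
  codes <- matrix(0L, nrow = 4L * bpr, ncol = p)
  idx <- seq(1L, by = 4L, length.out = bpr)
  codes[idx, ] <- v %% 4L
  codes[idx + 1L, ] <- (v %/% 4L) %% 4L
  codes[idx + 2L, ] <- (v %/% 16L) %% 4L
  codes[idx + 3L, ] <- (v %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 01 -> missing, 10 -> het, 11 -> 0 copies
  dosage <- matrix(c(2, NA, 1, 0)[codes + 1L], nrow = n, ncol = p)
  genotype_matrix(dosage, samples = samples, snps = snps)
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]: emits a v1.00 SNP-major `.bed` plus minimal
#' `.bim`/`.fam` sidecars. Sample identifiers containing an underscore are
#' split at the first underscore into FID and IID; otherwise FID = IID.
#' Alleles are written as A1 = "A" (the counted allele), A2 = "B".
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g); p <- ncol(g)
  samples <- rownames(g); snps <- colnames(g)

  us <- regexpr("_", samples, fixed = TRUE)
  fid <- ifelse(us > 0L, substr(samples, 1L, us - 1L), samples)
  iid <- ifelse(us > 0L, substring(samples, us + 1L), samples)
  utils::write.table(
    data.frame(fid, iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  utils::write.table(
    data.frame(1L, snps, 0L, seq_len(p), "A", "B"),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  dos <- unclass(g)
  code <- matrix(3L, n, p)
  code[dos == 2] <- 0L
  code[dos == 1] <- 2L
  code[is.na(dos)] <- 1L
  bpr <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bpr, p)  # pad bits are 00
  padded[seq_len(n), ] <- code
  i1 <- seq(1L, by = 4L, length.out = bpr)
  bytes <- padded[i1, , drop = FALSE] +
    4L * padded[i1 + 1L, , drop = FALSE] +
    16L * padded[i1 + 2L, , drop = FALSE] +
    64L * padded[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read additive-coded genotypes from delimited text
#'
#' Expects a header row of SNP identifiers, then one row per sample: sample
#' identifier followed by dosages in `{0, 1, 2, NA}`, separated by tabs or
#' spaces.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_text_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1L]]
  # tolerate an optional leading corner label when the header has one more
  # token than a SNP list would need
  body <- fields[-1L]
  if (length(body) == 0L) stop("genotype file has a header but no samples: ", path)
  widths <- lengths(body)
  p <- length(header)
  if (all(widths == p) && widths[1L] > 1L) {
    # header includes a corner label for the sample-ID column
    snps <- header[-1L]
  } else if (all(widths == p + 1L)) {
    snps <- header
  } else {
    stop("row ", which(widths != widths[1L])[1L] + 1L,
         " has ", widths[which(widths != widths[1L])[1L]],
         " fields; expected a constant width matching the header")
  }
  samples <- vapply(body, `[`, character(1L), 1L)
  dat <- matrix(NA_real_, nrow = length(body), ncol = length(snps))
  for (i in seq_along(body)) {
    tok <- body[[i]][-1L]
    for (j in seq_along(tok)) {
      t <- tok[j]
      if (t == "NA" || t == "na" || t == "-9") next
      v <- suppressWarnings(as.numeric(t))
      if (is.na(v) || !(v %in% c(0, 1, 2)))
        stop("invalid genotype token '", t, "' at row ", i + 1L,
             ", column ", j + 1L, " of ", path)
      dat[i, j] <- v
    }
  }
  genotype_matrix(dat, samples = samples, snps = snps)
}

#' Restrict a genotype matrix to an AIMs panel
#'
#' Keeps only the requested ancestry informative markers, in the order of the
#' `aims` list. AIMs absent from the data are dropped with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param aims character vector of SNP identifiers.
#' @return a [genotype_matrix()] whose columns are `aims` intersected with the
#'   SNPs of `g`, in `aims` order.
#' @export
subset_to_aims <- function(g, aims) {
  aims <- as.character(aims)
  if (length(aims) == 0L) stop("empty AIMs list")
  present <- aims[aims %in% colnames(g)]
  absent <- setdiff(aims, colnames(g))
  if (length(present) == 0L)
    stop("none of the ", length(aims), " requested AIMs are present in the data")
  if (length(absent))
    warning(length(absent), " requested AIM(s) absent from the data: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ...")
  genotype_matrix(unclass(g)[, present, drop = FALSE],
                  samples = rownames(g), snps = present)
}

#' Read a sample-to-population label file
#'
#' Two-column delimited text (sample identifier, population name); `#` lines
#' are comments. A sample listed twice with the same population is
#' de-duplicated; conflicting duplicates are an error.
#'
#' @param path file path.
#' @return a [population_labels()] object.
#' @export
read_population_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty label file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("label file line ", bad[1L], " does not have 2 columns")
  samp <- vapply(fields, `[`, character(1L), 1L)
  pop <- vapply(fields, `[`, character(1L), 2L)
  dup <- duplicated(samp)
  if (any(dup)) {
    for (s in unique(samp[dup])) {
      if (length(unique(pop[samp == s])) > 1L)
        stop("sample '", s, "' is labelled with conflicting populations")
    }
    samp <- samp[!dup]
    pop <- pop[!dup]
  }
  population_labels(samp, pop)
}

#' Write an ancestry proportion matrix to delimited text
#'
#' ADMIXTURE-style `.Q` layout with a header: one row per sample holding the
#' sample identifier followed by one proportion per reference population.
#' Proportions are printed with 12 significant digits so that re-read rows
#' still satisfy the simplex invariant.
#'
#' @param q a [q_matrix()].
#' @param path output path.
#' @param comments optional character vector written first as `#` lines.
#' @return invisibly, `path`.
#' @export
write_q_matrix <- function(q, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("sample", colnames(q)), collapse = "\t"), con)
  if (nrow(q) > 0L) {
    body <- apply(unclass(q), 1L, function(r)
      paste(sprintf("%.12g", r), collapse = "\t"))
    writeLines(paste(rownames(q), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an ancestry proportion matrix written by [write_q_matrix()]
#'
#' @param path file path.
#' @return a [q_matrix()].
#' @export
read_q_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty Q file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pops <- fields[[1L]][-1L]
  body <- fields[-1L]
  m <- matrix(0, nrow = length(body), ncol = length(pops))
  for (i in seq_along(body)) m[i, ] <- as.numeric(body[[i]][-1L])
  q_matrix(m, samples = vapply(body, `[`, character(1L), 1L),
           populations = pops)
}
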