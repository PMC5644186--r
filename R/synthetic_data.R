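#' Simulate a structured genotype panel under the Balding-Nichols model
#'
#' Generates differentiated subpopulations with known ground truth, emulating
#' the modest allele-frequency divergence seen among intra-continental
#' (e.g. intra-European) populations. For each SNP an ancestral frequency is
#' drawn uniformly from `maf_range`; population `j`'s frequency is then drawn
#' from `Beta(q(1-F)/F, (1-q)(1-F)/F)`, whose variance `q(1-q)F` vanishes as
#' the divergence parameter `F` (FST) goes to 0. Unadmixed genotypes are
#' `Binomial(2, p_j)` draws; an admixed individual with mixing proportions
#' `m` draws `Binomial(2, sum_j m_j p_j)`.
#'
#' Randomness is organized in per-population substreams derived from `seed`
#' (population `j` uses `seed + 7919 * j`), so adding populations or admixed
#' profiles does not reshuffle genotypes already generated for earlier ones.
#'
#' @param n_pops number of subpopulations.
#' @param fst divergence parameter in (0, 1); scalar or per-population vector.
#' @param n_snps number of ancestry informative markers to simulate.
#' @param n_ref labelled reference samples per population.
#' @param n_test unlabelled test samples per population (same origin, no
#'   label handed to the inference).
#' @param admixed_profiles optional list of admixed groups, each a list with
#'   `mix` (mixing proportions over the `n_pops` populations, summing to 1)
#'   and `count` (number of individuals).
#' @param missing_rate fraction of genotype calls set to missing, in \[0, 1).
#' @param maf_range range of the ancestral allele frequency (subset of
#'   (0, 0.5\]).
#' @param seed integer seed (keep below 2^31).
#' @return a list of class `"aips_panel"` with elements
#'   \describe{
#'     \item{genotypes}{[genotype_matrix()] for all samples (reference, test,
#'       admixed)}
#'     \item{labels}{[population_labels()] covering the reference samples
#'       only}
#'     \item{true_q}{[q_matrix()] of ground-truth ancestry for every sample}
#'     \item{freqs}{n_pops x n_snps matrix of population allele frequencies}
#'   }
#' @export
simulate_structured_panel <- function(n_pops = 5L, fst = 0.05, n_snps = 2000L,
                                      n_ref = 50L, n_test = 20L,
                                      admixed_profiles = NULL,
                                      missing_rate = 0,
                                      maf_range = c(0.05, 0.5),
                                      seed = 1L) {
  n_pops <- as.integer(n_pops)
  if (n_pops < 2L) stop("need at least 2 populations")
  fst <- rep_len(fst, n_pops)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie strictly in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("maf_range must be (low, high) within (0, 0.5]")
  if (!is.null(admixed_profiles)) {
    for (pr in admixed_profiles) {
      if (length(pr$mix) != n_pops || abs(sum(pr$mix) - 1) > 1e-9 ||
          any(pr$mix < 0))
        stop("each admixed profile's mix must be a length-", n_pops,
             " vector on the simplex")
      if (is.null(pr$count) || pr$count < 1L)
        stop("each admixed profile needs a positive count")
    }
  }

  pop_names <- sprintf("POP%d", seq_len(n_pops))
  set.seed(seed)
  q0 <- stats::runif(n_snps, maf_range[1L], maf_range[2L])

  freqs <- matrix(NA_real_, nrow = n_pops, ncol = n_snps,
                  dimnames = list(pop_names, sprintf("rs%05d", seq_len(n_snps))))
  geno <- list(); ids <- list(); qtrue <- list()
  for (j in seq_len(n_pops)) {
    set.seed(seed + 7919L * j)
    f <- fst[j]
    freqs[j, ] <- stats::rbeta(n_snps, q0 * (1 - f) / f, (1 - q0) * (1 - f) / f)
    m <- n_ref + n_test
    g <- matrix(stats::rbinom(m * n_snps, 2L, rep(freqs[j, ], each = m)),
                nrow = m, ncol = n_snps)
    geno[[j]] <- g
    ids[[j]] <- c(sprintf("%s_R%03d", pop_names[j], seq_len(n_ref)),
                  if (n_test > 0L) sprintf("%s_T%03d", pop_names[j], seq_len(n_test)))
    unit <- matrix(0, m, n_pops); unit[, j] <- 1
    qtrue[[j]] <- unit
  }
  if (!is.null(admixed_profiles)) {
    for (a in seq_along(admixed_profiles)) {
      pr <- admixed_profiles[[a]]
      set.seed(seed + 7919L * (n_pops + a))
      fmix <- drop(pr$mix %*% freqs)
      cnt <- as.integer(pr$count)
      g <- matrix(stats::rbinom(cnt * n_snps, 2L, rep(fmix, each = cnt)),
                  nrow = cnt, ncol = n_snps)
      geno[[n_pops + a]] <- g
      ids[[n_pops + a]] <- sprintf("ADM%d_A%03d", a, seq_len(cnt))
      qtrue[[n_pops + a]] <- matrix(pr$mix, cnt, n_pops, byrow = TRUE)
    }
  }
  dat <- do.call(rbind, geno)
  storage.mode(dat) <- "double"
  all_ids <- unlist(ids)
  if (missing_rate > 0) {
    set.seed(seed + 499979L)
    dat[stats::runif(length(dat)) < missing_rate] <- NA_real_
  }
  g <- genotype_matrix(dat, samples = all_ids, snps = colnames(freqs))
  ref_ids <- unlist(lapply(seq_len(n_pops), function(j)
    ids[[j]][seq_len(n_ref)]))
  labels <- population_labels(ref_ids, rep(pop_names, each = n_ref))
  tq <- q_matrix(do.call(rbind, qtrue), samples = all_ids,
                 populations = pop_names)
  structure(list(genotypes = g, labels = labels, true_q = tq, freqs = freqs,
                 seed = seed),
            class = "aips_panel")
}

#' @export
print.aips_panel <- function(x, ...) {
  cat("Simulated panel: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " SNPs; ", length(x$labels$populations),
      " populations (", length(x$labels$sample), " labelled)\n", sep = "")
  invisible(x)
}

#' Write a simulated panel to disk as a PLINK fixture
#'
#' Emits the PLINK binary triple plus the reference label file and the
#' ground-truth Q matrix, all readable back with [read_plink()],
#' [read_population_labels()] and [read_q_matrix()].
#'
#' @param panel an `"aips_panel"` from [simulate_structured_panel()].
#' @param dir output directory (created if needed).
#' @param basename file stem (default `"panel"`).
#' @return invisibly, a named list of the paths written.
#' @export
write_fixture <- function(panel, dir, basename = "panel") {
  stopifnot(inherits(panel, "aips_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, basename)
  write_plink(panel$genotypes, prefix)
  labf <- paste0(prefix, ".labels.tsv")
  writeLines(c("# sample\tpopulation",
               paste(panel$labels$sample, panel$labels$population, sep = "\t")),
             labf)
  qf <- paste0(prefix, ".true_q.tsv")
  write_q_matrix(panel$true_q, qf,
                 comments = "ground-truth ancestry proportions")
  invisible(list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
                 fam = paste0(prefix, ".fam"), labels = labf, true_q = qf))
}
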