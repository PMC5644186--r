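#' Inference configuration
#'
#' Bundles the tunable parameters of the inverse-distance-weighted ancestry
#' assignment.
#'
#' @param scheme weighting kernel: `"PD"` (power-distance), `"ED"`
#'   (exponential-distance) or `"EVD"` (power kernel on eigenvalue-weighted
#'   distances).
#' @param alpha positive decay rate. Default 2 for the power kernels
#'   (PD, EVD — the classical inverse-square IDW) and 1 for ED.
#' @param s maximum admixture count: the candidate set size examined by the
#'   selection rule (default 3). The selected set may be smaller.
#' @param zero_distance_epsilon distances below this (score units) are
#'   treated as exact hits: all mass is split equally among sub-epsilon
#'   populations.
#' @return a list of class `"inference_config"`.
#' @export
inference_config <- function(scheme = c("PD", "ED", "EVD"), alpha = NULL,
                             s = 3L, zero_distance_epsilon = 1e-12) {
  scheme <- match.arg(scheme)
  if (is.null(alpha)) alpha <- if (scheme == "ED") 1 else 2
  if (alpha <= 0) stop("alpha must be positive")
  s <- as.integer(s)
  if (s < 1L) stop("admixture count s must be >= 1")
  if (zero_distance_epsilon <= 0) stop("zero_distance_epsilon must be positive")
  structure(list(scheme = scheme, alpha = alpha, s = s,
                 zero_distance_epsilon = zero_distance_epsilon),
            class = "inference_config")
}

#' Distances from one individual's score vector to all centroids
#'
#' Plain scheme: Euclidean distance over the K score dimensions,
#' `sqrt(sum_k (x_ik - x_jk)^2)`. Eigenvalue-weighted scheme: each squared
#' coordinate difference is scaled by `EV_k / sum(EV)` before summing, so
#' components explaining more variance weigh more,
#' `sqrt(sum_k (x_ik - x_jk)^2 EV_k / sum(EV))`.
#'
#' @param score_row numeric K-vector.
#' @param ref a `"population_reference"`.
#' @param scheme `"plain"` or `"evd"`.
#' @return named P-vector of distances.
#' @export
pop_distances <- function(score_row, ref, scheme = c("plain", "evd")) {
  scheme <- match.arg(scheme)
  cent <- ref$centroids
  if (length(score_row) != ncol(cent))
    stop("score vector has length ", length(score_row),
         " but centroids have ", ncol(cent), " dimensions")
  diff2 <- sweep(cent, 2L, as.numeric(score_row), "-")^2
  if (scheme == "evd") {
    ev <- ref$eigenvalues
    if (is.null(ev))
      stop("eigenvalue-weighted distances need eigenvalues in the reference")
    diff2 <- sweep(diff2, 2L, ev / sum(ev), "*")
  }
  stats::setNames(sqrt(rowSums(diff2)), ref$populations)
}

#' Select an individual's admixture set
#'
#' Geometric selection rule: the nearest population `c1` is always kept.
#' Each of the next `s - 1` nearest candidate populations `j` (ordered by the
#' individual's distance, ascending) is kept only when the individual is
#' strictly closer to centroid `j` than centroid `c1` is — i.e. when
#' `dist(c1, j) > distance_j`. A candidate centroid farther from the
#' individual than from the nearest centroid would contribute spurious
#' ancestry and is excluded; in particular, an individual sitting exactly on
#' a centroid keeps only that population.
#'
#' @param distances P-vector of individual-to-centroid distances.
#' @param cdist P x P centroid-centroid distance matrix (or a
#'   `"centroid_distances"` object) in the same metric as `distances`.
#' @param s maximum admixture count.
#' @return integer indices of the selected populations, ordered by the
#'   individual's distance (nearest first). Ties in the candidate ordering are
#'   broken by lower population index.
#' @export
select_admixture_set <- function(distances, cdist, s = 3L) {
  if (inherits(cdist, "centroid_distances")) cdist <- cdist$matrix
  cdist <- as.matrix(cdist)
  P <- length(distances)
  if (!all(dim(cdist) == P))
    stop("centroid distance matrix does not match the number of populations")
  if (any(!is.finite(distances))) stop("non-finite individual distance")
  s <- min(as.integer(s), P)
  if (s < 1L) stop("admixture count s must be >= 1")
  ord <- order(distances)           # ties -> lower index (stable in order())
  c1 <- ord[1L]
  keep <- c1
  for (j in ord[seq_len(s)[-1L]]) {
    if (cdist[c1, j] > distances[j]) keep <- c(keep, j)
  }
  keep
}

#' Inverse-distance weights over a selected population set
#'
#' Converts distances to normalized membership proportions. PD and EVD use
#' the negative-power kernel `d^-alpha / sum(d^-alpha)`; ED uses the
#' negative-exponential kernel `exp(-alpha d) / sum(exp(-alpha d))`. If any
#' distance falls below `epsilon` the limit behaviour applies: all mass is
#' split equally among the sub-epsilon populations. Kernels are evaluated
#' relative to the smallest distance, which leaves the normalized weights
#' unchanged but avoids overflow/underflow.
#'
#' @param distances nonnegative distances for the selected populations.
#' @param scheme `"PD"`, `"ED"` or `"EVD"`.
#' @param alpha positive decay rate.
#' @param epsilon zero-distance threshold.
#' @return proportions summing to 1, parallel to `distances`.
#' @export
idw_proportions <- function(distances, scheme = c("PD", "ED", "EVD"),
                            alpha = 2, epsilon = 1e-12) {
  scheme <- match.arg(scheme)
  d <- as.numeric(distances)
  if (length(d) == 0L) stop("empty population set")
  if (any(d < 0)) stop("negative distance")
  if (all(is.infinite(d))) stop("all distances are infinite")
  hit <- d < epsilon
  if (any(hit)) {
    w <- as.numeric(hit)
    return(stats::setNames(w / sum(w), names(distances)))
  }
  dmin <- min(d)
  w <- if (scheme == "ED") exp(-alpha * (d - dmin)) else (d / dmin)^(-alpha)
  stats::setNames(w / sum(w), names(distances))
}

#' Infer ancestry membership proportions
#'
#' The complete distance-based assignment: for each individual, compute
#' distances to every reference centroid, select the admixture set, weight
#' the selected populations by inverse distance, and scatter the proportions
#' into a full-width simplex row (zeros for unselected populations).
#' Individuals close to a known population's centroid receive a higher
#' membership proportion which diminishes with distance.
#'
#' The EVD scheme uses eigenvalue-weighted distances consistently for both
#' the selection geometry and the weighting; PD and ED use plain Euclidean
#' distances for both.
#'
#' @param scores score matrix (samples x K) from [project_scores()].
#' @param ref a `"population_reference"` from [compute_centroids()].
#' @param config an [inference_config()].
#' @return a [q_matrix()] (samples x populations).
#' @export
infer_ancestry <- function(scores, ref, config = inference_config()) {
  stopifnot(inherits(config, "inference_config"))
  s_mat <- unclass(as.matrix(scores))
  cent <- ref$centroids
  if (ncol(s_mat) != ncol(cent))
    stop("scores have ", ncol(s_mat), " components but centroids have ",
         ncol(cent))
  metric <- if (config$scheme == "EVD") "evd" else "plain"
  cdist <- centroid_distance_matrix(ref, metric)
  P <- length(ref$populations)
  q <- matrix(0, nrow = nrow(s_mat), ncol = P,
              dimnames = list(rownames(s_mat), ref$populations))
  for (i in seq_len(nrow(s_mat))) {
    d <- pop_distances(s_mat[i, ], ref, metric)
    sel <- select_admixture_set(d, cdist, config$s)
    q[i, sel] <- idw_proportions(d[sel], config$scheme, config$alpha,
                                 config$zero_distance_epsilon)
  }
  q_matrix(q)
}
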