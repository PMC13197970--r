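#' Frequency-weighted partitioning around medoids
#'
#' k-medoids clustering of unique state sequences minimizing the weighted
#' objective `sum_i w_i d(i, medoid(i))`. Initialization is the greedy BUILD
#' step; refinement is steepest-descent SWAP, so the objective is
#' non-increasing and the algorithm terminates at a local optimum. Ties
#' (nearest medoid, equal-gain swaps) resolve to the lowest index. On small
#' instances (at most 100 unique sequences by default) a handful of seeded
#' random restarts guard against the rare SWAP local optimum, so tiny
#' problems are solved to global optimality in practice; everything is
#' deterministic given `seed`.
#'
#' @param dist A [sequence_distance_matrix()] object, or a plain symmetric
#'   distance matrix (then `weights` may be supplied).
#' @param k Number of clusters (2 to the number of unique sequences).
#' @param weights Frequency weights when `dist` is a plain matrix.
#' @param seed Seed for the restart draws.
#' @param n_restarts Number of random restarts after the BUILD start; the
#'   default uses 20 on small instances and none on large ones, where BUILD
#'   is stable and restarts are costly.
#' @return An object of class `posticu_pam`: medoid indices, per-unique-
#'   sequence assignment (labelled by medoid index), weighted objective, k,
#'   and the average silhouette width.
#' @export
weighted_pam <- function(dist, k, weights = NULL, seed = 1L, n_restarts = NULL) {
  if (inherits(dist, "posticu_distmatrix")) {
    D <- dist$D
    w <- dist$weights
  } else {
    D <- as.matrix(dist)
    w <- if (is.null(weights)) rep(1, nrow(D)) else weights
  }
  m <- nrow(D)
  if (k > m) stop("k exceeds the number of unique sequences", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (is.null(n_restarts)) n_restarts <- if (m <= 100) 20L else 0L
  if (!is.null(seed)) set.seed(seed)
  fit <- weighted_pam_cpp(D, as.numeric(w), as.integer(k),
                          n_restarts = as.integer(n_restarts))
  sil <- if (k >= 2) silhouette_width(D, fit$assignment, w) else NA_real_
  structure(list(k = k, medoids = fit$medoids, assignment = fit$assignment,
                 objective = fit$objective, weights = w,
                 avg_silhouette = sil),
            class = "posticu_pam")
}

#' Weighted average silhouette width
#'
#' Silhouette under replication semantics: a unique sequence with weight w
#' behaves exactly like w identical rows. For observation i in cluster C,
#' `a(i)` is its weighted mean distance to C (denominator `W_C - 1`, so
#' co-located duplicates count), `b(i)` the smallest weighted mean distance to
#' another cluster, and `s(i) = (b - a) / max(a, b)`. Clusters of total weight
#' one get `s(i) = 0`. The return value is the weight-averaged mean of s.
#'
#' @param D Symmetric distance matrix over unique sequences.
#' @param assignment Cluster label per unique sequence (any label type).
#' @param weights Frequency weights.
#' @return A scalar in \[-1, 1\].
#' @export
silhouette_width <- function(D, assignment, weights = NULL) {
  D <- as.matrix(D)
  m <- nrow(D)
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  cl <- as.integer(factor(assignment))
  k <- max(cl)
  if (k < 2) stop("silhouette requires at least 2 clusters", call. = FALSE)
  ind <- matrix(0, m, k)
  ind[cbind(seq_len(m), cl)] <- 1
  Wc <- as.numeric(crossprod(ind, w))
  S <- D %*% (ind * w)  # total weighted distance from i to each cluster
  own <- S[cbind(seq_len(m), cl)]
  a <- own / pmax(Wc[cl] - 1, .Machine$double.eps)
  Smean <- sweep(S, 2, Wc, "/")
  Smean[cbind(seq_len(m), cl)] <- Inf
  b <- apply(Smean, 1, min)
  s <- (b - a) / pmax(pmax(a, b), .Machine$double.eps)
  s[Wc[cl] <= 1] <- 0
  sum(w * s) / sum(w)
}

#' Select the number of clusters by average silhouette width
#'
#' Fits [weighted_pam()] for each k in `k_range` and returns the solution with
#' the largest weighted average silhouette width, together with the full
#' profile so that a different k can be chosen on interpretability grounds
#' (`override_k`).
#'
#' @param dist A [sequence_distance_matrix()] object.
#' @param k_range Candidate cluster counts.
#' @param override_k Optional manually chosen k (must lie in `k_range`).
#' @param seed Unused; the search is deterministic.
#' @return A list of class `posticu_kselect`: `best_k`, `silhouette` tibble,
#'   and all fitted `solutions`.
#' @export
select_k <- function(dist, k_range = 2:8, override_k = NULL, seed = NULL) {
  m <- nrow(dist$D)
  k_range <- k_range[k_range >= 2 & k_range <= m]
  if (!length(k_range)) stop("k_range is empty after bounds check", call. = FALSE)
  sols <- map(k_range, function(k) weighted_pam(dist, k))
  names(sols) <- paste0("k", k_range)
  sil <- map_dbl(sols, "avg_silhouette")
  best <- if (!is.null(override_k)) {
    stopifnot(override_k %in% k_range)
    override_k
  } else {
    k_range[which.max(sil)]
  }
  structure(list(best_k = best,
                 silhouette = tibble(k = k_range, avg_silhouette = sil),
                 solutions = sols),
            class = "posticu_kselect")
}

#' Expand a PAM solution to per-patient cluster labels
#'
#' @param solution A `posticu_pam` object.
#' @param dist The [sequence_distance_matrix()] the solution was fitted on.
#' @return Integer cluster labels (1..k, ordered by medoid index) per patient.
#' @export
cluster_assignments <- function(solution, dist) {
  lab <- match(solution$assignment, solution$medoids)
  lab[dist$map]
}
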