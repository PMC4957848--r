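# Clustering engines: Ward hierarchical clustering, permutation consensus
# for stable-core extraction, seeded Lloyd k-means, and multi-start k-means.

new_cluster_solution <- function(x, labels, method, seed = NA_integer_, ...) {
  k <- max(labels)
  centers <- cluster_centroids(x, labels, k)
  structure(list(labels = labels, k = k, centroids = centers,
                 tot_withinss = total_within_ss(x, labels, centers),
                 sizes = tabulate(labels, k), method = method, seed = seed,
                 ...),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("%s clustering: k = %d, n = %d, within-SS = %.3f\n",
              x$method, x$k, length(x$labels), x$tot_withinss))
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Ward hierarchical clustering of an ordinal rating matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion with
#' Euclidean distance (squared-distance merge costs), cut at `k` clusters.
#' The result is deterministic given the row order of `x`; on ordinal data
#' exact merge-cost ties are common and make the solution depend on that
#' order, which is exactly why [permutation_consensus()] reruns this engine
#' on permuted row orders.
#'
#' @param x Numeric matrix (subjects x items), a data frame, or a
#'   `cohort_table`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `cluster_solution`: `labels` (1..k, numbered by first
#'   appearance in row order), `centroids`, `tot_withinss`, `sizes`.
#' @export
#' @examples
#' ward_cluster(cbind(c(0, 0.1, 10, 10.1)), k = 2)$labels
ward_cluster <- function(x, k) {
  x <- as_score_matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  stopifnot(k >= 1L)
  labels <- if (k == n) seq_len(n) else {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    unname(stats::cutree(hc, k))
  }
  labels <- match(labels, unique(labels))  # renumber by first appearance
  new_cluster_solution(x, labels, method = "ward")
}

#' Permutation consensus of Ward solutions (stable core)
#'
#' Runs [ward_cluster()] on `n_permutations` row orders of the data (the
#' original order plus random permutations), maps every solution back to the
#' original order, and aligns each to the first with [align_labels()].  A
#' subject is *stable* when its aligned label is identical in at least
#' `min_concordant` of the solutions; if the stable fraction reaches
#' `agreement_threshold` the centroids of the stable subjects are computed as
#' initial centroids for the k-means refinement, otherwise the same centroids
#' are returned with a below-threshold diagnostic flag (and a warning).
#'
#' @inheritParams ward_cluster
#' @param n_permutations Number of row orders (default 4).
#' @param agreement_threshold Required stable fraction (default 0.70).
#' @param min_concordant Minimum number of concordant solutions per subject
#'   (default 3).
#' @param seed Integer seed for the random permutations.
#' @return An object of class `"stable_core"`: `solutions` (aligned label
#'   matrix, original order), `reference` (first solution),
#'   `stability_mask`, `stable_fraction`, `stable_labels`,
#'   `initial_centroids` (k x d), `pairwise_agreement`, `below_threshold`,
#'   `seed`.
#' @export
permutation_consensus <- function(x, k, n_permutations = 4L,
                                  agreement_threshold = 0.70,
                                  min_concordant = 3L, seed = NULL) {
  x <- as_score_matrix(x)
  n <- nrow(x)
  stopifnot(n_permutations >= 2L, min_concordant <= n_permutations,
            min_concordant >= 1L)
  seed <- resolve_seed(seed)
  set.seed(seed)
  orders <- c(list(seq_len(n)),
              replicate(n_permutations - 1L, sample.int(n), simplify = FALSE))
  aligned <- matrix(NA_integer_, n, n_permutations)
  reference <- NULL
  for (m in seq_len(n_permutations)) {
    sol <- ward_cluster(x[orders[[m]], , drop = FALSE], k)
    lab <- integer(n)
    lab[orders[[m]]] <- sol$labels
    if (m == 1L) {
      reference <- sol
      aligned[, 1L] <- lab
    } else {
      map <- align_labels(aligned[, 1L], lab)
      aligned[, m] <- unname(map[as.character(lab)])
    }
  }
  pa <- diag(1, n_permutations)
  for (i in seq_len(n_permutations - 1L))
    for (j in (i + 1L):n_permutations)
      pa[i, j] <- pa[j, i] <- mean(aligned[, i] == aligned[, j])
  ## modal aligned label and its multiplicity, per subject
  modal <- apply(aligned, 1L, function(l) {
    tab <- tabulate(l, nbins = k)
    c(which.max(tab), max(tab))
  })
  mask <- modal[2L, ] >= min_concordant
  stable_fraction <- mean(mask)
  stable_labels <- ifelse(mask, modal[1L, ], NA_integer_)
  if (any(tabulate(stable_labels[mask], nbins = k) == 0L))
    stop("invalid stable core: a cluster retained no stable subject")
  centers <- cluster_centroids(x[mask, , drop = FALSE], stable_labels[mask], k)
  below <- stable_fraction < agreement_threshold
  if (below)
    warning(sprintf(paste0("stable fraction %.2f below the %.2f threshold; ",
                           "proceeding with stable-core centroids"),
                    stable_fraction, agreement_threshold))
  structure(list(solutions = aligned, reference = reference, k = k,
                 stability_mask = mask, stable_fraction = stable_fraction,
                 stable_labels = stable_labels, initial_centroids = centers,
                 pairwise_agreement = pa, below_threshold = below,
                 seed = seed),
            class = "stable_core")
}

#' @export
print.stable_core <- function(x, ...) {
  cat(sprintf(paste0("Permutation consensus (k = %d, %d permutations): ",
                     "stable fraction %.3f%s\n"),
              x$k, ncol(x$solutions), x$stable_fraction,
              if (x$below_threshold) " [below threshold]" else ""))
  invisible(x)
}

#' Lloyd k-means from supplied initial centroids
#'
#' Standard Lloyd iterations from `centers`: assign each subject to the
#' Euclidean-nearest centroid (ties to the lowest cluster index), recompute
#' centroids as member means, and stop when the assignment is unchanged
#' (exact convergence, well-defined on integer-valued data) or after
#' `max_iter` iterations.  A cluster left empty by an assignment step is
#' re-seeded at the subject farthest from its own centroid before iterating
#' further.
#'
#' @inheritParams ward_cluster
#' @param centers k x d numeric matrix of initial centroids (finite).
#' @param max_iter Iteration cap (default 300).
#' @return A `cluster_solution` with additional elements `iterations`,
#'   `converged`, and `wss_trace` (total within-SS after each update, a
#'   non-increasing sequence).
#' @export
#' @examples
#' kmeans_refine(cbind(c(0, 1, 9, 10)), centers = cbind(c(0, 10)))$centroids
kmeans_refine <- function(x, centers, max_iter = 300L) {
  x <- as_score_matrix(x)
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (!all(is.finite(centers))) stop("non-finite initial centroid")
  k <- nrow(centers)
  n <- nrow(x)
  stopifnot(ncol(centers) == ncol(x), k <= n, k >= 1L)
  labels <- integer(0L)
  wss_trace <- numeric(0L)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    new_labels <- max.col(-dist2(x, centers), ties.method = "first")
    empty <- which(tabulate(new_labels, k) == 0L)
    if (length(empty)) {
      ## re-seed each empty centroid at the point currently farthest from
      ## its own centroid, then redo the assignment
      for (j in empty) {
        d_own <- rowSums((x - centers[new_labels, , drop = FALSE])^2)
        centers[j, ] <- x[which.max(d_own), ]
        new_labels <- max.col(-dist2(x, centers), ties.method = "first")
      }
    }
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    centers <- cluster_centroids(x, labels, k)
    wss_trace <- c(wss_trace, total_within_ss(x, labels, centers))
  }
  sol <- new_cluster_solution(x, labels, method = "seeded-kmeans",
                              iterations = iter, converged = converged,
                              wss_trace = wss_trace)
  sol
}

#' Multi-start k-means
#'
#' Runs [kmeans_refine()] from `n_starts` random initializations (each start
#' seeds the k centroids at k distinct subject rows sampled without
#' replacement) and retains the solution with the smallest total
#' within-cluster sum of squares; ties keep the earliest start.  Used as the
#' robustness benchmark for the mixed Ward/k-means solution.
#'
#' @inheritParams ward_cluster
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer seed; the start schedule is drawn up front so the
#'   first `m` starts coincide for any two runs sharing a seed.
#' @return The best `cluster_solution` (method `"multistart-kmeans"`), with
#'   `start` (index of the winning start) and `seed`.
#' @export
kmeans_multistart <- function(x, k, n_starts = 100L, seed = NULL) {
  x <- as_score_matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  stopifnot(n_starts >= 1L)
  seed <- resolve_seed(seed)
  set.seed(seed)
  starts <- replicate(n_starts, sample.int(n, k), simplify = FALSE)
  best <- NULL
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    sol <- kmeans_refine(x, x[starts[[s]], , drop = FALSE])
    if (is.null(best) || sol$tot_withinss < best$tot_withinss) {
      best <- sol
      best_start <- s
    }
  }
  best$method <- "multistart-kmeans"
  best$seed <- seed
  best$start <- best_start
  best$n_starts <- n_starts
  best
}
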