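#' Fit clinical profiles by the mixed Ward/k-means approach
#'
#' The core fitting function of the package.  The mixed approach first runs
#' Ward hierarchical clustering on `n_permutations` row orders of the data
#' and extracts the stable core of subjects classified concordantly across
#' the permuted runs ([permutation_consensus()]); the stable-core centroids
#' then seed a Lloyd k-means refinement over all subjects
#' ([kmeans_refine()]).  Hierarchical clustering provides data-driven seeds
#' while k-means repairs the greedy, order-dependent merges, combining the
#' strengths of the two families.
#'
#' @param x Numeric rating matrix (subjects x items), data frame, or
#'   `cohort_table`; the nine ordinal HoNOS65+ items in the canonical
#'   application.
#' @param k Number of profiles to fit.
#' @param n_permutations,stability_threshold,min_concordant Consensus
#'   parameters, see [permutation_consensus()].
#' @param standardize Cluster on column-standardized scores instead of raw
#'   0-4 scores (off by default: the items share one ordinal scale).
#'   Reported centroids are always raw-scale member means.
#' @param seed Integer master seed (expanded internally); `NULL` draws one
#'   from the session RNG and records it.
#' @return An object of class `"profile_fit"` (inherits
#'   `"cluster_solution"`): `labels`, `k`, `centroids` (raw-scale, rows
#'   named by [label_profiles()] when k = 4 on the nine canonical items),
#'   `tot_withinss`, `sizes`, `core` (the [permutation_consensus()] result),
#'   `seed`, `call`.
#' @seealso [predict.profile_fit()], [select_profiles()],
#'   [crossval_profiles()], [summarize_profiles()]
#' @export
#' @examples
#' coh <- simulate_cohort(n = 120, seed = 7)
#' fit <- profile_fit(coh, k = 4, seed = 7)
#' fit
#' coef(fit)
profile_fit <- function(x, k, n_permutations = 4L,
                        stability_threshold = 0.70, min_concordant = 3L,
                        standardize = FALSE, seed = NULL) {
  x <- as_score_matrix(x)
  seed <- resolve_seed(seed)
  xs <- if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    scale(x, scale = ifelse(sds > 0, sds, 1))
  } else x
  core <- tryCatch(
    permutation_consensus(xs, k, n_permutations = n_permutations,
                          agreement_threshold = stability_threshold,
                          min_concordant = min_concordant, seed = seed),
    error = function(e) {
      if (!grepl("invalid stable core", conditionMessage(e))) stop(e)
      NULL
    })
  if (is.null(core)) {
    ## a cluster retained no stable subject across the permuted runs; fall
    ## back to seeding from the single Ward solution on the original order
    warning("invalid stable core at k = ", k,
            "; seeding k-means from the plain Ward solution", call. = FALSE)
    ref <- ward_cluster(xs, k)
    core <- list(reference = ref, k = k, stability_mask = NULL,
                 stable_fraction = NA_real_, below_threshold = TRUE,
                 initial_centroids = ref$centroids, fallback = TRUE,
                 seed = seed)
    class(core) <- "stable_core"
  }
  sol <- kmeans_refine(xs, core$initial_centroids)
  centers <- cluster_centroids(x, sol$labels, k)  # raw-scale means
  if (k == 4L && ncol(x) == 9L)
    rownames(centers) <- label_profiles(centers)
  structure(list(labels = sol$labels, k = k, centroids = centers,
                 tot_withinss = total_within_ss(x, sol$labels, centers),
                 sizes = sol$sizes, core = core, kmeans = sol,
                 standardize = standardize, method = "mixed-ward-kmeans",
                 seed = seed, call = match.call()),
            class = c("profile_fit", "cluster_solution"))
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("Mixed Ward/k-means profile fit: k = %d, n = %d\n",
              x$k, length(x$labels)))
  if (isTRUE(x$core$fallback)) {
    cat("  stable core: invalid; seeded from the plain Ward solution\n")
  } else {
    cat(sprintf("  stable core: %.1f%% of subjects%s\n",
                100 * x$core$stable_fraction,
                if (x$core$below_threshold) " (below threshold)" else ""))
  }
  cat(sprintf("  total within-SS: %.2f   seed: %d\n", x$tot_withinss, x$seed))
  sizes <- stats::setNames(x$sizes, rownames(x$centroids) %||%
                             paste0("profile-", seq_len(x$k)))
  cat("  profile sizes:\n")
  print(sizes)
  invisible(x)
}

#' @export
summary.profile_fit <- function(object, ...) {
  structure(list(fit = object,
                 centroids = round(object$centroids, 2),
                 sizes = object$sizes,
                 stable_fraction = object$core$stable_fraction),
            class = "summary.profile_fit")
}

#' @export
print.summary.profile_fit <- function(x, ...) {
  print(x$fit)
  cat("  centroids (item-score units):\n")
  print(x$centroids)
  invisible(x)
}

#' @export
coef.profile_fit <- function(object, ...) object$centroids

#' Classify new subjects into fitted profiles
#'
#' Assigns each new subject to the profile with the Euclidean-nearest
#' centroid (ties to the lowest profile index) -- the same rule used for the
#' S2_a arm of the split-sample cross-validation, and the rule by which the
#' fitted solution would classify future patients.
#'
#' @param object A [profile_fit()] (or any object with a `centroids`
#'   element).
#' @param newdata Rating matrix, data frame, or `cohort_table`; omitted
#'   returns the training labels.
#' @param ... Unused.
#' @return Integer vector of profile indices.
#' @export
predict.profile_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  assign_nearest(newdata, object$centroids)
}

#' @export
fitted.profile_fit <- function(object, ...) object$labels

#' Plot fitted profile centroids
#'
#' Line plot of the per-item centroid of each profile across the clustering
#' items, the standard display of HoNOS65+ profile signatures.
#'
#' @param x A [profile_fit()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.profile_fit <- function(x, ...) {
  cn <- x$centroids
  graphics::matplot(t(cn), type = "b", pch = seq_len(nrow(cn)),
                    lty = 1, xaxt = "n", ylim = c(0, 4),
                    xlab = "item", ylab = "mean score", ...)
  graphics::axis(1, at = seq_len(ncol(cn)), labels = colnames(cn),
                 las = 2, cex.axis = 0.8)
  graphics::legend("topleft",
                   legend = rownames(cn) %||% paste0("profile-", seq_len(nrow(cn))),
                   lty = 1, pch = seq_len(nrow(cn)), col = seq_len(nrow(cn)),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate rating matrices from a fitted profile solution
#'
#' Draws new synthetic rating matrices using the fitted centroids as profile
#' means and the observed profile sizes as mixing weights, under the same
#' discretized-Gaussian ordinal noise model as [simulate_cohort()].
#'
#' @param object A [profile_fit()].
#' @param nsim Number of replicate matrices.
#' @param seed Optional integer seed.
#' @param noise_sd Latent noise standard deviation (default 1).
#' @param ... Unused.
#' @return A list of `nsim` integer score matrices.
#' @export
simulate.profile_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = 1, ...) {
  set.seed(resolve_seed(seed))
  n <- length(object$labels)
  centers <- pmin(4, pmax(0, object$centroids))
  prop <- object$sizes / n
  lapply(seq_len(nsim), function(i) {
    p <- sample.int(object$k, n, replace = TRUE, prob = prop)
    latent <- centers[p, , drop = FALSE] +
      matrix(stats::rnorm(n * ncol(centers), sd = noise_sd), n, ncol(centers))
    matrix(pmin(4L, pmax(0L, as.integer(round(latent)))), n, ncol(centers),
           dimnames = list(NULL, colnames(centers)))
  })
}
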