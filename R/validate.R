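# Split-sample cross-validation, Calinski-Harabasz index, and the
# model-selection sweep over candidate cluster counts.

#' Random split of subjects into development and validation sub-samples
#'
#' @param n Number of subjects.
#' @param fractions Two positive fractions summing to 1 (default 0.6/0.4);
#'   the first part receives `floor(fractions[1] * n)` subjects, the second
#'   the remainder.
#' @param seed Integer seed.
#' @return List with integer index vectors `s1` and `s2` (a disjoint,
#'   exhaustive partition) and the `seed` used.
#' @export
#' @examples
#' lengths(split_sample(542, seed = 1)[1:2])  # 325, 217
split_sample <- function(n, fractions = c(0.6, 0.4), seed = NULL) {
  stopifnot(length(fractions) == 2L, all(fractions > 0),
            abs(sum(fractions) - 1) <= 1e-9, n >= 2L)
  seed <- resolve_seed(seed)
  set.seed(seed)
  n1 <- floor(fractions[1L] * n)
  idx <- sample.int(n)
  list(s1 = sort(idx[seq_len(n1)]), s2 = sort(idx[(n1 + 1L):n]), seed = seed)
}

#' Nearest-centroid classification
#'
#' Assigns each subject to the Euclidean-nearest centroid, ties to the
#' lowest centroid index.  Exact on integer scores, so ties are resolved
#' reproducibly.
#'
#' @param x Rating matrix, data frame, or `cohort_table`.
#' @param centers k x d numeric centroid matrix.
#' @return Integer vector of centroid indices (1..k).
#' @export
assign_nearest <- function(x, centers) {
  x <- as_score_matrix(x)
  centers <- as.matrix(centers)
  if (!nrow(centers)) stop("empty centroid set")
  stopifnot(ncol(centers) == ncol(x), all(is.finite(centers)))
  max.col(-dist2(x, centers), ties.method = "first")
}

#' Calinski-Harabasz index of a partition
#'
#' The weighted ratio of between- to within-cluster variance,
#' \eqn{CH = (B / (k - 1)) / (W / (n - k))} with
#' \eqn{B = \sum_j n_j \|c_j - \bar c\|^2} and
#' \eqn{W = \sum_i \|x_i - c_{l(i)}\|^2} (Euclidean).  Large values indicate
#' compact, well-separated partitions.
#'
#' @param x Rating matrix, data frame, or `cohort_table`.
#' @param labels Cluster labels; all clusters non-empty, `2 <= k < n`.
#' @return The CH index (dimensionless scalar).
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' calinski_harabasz(pts, c(1, 1, 2, 2))  # 400
calinski_harabasz <- function(x, labels) {
  x <- as_score_matrix(x)
  n <- nrow(x)
  labels <- match(labels, sort(unique(labels)))
  k <- max(labels)
  if (k < 2L || k >= n)
    stop("Calinski-Harabasz index undefined for k = ", k, " with n = ", n)
  centers <- cluster_centroids(x, labels, k)
  w <- total_within_ss(x, labels, centers)
  grand <- colMeans(x)
  b <- sum(tabulate(labels, k) * rowSums(sweep(centers, 2L, grand)^2))
  (b / (k - 1)) / (w / (n - k))
}

#' Split-sample cross-validation of a k-cluster solution
#'
#' The reproducibility check of the pipeline: subjects are randomly split
#' 60/40 into a development sample S1 and a validation sample S2.  The mixed
#' Ward/k-means approach is fitted on S1; S2 is then labeled twice -- S2_a
#' by nearest-centroid assignment to the S1 centroids, and S2_b by
#' independently refitting the mixed approach on S2 -- and the two labelings
#' are compared by optimally aligned Cohen's kappa.  The solution is
#' *retained* when kappa reaches `kappa_min` (default 0.61, the conventional
#' substantial-agreement floor).
#'
#' @inheritParams profile_fit
#' @param fractions Split fractions, see [split_sample()].
#' @param kappa_min Retention threshold on kappa (default 0.61).
#' @param ... Passed to [profile_fit()] (consensus parameters).
#' @return An object of class `"profile_crossval"`: `split`, `s1_fit`,
#'   `s2a_labels`, `s2b_fit`, `agreement` (a [agreement()] result),
#'   `kappa`, `retained`, `k`, `seed`.
#' @export
crossval_profiles <- function(x, k, fractions = c(0.6, 0.4),
                              kappa_min = 0.61, seed = NULL, ...) {
  x <- as_score_matrix(x)
  seed <- resolve_seed(seed)
  seeds <- seed_stream(seed, c("split", "s1", "s2b"))
  split <- split_sample(nrow(x), fractions, seed = seeds[["split"]])
  if (min(lengths(split[c("s1", "s2")])) < k)
    stop("a split part has fewer subjects than k = ", k)
  s1_fit <- profile_fit(x[split$s1, , drop = FALSE], k,
                        seed = seeds[["s1"]], ...)
  s2 <- x[split$s2, , drop = FALSE]
  s2a <- assign_nearest(s2, s1_fit$centroids)
  s2b_fit <- profile_fit(s2, k, seed = seeds[["s2b"]], ...)
  agr <- agreement(s2a, s2b_fit$labels)
  structure(list(split = split, s1_fit = s1_fit, s2a_labels = s2a,
                 s2b_fit = s2b_fit, agreement = agr, kappa = agr$kappa,
                 retained = agr$kappa >= kappa_min, kappa_min = kappa_min,
                 k = k, seed = seed),
            class = "profile_crossval")
}

#' @export
print.profile_crossval <- function(x, ...) {
  cat(sprintf(paste0("Split-sample cross-validation (k = %d): ",
                     "kappa = %.3f -> %s (threshold %.2f)\n"),
              x$k, x$kappa, if (x$retained) "retained" else "not retained",
              x$kappa_min))
  invisible(x)
}

## The codified selection rule: among cross-validated k with kappa >= kappa_min,
## pick the k maximizing kappa provided its CH index lies within ch_tolerance
## of the maximum CH over the whole range; fall back to max-CH with a
## "no reproducible solution" flag when nothing is retained.
selection_rule <- function(rows, kappa_min, ch_tolerance) {
  trace <- character(0L)
  note <- function(...) trace <<- c(trace, sprintf(...))
  ch_max <- max(rows$ch)
  ch_floor <- (1 - ch_tolerance) * ch_max
  note("max CH over k = {%s} is %.2f (at k = %d); CH band floor %.2f",
       paste(rows$k, collapse = ","), ch_max, rows$k[which.max(rows$ch)],
       ch_floor)
  retained <- rows[rows$kappa >= kappa_min, , drop = FALSE]
  flags <- character(0L)
  if (!nrow(retained)) {
    selected <- rows$k[which.max(rows$ch)]
    flags <- "no-reproducible-solution"
    note("no k reaches kappa >= %.2f: no reproducible solution; falling back to max-CH k = %d",
         kappa_min, selected)
    return(list(selected_k = selected, flags = flags, trace = trace))
  }
  note("retained (kappa >= %.2f): k = {%s}", kappa_min,
       paste(retained$k, collapse = ","))
  in_band <- retained[retained$ch >= ch_floor, , drop = FALSE]
  if (nrow(in_band)) {
    ord <- order(-in_band$kappa, -in_band$ch, in_band$k)
    selected <- in_band$k[ord[1L]]
    note("selected k = %d: maximal kappa %.3f among retained k inside the CH band",
         selected, in_band$kappa[ord[1L]])
  } else {
    ord <- order(-retained$kappa, -retained$ch, retained$k)
    selected <- retained$k[ord[1L]]
    flags <- "ch-band-violated"
    note("no retained k inside the CH band; selected max-kappa retained k = %d",
         selected)
  }
  list(selected_k = selected, flags = flags, trace = trace)
}

#' Sweep candidate cluster counts and select the best profile solution
#'
#' The full selection pipeline: for every `k` in `k_range` the mixed
#' Ward/k-means approach is fitted on the whole sample (giving the
#' Calinski-Harabasz index) and cross-validated with [crossval_profiles()]
#' (giving the reproducibility kappa).  The selection rule codifies the
#' joint CH/kappa judgment: among k with kappa at least `kappa_min`, the k
#' maximizing kappa is selected provided its CH lies within `ch_tolerance`
#' (default 15%) of the maximum CH over the range; when no k is retained the
#' max-CH k is reported with a `no-reproducible-solution` flag.  Every
#' comparison is recorded in `rule_trace`.  Finally the robustness of the
#' selected whole-sample solution is measured as its kappa against an
#' independent [kmeans_multistart()] solution at the same k.
#'
#' @inheritParams crossval_profiles
#' @param k_range Candidate cluster counts (default `3:7`).
#' @param ch_tolerance Relative CH band width (default 0.15).
#' @param n_starts Starts of the robustness multi-start k-means (default
#'   100).
#' @param seed Master seed, expanded deterministically into per-stage seeds.
#' @return An object of class `"profile_selection"`: `table` (data frame
#'   with columns `k`, `ch`, `kappa`, `retained`), `selected_k`, `flags`,
#'   `rule_trace`, `fit` (the selected whole-sample [profile_fit()]),
#'   `fits` (all whole-sample fits), `crossval` (all [crossval_profiles()]
#'   results), `multistart`, `robustness_kappa`, `seed`.
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(seed = 11)
#' sel <- select_profiles(coh, seed = 11)
#' sel$selected_k
#' }
select_profiles <- function(x, k_range = 3:7, kappa_min = 0.61,
                            ch_tolerance = 0.15, fractions = c(0.6, 0.4),
                            n_starts = 100L, seed = NULL, ...) {
  x <- as_score_matrix(x)
  stopifnot(length(k_range) >= 1L, all(k_range >= 2L))
  seed <- resolve_seed(seed)
  stages <- c(paste0("fit", k_range), paste0("cv", k_range), "multistart")
  seeds <- seed_stream(seed, stages)
  fits <- cvs <- vector("list", length(k_range))
  rows <- data.frame(k = k_range, ch = NA_real_, kappa = NA_real_,
                     retained = NA)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- profile_fit(x, k, seed = seeds[[paste0("fit", k)]], ...)
    rows$ch[i] <- calinski_harabasz(x, fits[[i]]$labels)
    cvs[[i]] <- crossval_profiles(x, k, fractions = fractions,
                                  kappa_min = kappa_min,
                                  seed = seeds[[paste0("cv", k)]], ...)
    rows$kappa[i] <- cvs[[i]]$kappa
    rows$retained[i] <- cvs[[i]]$retained
  }
  rule <- selection_rule(rows, kappa_min, ch_tolerance)
  sel_i <- match(rule$selected_k, k_range)
  ms <- kmeans_multistart(x, rule$selected_k, n_starts = n_starts,
                          seed = seeds[["multistart"]])
  robustness <- cohen_kappa(fits[[sel_i]]$labels, ms$labels)
  structure(list(table = rows, selected_k = rule$selected_k,
                 flags = rule$flags, rule_trace = rule$trace,
                 fit = fits[[sel_i]], fits = fits, crossval = cvs,
                 multistart = ms, robustness_kappa = robustness,
                 kappa_min = kappa_min, ch_tolerance = ch_tolerance,
                 seed = seed),
            class = "profile_selection")
}

#' @export
print.profile_selection <- function(x, digits = 3L, ...) {
  cat("Profile model selection\n")
  tab <- x$table
  tab$ch <- round(tab$ch, 2L)
  tab$kappa <- round(tab$kappa, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("selected k = %d%s; robustness kappa vs %d-start k-means: %.3f\n",
              x$selected_k,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else "",
              x$multistart$n_starts, x$robustness_kappa))
  invisible(x)
}

#' @export
summary.profile_selection <- function(object, ...) {
  cat(paste(object$rule_trace, collapse = "\n"), "\n")
  print(object)
  invisible(object)
}

#' Plot the model-selection sweep
#'
#' Two panels: Calinski-Harabasz index and cross-validation kappa against
#' the candidate number of clusters, with the retention threshold and the
#' selected k marked.
#'
#' @param x A [select_profiles()] result.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.profile_selection <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  with(x$table, {
    plot(k, ch, type = "b", ylab = "Calinski-Harabasz index", xlab = "k")
    graphics::abline(v = x$selected_k, lty = 3)
    plot(k, kappa, type = "b", ylab = "cross-validation kappa", xlab = "k",
         ylim = range(c(kappa, x$kappa_min)))
    graphics::abline(h = x$kappa_min, lty = 2)
    graphics::abline(v = x$selected_k, lty = 3)
  })
  invisible(x)
}
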