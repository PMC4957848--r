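# Agreement between two cluster labelings: optimal label alignment,
# percent agreement, and unweighted Cohen's kappa.  Cluster indices are
# arbitrary, so two labelings are only comparable after a one-to-one
# relabeling; the alignment used throughout is the exact maximum-weight
# injective assignment over the confusion matrix.

## Exact max-weight injective assignment of columns to rows of a weight
## matrix, by dynamic programming over row subsets (O(kb * 2^ka * ka)).
## Ties prefer a matched column over an unmatched one, then the lowest row
## index.  Returns integer vector of length ncol(w): row assigned to each
## column (NA = unmatched).
best_assignment <- function(w) {
  ka <- nrow(w); kb <- ncol(w)
  if (ka > 20L) stop("exact assignment supports at most 20 clusters")
  ns <- bitwShiftL(1L, ka)
  dp <- matrix(0, kb + 1L, ns)
  choice <- matrix(0L, kb, ns)
  for (j in seq_len(kb)) {
    for (s in seq_len(ns) - 1L) {
      best <- -Inf; pick <- 0L
      for (a in seq_len(ka)) {
        bit <- bitwShiftL(1L, a - 1L)
        if (bitwAnd(s, bit) > 0L) {
          v <- dp[j, s - bit + 1L] + w[a, j]
          if (v > best) { best <- v; pick <- a }
        }
      }
      skip <- dp[j, s + 1L]
      if (skip > best) { best <- skip; pick <- 0L }
      dp[j + 1L, s + 1L] <- best
      choice[j, s + 1L] <- pick
    }
  }
  map <- rep(NA_integer_, kb)
  s <- ns - 1L
  for (j in rev(seq_len(kb))) {
    a <- choice[j, s + 1L]
    if (a > 0L) { map[j] <- a; s <- s - bitwShiftL(1L, a - 1L) }
  }
  map
}

label_levels <- function(x) sort(unique(as.vector(x)))

## Assignment weights: matched count, with a secondary term so that ties in
## matched count are broken toward the mapping with the smallest chance
## agreement p_e.  The secondary term is scaled below the smallest possible
## primary gap (1 subject), keeping the matched count strictly dominant,
## and it depends only on the margins, so the tie-break is invariant to any
## permutation of cluster indices.
alignment_weights <- function(conf, n) {
  unclass(conf) - 0.5 * outer(rowSums(conf), colSums(conf)) / n^2
}

#' Optimal alignment of two cluster labelings
#'
#' Finds the one-to-one assignment of the labels of `labels_b` onto the
#' labels of `labels_a` that maximizes the number of co-classified subjects
#' (exact maximum-weight assignment on the confusion matrix).  When the
#' labelings use different numbers of clusters, surplus labels stay unmapped.
#'
#' @param labels_a,labels_b Cluster label vectors of equal length.
#' @return Named vector: for each label of `labels_b`, the label of
#'   `labels_a` it is mapped to (`NA` if unmapped), with attribute
#'   `matched` giving the total matched count.
#' @seealso [agreement()], [cohen_kappa()]
#' @export
#' @examples
#' align_labels(c(0, 0, 1, 1), c(1, 1, 0, 0))  # pure relabeling
align_labels <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths (", length(labels_a), " vs ",
         length(labels_b), ")")
  if (!length(labels_a)) stop("empty labelings")
  la <- label_levels(labels_a); lb <- label_levels(labels_b)
  conf <- table(factor(labels_a, la), factor(labels_b, lb))
  idx <- best_assignment(alignment_weights(conf, length(labels_a)))
  map <- stats::setNames(la[idx], lb)
  matched <- sum(conf[cbind(idx[!is.na(idx)], which(!is.na(idx)))])
  structure(map, matched = matched)
}

agreement_core <- function(labels_a, labels_b) {
  la <- label_levels(labels_a); lb <- label_levels(labels_b)
  conf <- table(A = factor(labels_a, la), B = factor(labels_b, lb))
  n <- length(labels_a)
  idx <- best_assignment(alignment_weights(conf, n))
  mapped <- which(!is.na(idx))
  p_o <- sum(conf[cbind(idx[mapped], mapped)]) / n
  p_e <- sum(rowSums(conf)[idx[mapped]] * colSums(conf)[mapped]) / n^2
  kappa <- if (p_e >= 1) {
    if (p_o >= 1) {
      warning("degenerate agreement: both labelings have a single cluster")
      1
    } else NaN
  } else (p_o - p_e) / (1 - p_e)
  list(confusion = conf, mapping = stats::setNames(la[idx], lb),
       percent_agreement = p_o, p_expected = p_e, kappa = kappa, n = n)
}

#' Agreement statistics between two cluster labelings
#'
#' Aligns the labelings with [align_labels()] and reports the confusion
#' matrix, percent agreement, and unweighted Cohen's kappa
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, where \eqn{p_o} is the aligned
#' percent agreement and \eqn{p_e} the chance agreement
#' \eqn{\sum_c p_a(c)\, p_b(c')} over mapped label pairs \eqn{(c, c')}.
#' Both statistics are invariant under permutation of cluster indices in
#' either argument.
#'
#' @inheritParams align_labels
#' @return An object of class `"label_agreement"`: `confusion`, `mapping`,
#'   `percent_agreement`, `p_expected`, `kappa`, `n`.
#' @export
#' @examples
#' agreement(c(0, 0, 1, 1), c(0, 1, 1, 1))  # p_o 0.75, kappa 0.5
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths (", length(labels_a), " vs ",
         length(labels_b), ")")
  if (!length(labels_a)) stop("empty labelings")
  structure(agreement_core(labels_a, labels_b), class = "label_agreement")
}

#' @rdname agreement
#' @export
percent_agreement <- function(labels_a, labels_b) {
  agreement(labels_a, labels_b)$percent_agreement
}

#' @rdname agreement
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  agreement(labels_a, labels_b)$kappa
}

#' @export
print.label_agreement <- function(x, digits = 3L, ...) {
  cat(sprintf("Cluster agreement over n = %d subjects\n", x$n))
  cat(sprintf("  percent agreement: %.*f   Cohen's kappa: %.*f\n",
              digits, x$percent_agreement, digits, x$kappa))
  cat("  aligned confusion matrix (rows A, columns B):\n")
  print(x$confusion)
  invisible(x)
}
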