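# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Resolve a user-supplied seed: NULL draws one from the session RNG so that
## every stochastic result carries a reportable seed in its provenance.
resolve_seed <- function(seed) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max - 1L, 1L))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  seed
}

## Expand one master seed into named per-stage seeds.  A single master seed
## determines every stochastic stage of a run (split, permutations,
## multistart, ...) so whole pipelines are pure functions of (data, config,
## seed).  The expansion does not disturb the caller's RNG stream.
seed_stream <- function(seed, stages) {
  state <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(resolve_seed(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

## Squared Euclidean distances between rows of x (n x d) and rows of
## centers (k x d).  Exact for integer-valued inputs, so nearest-centroid
## ties on ordinal data are genuine ties, broken to the lowest index by
## max.col(-d2, ties.method = "first") at the call sites.
dist2 <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d[d < 0] <- 0
  d
}

## Cluster means in label order 1..k; clusters must all be non-empty unless
## allow_empty, in which case empty rows are NA.
cluster_centroids <- function(x, labels, k) {
  g <- factor(labels, levels = seq_len(k))
  counts <- tabulate(g, nbins = k)
  cs <- rowsum(x, g, reorder = TRUE)
  out <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  out[counts > 0L, ] <- cs[counts > 0L, , drop = FALSE] / counts[counts > 0L]
  out
}

total_within_ss <- function(x, labels, centers) {
  sum((x - centers[labels, , drop = FALSE])^2)
}

## Coerce clustering input (matrix, data frame, or cohort_table) to the
## numeric score matrix used by the engines.
as_score_matrix <- function(x) {
  if (inherits(x, "cohort_table")) x <- ratings(x)
  if (is.data.frame(x)) {
    keep <- vapply(x, is.numeric, logical(1L))
    x <- as.matrix(x[keep])
  }
  storage.mode(x) <- "double"
  stopifnot(is.matrix(x), nrow(x) >= 1L, ncol(x) >= 1L, all(is.finite(x)))
  x
}
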