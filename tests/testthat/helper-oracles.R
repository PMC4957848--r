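# Independent brute-force oracles used to verify the implementation on
# small instances.  These deliberately share no code with the package
# internals.

## All injective maps from seq_len(kb) into seq_len(ka) (as list of integer
## vectors, NA = unmatched when kb > ka is not required here: callers pad).
all_injections <- function(ka, kb) {
  if (kb == 0L) return(list(integer(0L)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == kb) { out[[length(out) + 1L]] <<- prefix; return() }
    for (a in c(remaining, NA_integer_)) {
      rec(c(prefix, a),
          if (is.na(a)) remaining else setdiff(remaining, a))
      if (is.na(a)) break
    }
  }
  rec(integer(0L), seq_len(ka))
  out
}

## Brute-force optimal matched count and kappa between two labelings.
## Among all injective maps maximizing the matched count, the one with the
## smallest chance agreement p_e is reported (the package's tie-break).
brute_agreement <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  conf <- table(factor(a, la), factor(b, lb))
  n <- length(a)
  best <- -Inf; best_pe <- Inf
  for (map in all_injections(length(la), length(lb))) {
    matched <- sum(vapply(seq_along(map), function(j)
      if (is.na(map[j])) 0 else conf[map[j], j], numeric(1L)))
    mapped <- which(!is.na(map))
    p_e <- sum(rowSums(conf)[map[mapped]] * colSums(conf)[mapped]) / n^2
    if (matched > best + 1e-9 ||
        (abs(matched - best) < 1e-9 && p_e < best_pe - 1e-12)) {
      best <- matched; best_pe <- p_e
    }
  }
  p_o <- best / n
  list(matched = best, percent = p_o,
       kappa = if (best_pe < 1) (p_o - best_pe) / (1 - best_pe) else 1)
}

## Greedy Ward agglomeration via explicit merge-cost recomputation:
## cost(A, B) = |A||B| / (|A| + |B|) * ||mean(A) - mean(B)||^2, merging the
## minimum-cost pair at each step (ties: lowest pair index).
brute_ward <- function(x, k) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  cost <- function(A, B) {
    ma <- colMeans(x[A, , drop = FALSE]); mb <- colMeans(x[B, , drop = FALSE])
    length(A) * length(B) / (length(A) + length(B)) * sum((ma - mb)^2)
  }
  while (length(clusters) > k) {
    best <- Inf; pair <- NULL
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        cc <- cost(clusters[[i]], clusters[[j]])
        if (cc < best - 1e-12) { best <- cc; pair <- c(i, j) }
      }
    clusters[[pair[1L]]] <- c(clusters[[pair[1L]]], clusters[[pair[2L]]])
    clusters[[pair[2L]]] <- NULL
  }
  labels <- integer(nrow(x))
  for (j in seq_along(clusters)) labels[clusters[[j]]] <- j
  labels
}

## Direct-formula Calinski-Harabasz, written independently of the package.
brute_ch <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); ks <- sort(unique(labels)); k <- length(ks)
  grand <- colMeans(x)
  b <- 0; w <- 0
  for (g in ks) {
    block <- x[labels == g, , drop = FALSE]
    cg <- colMeans(block)
    b <- b + nrow(block) * sum((cg - grand)^2)
    w <- w + sum(sweep(block, 2L, cg)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

## All bipartitions of n points (labelings into 2 non-empty clusters).
all_bipartitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1L) - 1L)) {
    lab <- as.integer(intToBits(code))[seq_len(n)] + 1L
    out[[length(out) + 1L]] <- lab
  }
  out
}

## Exact mean of a Gaussian(mu, sd) rounded to the nearest integer and
## clipped to {0, ..., 4}.
discretized_mean <- function(mu, sd) {
  cuts <- c(-Inf, 0.5, 1.5, 2.5, 3.5, Inf)
  p <- diff(pnorm(cuts, mean = mu, sd = sd))
  sum(0:4 * p)
}

## Two labelings agree as partitions (identical up to label renaming).
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
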