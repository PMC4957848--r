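# Ward clustering, permutation consensus, Lloyd k-means, multi-start.

zero_noise_cohort <- function(n = 120, seed = 5) {
  simulate_cohort(cohort_config(noise_sd = 0), n = n, seed = seed)
}

test_that("Ward separates well-separated 1-D groups and is exact at k = n", {
  x <- cbind(c(0, 0.1, 10, 10.1))
  sol <- ward_cluster(x, 2)
  expect_true(same_partition(sol$labels, c(1, 1, 2, 2)))
  sol_n <- ward_cluster(x, 4)
  expect_equal(sol_n$tot_withinss, 0)
  expect_equal(sort(sol_n$labels), 1:4)
  expect_error(ward_cluster(x, 5), "exceeds")
})

test_that("cluster solutions respect their structural invariants", {
  set.seed(23)
  x <- matrix(sample(0:4, 60 * 4, replace = TRUE), 60, 4)
  for (k in c(2, 4, 6)) {
    sol <- ward_cluster(x, k)
    expect_setequal(unique(sol$labels), seq_len(k))
    expect_equal(sol$centroids,
                 t(sapply(seq_len(k), function(j)
                   colMeans(x[sol$labels == j, , drop = FALSE]))),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("Ward matches a brute-force greedy merge oracle on tie-free instances", {
  set.seed(29)
  for (rep in 1:25) {
    n <- sample(4:8, 1L)
    k <- sample(2:3, 1L)
    x <- matrix(rnorm(n * 3), n, 3)  # continuous: merge costs tie-free a.s.
    sol <- ward_cluster(x, k)
    expect_true(same_partition(sol$labels, brute_ward(x, k)),
                info = sprintf("rep %d (n=%d, k=%d)", rep, n, k))
  }
})

test_that("Ward is invariant to row order on tie-free instances", {
  set.seed(31)
  x <- matrix(rnorm(40 * 3), 40, 3)
  ref <- ward_cluster(x, 3)$labels
  for (rep in 1:5) {
    o <- sample.int(nrow(x))
    lab <- integer(nrow(x))
    lab[o] <- ward_cluster(x[o, ], 3)$labels
    expect_equal(percent_agreement(ref, lab), 1)
  }
})

test_that("permutation consensus on a separated cohort is fully stable", {
  coh <- zero_noise_cohort()
  core <- permutation_consensus(ratings(coh), k = 4, seed = 1)
  expect_equal(core$stable_fraction, 1.0)
  expect_false(core$below_threshold)
  expect_true(all(core$pairwise_agreement == 1))
  ## initial centroids are the rounded generating centroids
  agr <- agreement(coh$true_profile, core$stable_labels)
  expect_equal(agr$kappa, 1)
})

test_that("a tie-free dataset yields identical solutions across permutations", {
  set.seed(37)
  x <- matrix(rnorm(50 * 3), 50, 3)
  core <- permutation_consensus(x, k = 3, seed = 2)
  expect_equal(core$stable_fraction, 1.0)
})

test_that("increasing min_concordant never increases the stable fraction", {
  set.seed(41)
  x <- matrix(sample(0:4, 60 * 9, replace = TRUE), 60, 9)  # i.i.d. noise
  fracs <- vapply(2:4, function(mc)
    suppressWarnings(permutation_consensus(x, k = 4, min_concordant = mc,
                                           seed = 3))$stable_fraction,
    numeric(1L))
  expect_true(all(diff(fracs) <= 0))
  expect_true(all(fracs >= 0 & fracs <= 1))
})

test_that("consensus on i.i.d. scores reproduces its frozen regression value", {
  set.seed(43)
  x <- matrix(sample(0:4, 60 * 9, replace = TRUE), 60, 9)
  core <- suppressWarnings(permutation_consensus(x, k = 4, seed = 6))
  expect_equal(core$stable_fraction, 38 / 60, tolerance = 1e-12)
  expect_true(core$below_threshold)
})

test_that("Lloyd refinement reproduces the hand-worked 1-D example", {
  sol <- kmeans_refine(cbind(c(0, 1, 9, 10)), centers = cbind(c(0, 10)))
  expect_equal(unname(sol$centroids[, 1]), c(0.5, 9.5))
  expect_equal(sol$tot_withinss, 1.0)
  expect_true(sol$converged)
})

test_that("Lloyd refinement is a fixed point at an optimum and descends monotonically", {
  coh <- zero_noise_cohort()
  x <- ratings(coh)
  centers <- t(sapply(1:4, function(p)
    colMeans(x[coh$true_profile == p, , drop = FALSE])))
  sol <- kmeans_refine(x, centers)
  expect_length(sol$wss_trace, 1L)  # one pass, no label ever moves
  expect_true(sol$converged)
  expect_equal(cohen_kappa(sol$labels, coh$true_profile), 1)

  set.seed(47)
  x2 <- matrix(sample(0:4, 80 * 9, replace = TRUE), 80, 9)
  init <- x2[sample.int(80, 5), ]
  sol2 <- kmeans_refine(x2, init)
  expect_true(all(diff(sol2$wss_trace) <= 1e-9))
  ## never worse than the within-SS of the initial assignment
  init_lab <- assign_nearest(x2, init)
  init_wss <- sum((x2 - init[init_lab, ])^2)
  expect_lte(sol2$tot_withinss, init_wss)
  expect_error(kmeans_refine(x2, matrix(NA_real_, 2, 9)), "non-finite")
})

test_that("Lloyd refinement agrees with stats::kmeans from the same start", {
  set.seed(53)
  x <- matrix(rnorm(100 * 5), 100, 5)
  init <- x[sample.int(100, 4), ]
  ours <- kmeans_refine(x, init)
  ref <- stats::kmeans(x, centers = init, algorithm = "Lloyd",
                       iter.max = 300)
  expect_equal(ours$tot_withinss, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(percent_agreement(ours$labels, ref$cluster), 1)
})

test_that("an emptied cluster is re-seeded at the farthest point", {
  x <- cbind(c(0, 0.5, 10, 10.5, 20, 20.5))
  ## third centroid far away: it captures nothing on the first assignment
  sol <- kmeans_refine(x, cbind(c(0, 10, 1000)))
  expect_equal(sort(unique(sol$labels)), 1:3)
  expect_equal(sol$tot_withinss, 3 * 0.125)
})

test_that("multi-start k-means finds the enumerated global optimum for small n", {
  set.seed(59)
  for (rep in 1:8) {
    n <- sample(6:10, 1L)
    x <- matrix(rnorm(n * 2), n, 2)
    best <- min(vapply(all_bipartitions(n), function(lab) {
      w <- 0
      for (g in 1:2) {
        b <- x[lab == g, , drop = FALSE]
        if (nrow(b)) w <- w + sum(sweep(b, 2L, colMeans(b))^2)
      }
      w
    }, numeric(1L)))
    sol <- kmeans_multistart(x, k = 2, n_starts = 50, seed = rep)
    expect_equal(sol$tot_withinss, best, tolerance = 1e-8,
                 info = paste("rep", rep))
  }
})

test_that("multi-start recovers a separated cohort and nests across n_starts", {
  coh <- zero_noise_cohort()
  sol <- kmeans_multistart(ratings(coh), k = 4, n_starts = 20, seed = 9)
  expect_equal(ground_truth_agreement(coh, sol)$kappa, 1)

  set.seed(61)
  x <- matrix(sample(0:4, 70 * 9, replace = TRUE), 70, 9)
  wss <- vapply(c(1, 5, 20, 60), function(m)
    kmeans_multistart(x, k = 3, n_starts = m, seed = 101)$tot_withinss,
    numeric(1L))
  expect_true(all(diff(wss) <= 1e-9))
})
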