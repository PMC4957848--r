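# Profile description tables and the between-profile test battery.

test_that("profile summaries compute t-based confidence intervals as by hand", {
  x <- matrix(c(2, 2, 2,   # item A constant in profile 1
                1, 2, 3),  # item B spread 1,2,3
              3, 2)
  s <- summarize_profiles(x, labels = c(1, 1, 1))
  tab <- s$table
  a <- tab[1, ]
  expect_equal(a$mean, 2)
  expect_equal(a$upper - a$lower, 0)
  b <- tab[2, ]
  expect_equal(b$mean, 2)
  expect_equal(b$upper, 2 + qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3),
               tolerance = 1e-9)
  ## the total row equals the sum of item means
  tot <- tab[tab$item == "total", ]
  expect_equal(tot$mean, sum(tab$mean[tab$item != "total"]))
})

test_that("a singleton profile reports undefined intervals", {
  x <- rbind(c(1, 1), c(3, 3), c(4, 4))
  s <- summarize_profiles(x, labels = c(1, 1, 2))
  expect_true(all(is.na(s$table[s$table$profile == 2, c("lower", "upper")])))
  expect_equal(s$sizes, c(2, 1))
})

test_that("the zero-noise cohort reproduces the rounded reference centroids", {
  coh <- simulate_cohort(cohort_config(noise_sd = 0), n = 300, seed = 21)
  s <- summarize_profiles(coh, coh$true_profile)
  expect_equal(unname(s$centroids), unname(round(reference_centroids())))
  ## item-6 mean of the psychotic profile: centroid 3.22 discretizes to 3
  expect_equal(unname(s$centroids[4, "HoNOS-6"]), 3)
  ## CI width is zero under zero noise
  expect_true(all(s$table$upper - s$table$lower == 0))
})

test_that("profile naming matches centroids to the canonical profiles", {
  ref <- reference_centroids()
  expect_equal(label_profiles(ref), profile_names())
  shuffle <- c(3, 1, 4, 2)
  expect_equal(label_profiles(ref[shuffle, ]), profile_names()[shuffle])
  set.seed(23)
  for (rep in 1:10) {
    pert <- ref + matrix(runif(36, -0.2, 0.2), 4, 9)
    expect_equal(label_profiles(pert), profile_names())
  }
  expect_equal(label_profiles(ref[1:3, ]), paste0("profile-", 1:3))
})

test_that("Pearson chi-squared reproduces the published admission statistics", {
  sizes <- c(233, 95, 137, 77)
  delusions <- rbind(yes = c(32, 7, 5, 23))
  delusions <- rbind(delusions, no = sizes - delusions)
  expect_equal(chi_square(delusions)$statistic, 33.97, tolerance = 0.02 / 33.97)
  self_harm <- rbind(yes = c(33, 10, 9, 3))
  self_harm <- rbind(self_harm, no = sizes - self_harm)
  expect_equal(chi_square(self_harm)$statistic, 9.36, tolerance = 0.02 / 9.36)
  expect_equal(chi_square(self_harm)$df, 3)
})

test_that("chi-squared equals the brute-force O/E sum and is zero under homogeneity", {
  homog <- outer(c(10, 20), c(3, 5, 7))
  expect_equal(chi_square(homog)$statistic, 0)
  set.seed(29)
  for (rep in 1:15) {
    tab <- matrix(rpois(12, 20) + 1L, 3, 4)
    r <- chi_square(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - expected)^2 / expected),
                 tolerance = 1e-10)
    expect_equal(r$df, 6)
  }
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero marginal")
  expect_warning(chi_square(rbind(c(1, 2), c(2, 1))), "below 5")
})

test_that("one-way ANOVA reproduces the hand-worked F and degenerate cases", {
  r <- anova_posthoc(c(1, 2, 5, 6), c("a", "a", "b", "b"))
  expect_equal(r$statistic, 32)
  expect_equal(r$df, c(1, 2))
  ## identical constant groups are degenerate
  d <- anova_posthoc(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_true(d$degenerate)
  expect_true(is.na(d$statistic))
})

test_that("post hoc homogeneous subsets separate the profiles that differ", {
  set.seed(31)
  g <- rep(1:4, times = c(233, 95, 137, 77))
  cirs <- rnorm(length(g), mean = c(18.72, 16.53, 22.14, 20.36)[g], sd = 6.3)
  r <- anova_posthoc(cirs, profile_names()[g])
  expect_gt(r$statistic, 5)
  in_same_subset <- function(a, b) any(vapply(r$subsets, function(s)
    all(c(a, b) %in% s), logical(1L)))
  ## somatic separated from affective and psychotic... functional lowest
  expect_false(in_same_subset("BPSD-somatic", "BPSD-affective"))
  expect_false(in_same_subset("BPSD-somatic", "BPSD-functional"))
  expect_equal(names(which.min(r$means)), "BPSD-functional")
})

test_that("Kruskal-Wallis reproduces the hand rank computation and handles ties", {
  r <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 3.857, tolerance = 1e-3)
  expect_equal(r$df, 1)
  expect_equal(kruskal_wallis(rep(5, 8), rep(1:2, 4))$statistic, 0)
})

test_that("Kruskal-Wallis p-values are near-uniform under the null", {
  set.seed(37)
  ps <- vapply(1:40, function(i) {
    v <- rnorm(60)
    kruskal_wallis(v, rep(1:3, each = 20))$p.value
  }, numeric(1L))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the item-8 breakdown reproduces the published percentages", {
  ## reconstruct per-subject primary sub-problems from the published
  ## per-profile counts
  counts <- rbind(
    phobias      = c(0, 0, 0, 2),
    anxiety      = c(133, 43, 74, 44),
    ocd          = c(0, 0, 2, 0),
    strain       = c(6, 0, 0, 1),
    dissociative = c(1, 0, 0, 0),
    somatoform   = c(1, 0, 0, 0),
    eating       = c(18, 2, 12, 11),
    sleep        = c(25, 6, 25, 8),
    sexual       = c(2, 1, 3, 0),
    other        = c(9, 4, 8, 2)
  )
  sizes <- c(233, 95, 137, 77)
  flags <- character(0); labels <- integer(0)
  for (p in 1:4) {
    rated <- rep(rownames(counts), counts[, p])
    flags <- c(flags, rated, rep("none", sizes[p] - length(rated)))
    labels <- c(labels, rep(p, sizes[p]))
  }
  br <- item8_breakdown(flags, labels)
  expect_equal(br$counts["rated", "total"], 443L)
  expect_equal(br$percent["rated", "total"], 81.7)
  expect_equal(br$counts["rated", "3"], 124L)   # somatic profile
  expect_equal(br$percent["rated", "3"], 90.5)
  expect_equal(br$percent["anxiety", "total"], 66.4)
  expect_equal(br$percent["anxiety", "2"], 76.8)
  ## empty flag set
  empty <- item8_breakdown(rep("none", 10), rep(1:2, 5))
  expect_true(all(empty$counts == 0))
  expect_true(all(empty$percent == 0))
  ## no percentage exceeds 100
  expect_true(all(br$percent <= 100))
})
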