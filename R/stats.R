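# Profile description and validation statistics: per-profile item means
# with t-based 95% CIs, canonical profile naming, and the between-profile
# test battery (Pearson chi-squared, one-way ANOVA with post hoc
# homogeneous subsets, Kruskal-Wallis).

new_group_comparison <- function(test, statistic, df, p.value, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p.value = unname(p.value), ...),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), x$p.value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (!is.null(x$subsets)) {
    cat("homogeneous subsets (alpha = 0.05):\n")
    for (s in x$subsets) cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Per-profile item summaries
#'
#' Per-profile, per-item means with two-sided t-based 95% confidence
#' intervals, plus the same summary of the total score (row sum over the
#' clustering items) -- the standard descriptive table of a profile
#' solution.  Profiles of size 1 have undefined intervals (reported as NA).
#'
#' @param x Rating matrix, data frame, or `cohort_table`.
#' @param labels Profile labels aligned with the rows of `x`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"profile_summary"`: `table` (long data frame
#'   with columns `profile`, `item`, `n`, `mean`, `lower`, `upper`, where
#'   `item = "total"` holds the total-score row), `sizes`, `centroids`
#'   (profiles x items mean matrix), `k`.
#' @export
summarize_profiles <- function(x, labels, level = 0.95) {
  x <- as_score_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("item-", seq_len(ncol(x)))
  stopifnot(length(labels) == nrow(x))
  labels <- match(labels, sort(unique(labels)))
  k <- max(labels)
  sizes <- tabulate(labels, k)
  vals <- cbind(x, total = rowSums(x))
  rows <- list()
  for (j in seq_len(k)) {
    block <- vals[labels == j, , drop = FALSE]
    n <- nrow(block)
    m <- colMeans(block)
    half <- if (n > 1L) {
      stats::qt(1 - (1 - level) / 2, n - 1L) * apply(block, 2L, stats::sd) / sqrt(n)
    } else rep(NA_real_, ncol(block))
    rows[[j]] <- data.frame(profile = j, item = colnames(vals), n = n,
                            mean = unname(m), lower = unname(m - half),
                            upper = unname(m + half))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, sizes = sizes,
                 centroids = cluster_centroids(x, labels, k), k = k,
                 level = level),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, digits = 2L, ...) {
  cat(sprintf("Profile summary: %d profiles, n = %d\n", x$k, sum(x$sizes)))
  wide <- stats::reshape(
    transform(x$table,
              cell = ifelse(is.na(x$table$lower),
                            sprintf("%.*f", digits, x$table$mean),
                            sprintf("%.*f (%.*f-%.*f)", digits, x$table$mean,
                                    digits, x$table$lower, digits,
                                    x$table$upper)))[c("profile", "item", "cell")],
    idvar = "item", timevar = "profile", direction = "wide")
  names(wide) <- c("item", sprintf("profile-%d (n=%d)", seq_len(x$k), x$sizes))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Name estimated profiles after the canonical BPSD profiles
#'
#' Matches each estimated centroid to the reference centroids of the four
#' canonical BPSD profiles by exact minimum-total-distance assignment and
#' inherits the matched name.  For solutions that are not 4 profiles on the
#' 9 canonical items, generic `profile-1..k` names are returned.
#'
#' @param centers k x d estimated centroid matrix.
#' @return Character vector of display names, one per centroid row.
#' @export
#' @examples
#' label_profiles(reference_centroids())  # identity
label_profiles <- function(centers) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k != 4L || ncol(centers) != 9L)
    return(paste0("profile-", seq_len(k)))
  ref <- reference_centroids()
  cost <- sqrt(dist2(centers, ref))  # rows: estimated, cols: reference
  ## maximize total (max cost - cost) <=> minimize total distance; the
  ## positive offset forces a complete matching
  map <- best_assignment(t(max(cost) - cost + 1))
  rownames(ref)[map]
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared without continuity correction, df = (r-1)(c-1), as
#' used to compare categorical covariates (admission causes, legal status)
#' across profiles.  A structured low-expected-count flag is raised when any
#' expected cell is below 5.
#'
#' @param tab r x c matrix of non-negative integer counts with positive row
#'   and column sums.
#' @return A `"group_comparison"` with `statistic`, `df`, `p.value`,
#'   `expected`, `low_expected`.
#' @export
#' @examples
#' chi_square(rbind(yes = c(32, 7, 5, 23), no = c(201, 88, 132, 54)))
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == floor(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero marginal")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ht$expected < 5)
  if (low)
    warning("expected count below 5 in some cell; chi-squared approximation ",
            "may be inaccurate")
  new_group_comparison("pearson-chi-squared", ht$statistic,
                       ht$parameter, ht$p.value,
                       expected = ht$expected, observed = tab,
                       low_expected = low)
}

## SPSS-style homogeneous subsets from a pairwise significance matrix:
## maximal runs of mean-ordered groups containing no significant pair.
homogeneous_subsets <- function(means, sig) {
  ord <- order(means)
  k <- length(means)
  subsets <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1L)], ord[i:(j + 1L)]])) j <- j + 1L
    subsets[[i]] <- ord[i:j]
  }
  ## drop subsets nested in an earlier/later one
  keep <- vapply(seq_along(subsets), function(i)
    !any(vapply(seq_along(subsets), function(j)
      j != i && all(subsets[[i]] %in% subsets[[j]]), logical(1L))),
    logical(1L))
  lapply(subsets[keep], function(s) names(means)[s])
}

#' One-way ANOVA with post hoc homogeneous subsets
#'
#' One-way ANOVA F test across profiles, followed by Tukey HSD pairwise
#' comparisons assembled into homogeneous subsets at alpha = 0.05 (groups
#' between which no pairwise difference is significant), the usual way of
#' reading post hoc structure in profile-validation tables.
#'
#' @param values Numeric response per subject (e.g. total score, CIRS-G);
#'   missing values are dropped pairwise with their labels.
#' @param labels Group (profile) labels, at least 2 groups of size >= 2.
#' @param alpha Significance level for the subsets (default 0.05).
#' @return A `"group_comparison"` with `statistic` (F), `df` (k-1, n-k),
#'   `p.value`, `means`, `tukey` (pairwise table), `subsets`, and
#'   `degenerate` flag (zero variance everywhere).
#' @export
anova_posthoc <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  g <- factor(labels[keep])
  stopifnot(nlevels(g) >= 2L, all(table(g) >= 2L))
  means <- tapply(values, g, mean)
  fit <- stats::aov(values ~ g)
  ## a perfect fit triggers R's unreliable-F warning; the degenerate case is
  ## detected and reported explicitly below
  at <- suppressWarnings(stats::anova(fit))
  if (at["Residuals", "Mean Sq"] <= 1e-12) {
    degenerate <- at["g", "Mean Sq"] <= 1e-12
    return(new_group_comparison("one-way-anova",
                                if (degenerate) NA_real_ else Inf,
                                at$Df, if (degenerate) NA_real_ else 0,
                                means = means, subsets = NULL,
                                degenerate = degenerate))
  }
  tukey <- stats::TukeyHSD(fit)$g
  sig <- matrix(FALSE, nlevels(g), nlevels(g),
                dimnames = list(levels(g), levels(g)))
  ## TukeyHSD rows follow combn() order of the factor levels; index by that
  ## rather than parsing row names (level names may contain the separator)
  pairs <- utils::combn(levels(g), 2L)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sig[a, b] <- sig[b, a] <- tukey[i, "p adj"] < alpha
  }
  new_group_comparison("one-way-anova", at["g", "F value"], at$Df,
                       at["g", "Pr(>F)"], means = means, tukey = tukey,
                       subsets = homogeneous_subsets(means, sig),
                       degenerate = FALSE)
}

#' Kruskal-Wallis rank test across profiles
#'
#' Tie-corrected Kruskal-Wallis H with df = k-1, used for skewed covariates
#' such as length of stay.  When every value is identical the statistic is 0
#' by convention (p = 1).
#'
#' @inheritParams anova_posthoc
#' @return A `"group_comparison"` with `statistic` (H), `df`, `p.value`,
#'   `medians`.
#' @export
kruskal_wallis <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  g <- factor(labels[keep])
  stopifnot(nlevels(g) >= 2L, all(table(g) >= 1L))
  medians <- tapply(values, g, stats::median)
  if (length(unique(values)) == 1L)
    return(new_group_comparison("kruskal-wallis", 0, nlevels(g) - 1L, 1,
                                medians = medians))
  ht <- stats::kruskal.test(values, g)
  new_group_comparison("kruskal-wallis", ht$statistic, ht$parameter,
                       ht$p.value, medians = medians)
}

#' Breakdown of the "other mental and behavioural problems" item
#'
#' Tabulates the sub-problem recorded under HoNOS65+ item 8 (phobias,
#' anxiety, obsessive-compulsive symptoms, mental strain, dissociative,
#' somatoform, eating, sleep, sexual, other) per profile and overall.  The
#' "rated 1 or more" row is a percentage of profile size; sub-problem rows
#' are percentages of the subjects rated 1 or more in that profile, the
#' convention of the published breakdown.
#'
#' @param flags Per-subject sub-problem: a factor/character vector whose
#'   `none` level (or `NA`) marks subjects with item 8 rated 0.
#' @param labels Profile labels aligned with `flags`.
#' @return An object of class `"item8_breakdown"`: `counts` and `percent`
#'   matrices (rows: `rated` plus sub-problems; columns: `total` plus
#'   profiles).
#' @export
item8_breakdown <- function(flags, labels) {
  stopifnot(length(flags) == length(labels))
  flags <- as.character(flags)
  flags[is.na(flags)] <- "none"
  cats <- setdiff(unique(flags), "none")
  profs <- sort(unique(labels))
  cols <- c("total", as.character(profs))
  counts <- matrix(0L, length(cats) + 1L, length(cols),
                   dimnames = list(c("rated", cats), cols))
  sizes <- c(length(labels), tabulate(factor(labels, profs)))
  for (ci in seq_along(cols)) {
    f <- if (ci == 1L) flags else flags[labels == profs[ci - 1L]]
    counts["rated", ci] <- sum(f != "none")
    for (cat in cats) counts[cat, ci] <- sum(f == cat)
  }
  percent <- counts
  percent["rated", ] <- 100 * counts["rated", ] / sizes
  denom <- pmax(counts["rated", ], 1L)
  if (length(cats))
    percent[cats, ] <- 100 * sweep(counts[cats, , drop = FALSE], 2L, denom, "/")
  structure(list(counts = counts, percent = round(percent, 1L),
                 sizes = sizes),
            class = "item8_breakdown")
}

#' @export
print.item8_breakdown <- function(x, ...) {
  cat("Item-8 sub-problem breakdown: n (%)\n")
  out <- matrix(sprintf("%d (%.1f)", x$counts, x$percent),
                nrow(x$counts), dimnames = dimnames(x$counts))
  print(out, quote = FALSE)
  invisible(x)
}
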