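#' Configuration for the synthetic cohort generator
#'
#' Collects every parameter of the generative model behind
#' [simulate_cohort()].  Defaults reproduce the structure of the reference
#' cohort: 542 subjects in four profiles of 233/95/137/77, item scores drawn
#' around the reference centroids, and profile-dependent covariates (MMSE,
#' CIRS-G, lengths of stay, legal admission status, sex, age, admission-cause
#' flags) matching the published per-profile summaries.  MMSE is set missing
#' with profile-dependent probability (cognitive testing is often impossible
#' in acutely ill patients), recorded with a missing-reason flag.
#'
#' Item scores are generated as a latent Gaussian (mean = profile centroid
#' entry, sd = `noise_sd`) rounded to the nearest integer and clipped to the
#' 0-4 ordinal support.  Acute length of stay is log-normal with the profile
#' median and a log-sd matched to the published interquartile range; total
#' length of stay is log-normal matched to the published mean and sd (both
#' right-skewed in practice).
#'
#' @param n_total Cohort size (default 542).
#' @param profile_proportions Four mixing fractions, summing to 1; default
#'   233/542, 95/542, 137/542, 77/542.
#' @param centroids 4 x 9 matrix of profile item means in `[0, 4]`; default
#'   [reference_centroids()].
#' @param noise_sd Latent per-item standard deviation (>= 0; 0 gives the
#'   deterministic rounded-centroid limit).  Default 1.
#' @param mmse_mean,mmse_sd Per-profile MMSE mean (default
#'   18.49/17.06/15.03/18.12) and common sd; scores clipped to 0-30.
#' @param mmse_missing_prob Per-profile probability that the MMSE is missing,
#'   ordered affective/functional/somatic/psychotic (default
#'   0.29/0.25/0.476/0.465).
#' @param cirs_mean,cirs_sd Per-profile CIRS-G comorbidity mean (default
#'   18.72/16.53/22.14/20.36) and common sd; clipped at 0.
#' @param acute_los_median,acute_los_iqr Per-profile median (34/41/43/45 days)
#'   and IQR of acute length of stay.
#' @param total_los_mean,total_los_sd Per-profile mean and sd of total length
#'   of stay in days.
#' @param nonvoluntary_prob,other_status_prob Per-profile probabilities of
#'   non-voluntary (0.80/0.83/0.94/0.93) and "other" legal admission status;
#'   voluntary takes the remainder.
#' @param female_prob Per-profile probability of female sex.
#' @param age_mean,age_sd Per-profile age mean (years) and common sd; ages
#'   clipped at 65 (psychogeriatric wards).
#' @param cause_probs 7 x 4 matrix of per-profile admission-cause
#'   probabilities (rows: agitation, harm, sheltering, denial_of_care,
#'   delusions, care_impossible, self_harm); a subject may carry several.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return An object of class `"cohort_config"` (validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_total = 542L,
                          profile_proportions = c(233, 95, 137, 77) / 542,
                          centroids = reference_centroids(),
                          noise_sd = 1,
                          mmse_mean = c(18.49, 17.06, 15.03, 18.12),
                          mmse_sd = 6.3,
                          mmse_missing_prob = c(0.29, 0.25, 0.476, 0.465),
                          cirs_mean = c(18.72, 16.53, 22.14, 20.36),
                          cirs_sd = 6.3,
                          acute_los_median = c(34, 41, 43, 45),
                          acute_los_iqr = c(37, 40, 32, 40),
                          total_los_mean = c(55.47, 72.18, 58.61, 62.16),
                          total_los_sd = c(54.4, 64.6, 45.1, 57.8),
                          nonvoluntary_prob = c(0.80, 0.83, 0.94, 0.93),
                          other_status_prob = c(0.013, 0.011, 0.015, 0),
                          female_prob = c(0.5751, 0.5578, 0.5620, 0.6623),
                          age_mean = c(80.98, 80.84, 82.94, 80.21),
                          age_sd = 8.8,
                          cause_probs = default_cause_probs(),
                          seed = NULL) {
  cfg <- list(n_total = as.integer(n_total),
              profile_proportions = profile_proportions,
              centroids = as.matrix(centroids), noise_sd = noise_sd,
              mmse_mean = mmse_mean, mmse_sd = mmse_sd,
              mmse_missing_prob = mmse_missing_prob,
              cirs_mean = cirs_mean, cirs_sd = cirs_sd,
              acute_los_median = acute_los_median,
              acute_los_iqr = acute_los_iqr,
              total_los_mean = total_los_mean, total_los_sd = total_los_sd,
              nonvoluntary_prob = nonvoluntary_prob,
              other_status_prob = other_status_prob,
              female_prob = female_prob,
              age_mean = age_mean, age_sd = age_sd,
              cause_probs = as.matrix(cause_probs), seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' Default per-profile admission-cause probabilities
#'
#' Column percentages of the seven admission causes in the reference cohort,
#' as probabilities; rows are causes, columns the four profiles.
#'
#' @return A 7 x 4 numeric matrix.
#' @export
default_cause_probs <- function() {
  m <- rbind(
    agitation       = c(30.9, 32.6, 24.8, 36.4),
    harm            = c(28.8, 24.4, 32.8, 37.7),
    sheltering      = c(16.3, 24.2, 16.1, 16.9),
    denial_of_care  = c(10.7, 14.7, 15.3, 16.9),
    delusions       = c(13.7,  7.4,  3.6, 29.9),
    care_impossible = c(10.7,  9.5, 13.1, 10.4),
    self_harm       = c(14.2, 10.5,  6.6,  3.9)
  ) / 100
  colnames(m) <- profile_names()
  m
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_total >= 1L,
            length(cfg$profile_proportions) == 4L,
            abs(sum(cfg$profile_proportions) - 1) <= 1e-9,
            all(cfg$profile_proportions >= 0),
            nrow(cfg$centroids) == 4L,
            all(cfg$centroids >= 0 & cfg$centroids <= 4),
            cfg$noise_sd >= 0,
            all(cfg$mmse_missing_prob >= 0 & cfg$mmse_missing_prob <= 1),
            all(cfg$nonvoluntary_prob + cfg$other_status_prob <= 1),
            all(cfg$female_prob >= 0 & cfg$female_prob <= 1),
            all(cfg$cause_probs >= 0 & cfg$cause_probs <= 1),
            all(cfg$acute_los_median > 0), all(cfg$acute_los_iqr > 0),
            all(cfg$total_los_mean > 0), all(cfg$total_los_sd > 0))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, profile proportions %s, noise sd %.2f\n",
              x$n_total, paste(round(x$profile_proportions, 3), collapse = "/"),
              x$noise_sd))
  cat("  centroids:\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' Simulate a synthetic psychogeriatric cohort
#'
#' Draws a cohort from the four-profile generative model of
#' [cohort_config()]: a profile per subject from the mixing proportions, the
#' nine ordinal item scores as discretized clipped Gaussians around the
#' profile centroid, and profile-dependent covariates.  The true profile of
#' every subject is recorded, so downstream clustering stages can be scored
#' against ground truth.  A fixed seed gives bit-identical output.
#'
#' @param config A [cohort_config()] object.
#' @param n Cohort size; defaults to `config$n_total`.
#' @param seed Integer seed; defaults to `config$seed`, or a seed drawn from
#'   the session RNG (recorded in the result) when both are `NULL`.
#' @return An object of class `"cohort_table"` (a data frame): `subject_id`,
#'   the nine item columns named by [rating_items()], covariates (`mmse`,
#'   `mmse_missing_reason`, `cirs_g`, `los_acute`, `los_total`,
#'   `legal_status`, `sex`, `age`, `cause_*` 0/1 flags), and `true_profile`
#'   (integer 1-4 in [profile_names()] order).  Attributes `seed` and
#'   `config` record provenance.
#' @seealso [ratings()], [ground_truth_agreement()]
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(), n = 100, seed = 1)
#' table(coh$true_profile)
simulate_cohort <- function(config = cohort_config(), n = config$n_total,
                            seed = config$seed) {
  validate_cohort_config(config)
  seed <- resolve_seed(seed)
  set.seed(seed)
  n <- as.integer(n)
  p <- sample.int(4L, n, replace = TRUE, prob = config$profile_proportions)
  if (length(unique(p)) < 4L)
    warning("profile(s) ", paste(setdiff(1:4, unique(p)), collapse = ", "),
            " received no subjects at n = ", n)
  d <- ncol(config$centroids)
  latent <- config$centroids[p, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
  scores <- pmin(4L, pmax(0L, as.integer(round(latent))))
  scores <- matrix(scores, n, d, dimnames = list(NULL, rating_items()))

  mmse <- round(pmin(30, pmax(0, stats::rnorm(n, config$mmse_mean[p],
                                              config$mmse_sd))))
  miss <- stats::rbinom(n, 1L, config$mmse_missing_prob[p]) == 1L
  mmse[miss] <- NA
  cirs <- round(pmax(0, stats::rnorm(n, config$cirs_mean[p], config$cirs_sd)))

  ## log-normal acute stay: log-sd matched to the printed IQR around the
  ## median via IQR = median * 2 * sinh(z75 * sigma)
  z75 <- stats::qnorm(0.75)
  sdlog <- asinh(config$acute_los_iqr / (2 * config$acute_los_median)) / z75
  los_acute <- pmax(1, round(stats::rlnorm(n, log(config$acute_los_median[p]),
                                           sdlog[p])))
  cv2 <- (config$total_los_sd / config$total_los_mean)^2
  sig2 <- log(1 + cv2)
  los_total <- pmax(1, round(stats::rlnorm(n,
    log(config$total_los_mean[p]) - sig2[p] / 2, sqrt(sig2[p]))))

  status_probs <- rbind(
    voluntary = 1 - config$nonvoluntary_prob - config$other_status_prob,
    `non-voluntary` = config$nonvoluntary_prob,
    other = config$other_status_prob)
  legal <- vapply(p, function(pp)
    sample(rownames(status_probs), 1L, prob = status_probs[, pp]), character(1L))
  sex <- ifelse(stats::rbinom(n, 1L, config$female_prob[p]) == 1L,
                "female", "male")
  age <- pmax(65, round(stats::rnorm(n, config$age_mean[p], config$age_sd)))
  causes <- vapply(seq_len(nrow(config$cause_probs)), function(j)
    stats::rbinom(n, 1L, config$cause_probs[j, p]), integer(n))
  colnames(causes) <- paste0("cause_", rownames(config$cause_probs))

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    scores,
                    mmse = mmse,
                    mmse_missing_reason = ifelse(miss, "not-assessable",
                                                 NA_character_),
                    cirs_g = cirs, los_acute = los_acute,
                    los_total = los_total,
                    legal_status = factor(legal, rownames(status_probs)),
                    sex = factor(sex, c("female", "male")),
                    age = age, causes, true_profile = p,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, seed = seed, config = config,
            class = c("cohort_table", "data.frame"))
}

#' Extract the rating matrix from a cohort
#'
#' @param cohort A `cohort_table` (or any data frame holding the item
#'   columns).
#' @param items Item columns to extract, default [rating_items()].
#' @return Integer score matrix (subjects x items) with subject ids as row
#'   names.
#' @export
ratings <- function(cohort, items = rating_items()) {
  stopifnot(all(items %in% names(cohort)))
  x <- as.matrix(cohort[items])
  storage.mode(x) <- "integer"
  rownames(x) <- as.character(cohort$subject_id %||% seq_len(nrow(x)))
  x
}

#' Agreement between estimated clusters and simulated ground truth
#'
#' Scores a clustering of a synthetic cohort against the generating profile
#' labels, after optimal label alignment (cluster indices are arbitrary).
#'
#' @param cohort A `cohort_table` with a `true_profile` column.
#' @param solution A fitted clustering (anything with a `$labels` element,
#'   e.g. [profile_fit()]) or a bare label vector.
#' @return A [agreement()] result: confusion matrix, optimal mapping, percent
#'   agreement, and Cohen's kappa.
#' @export
ground_truth_agreement <- function(cohort, solution) {
  truth <- cohort$true_profile
  if (is.null(truth))
    stop("cohort carries no true_profile column; ground truth is only ",
         "available for synthetic cohorts")
  labels <- if (is.list(solution)) solution$labels else solution
  agreement(truth, labels)
}
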