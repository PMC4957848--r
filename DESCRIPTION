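Package: bpsdprofiles
Title: Clinical Profiles of Psychogeriatric Inpatients by Hybrid
    Ward/K-Means Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions psychogeriatric inpatients into clinical profiles
    from nine ordinal HoNOS65+ items using a mixed clustering approach:
    permutation-stabilized Ward hierarchical clustering seeding Lloyd
    k-means, 60/40 split-sample cross-validation with optimally aligned
    Cohen's kappa, Calinski-Harabasz model selection over a range of
    cluster counts, and multi-start robustness checks.  Includes a
    synthetic cohort generator emulating the four canonical BPSD profiles
    (affective, functional, somatic, psychotic) with profile-dependent
    covariates, and profile-validation statistics (ANOVA with post hoc
    homogeneous subsets, Kruskal-Wallis, Pearson chi-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
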