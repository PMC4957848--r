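# bpsdprofiles

Clinical profiling of psychogeriatric inpatients hospitalized for
behavioural and psychological symptoms of dementia (BPSD), from nine
ordinal HoNOS65+ items (item 1, items 4–10, item 13; each scored 0–4).

Patients on acute psychogeriatric wards are heterogeneous: the same total
severity can reflect predominantly affective, functional, somatic or
psychotic presentations.  This package partitions such patients into
clinical profiles with a **mixed clustering approach** and validates the
partition statistically.  It is aimed at researchers in psychogeriatrics
and biostatisticians reproducing or extending profile analyses of ordinal
clinical scales.

## The method

For a ratings matrix $X \in \{0,\dots,4\}^{n \times 9}$ and a candidate
number of profiles $k$:

1. **Ward + permutation consensus** — Ward's minimum-variance hierarchical
   clustering (Euclidean distance) is run on four row orders of the data;
   solutions are aligned by optimal label assignment, and subjects whose
   aligned label agrees in ≥ 3 of the 4 runs form the *stable core*
   (required to cover ≥ 70 % of subjects).
2. **Seeded k-means** — Lloyd's algorithm, seeded at the stable-core
   centroids, refines the partition over all subjects until the assignment
   is exactly unchanged.
3. **Split-sample cross-validation** — a 60/40 split; the mixed approach is
   fitted on S1, and the held-out S2 is labeled both by nearest-centroid
   assignment to S1 centroids and by an independent mixed fit.  Agreement
   between the two labelings is Cohen's kappa after optimal label
   alignment, $\kappa = (p_o - p_e)/(1 - p_e)$, retained when
   $\kappa \ge 0.61$.
4. **Model selection over k = 3..7** — each whole-sample fit is scored by
   the Calinski–Harabasz index $CH = \frac{B/(k-1)}{W/(n-k)}$; among
   retained k the one maximizing kappa is selected, provided its CH lies
   within 15 % of the maximum over the range.
5. **Robustness** — the selected solution is compared (kappa) against the
   best of 100 random-start k-means runs.

A synthetic cohort generator emulates the reference four-profile cohort
(n = 542; profiles *BPSD-affective*, *BPSD-functional*, *BPSD-somatic*,
*BPSD-psychotic* sized 233/95/137/77) including profile-dependent
covariates (MMSE with structured missingness, CIRS-G, lengths of stay,
legal admission status, admission causes), so the whole pipeline is
testable without patient data.  Profile-validation statistics (per-profile
means with 95 % CIs, Pearson χ², one-way ANOVA with post hoc homogeneous
subsets, Kruskal–Wallis) describe and validate fitted profiles.

## Worked example

```r
library(bpsdprofiles)

coh <- simulate_cohort(seed = 1)    # default 542-subject synthetic cohort
check_sample_size(nrow(coh), 9)
#> sample size n = 542 for d = 9 clustering variables: 60d (adequate)

sel <- select_profiles(ratings(coh), seed = 1)
sel
#> Profile model selection
#>  k     ch kappa retained
#>  3 101.31 0.871     TRUE
#>  4  91.58 0.884     TRUE
#>  5  77.86 0.604    FALSE
#>  6  69.55 0.619     TRUE
#>  7  61.87 0.526    FALSE
#> selected k = 4; robustness kappa vs 100-start k-means: 0.997
```

The table mirrors the published validation layout: per candidate k, the
Calinski–Harabasz index of the whole-sample fit and the cross-validation
kappa, with the retention flag at the 0.61 threshold.  Here k = 4 is both
reproducible (kappa 0.884) and within the CH band, so it is selected; the
solution is essentially identical to the best 100-start k-means solution
(robustness kappa 0.997).

```r
fit <- sel$fits[[match(4, sel$table$k)]]
fit
#> Mixed Ward/k-means profile fit: k = 4, n = 542
#>   stable core: 92.4% of subjects
#>   ...
#>  BPSD-affective    BPSD-somatic  BPSD-psychotic BPSD-functional
#>             227             121              84             110

ground_truth_agreement(coh, fit)
#> Cluster agreement over n = 542 subjects
#>   percent agreement: 0.869   Cohen's kappa: 0.814
```

Estimated profiles are named by matching their centroids to the canonical
profile centroids (`label_profiles()`); against the generating labels the
4-profile fit recovers the simulated structure with kappa 0.81.
`summarize_profiles()`, `anova_posthoc()`, `kruskal_wallis()`,
`chi_square()` and `item8_breakdown()` then produce the descriptive and
validation tables.

See `vignettes/clinical-profiles.Rmd` for the full account of the model,
its assumptions, the generator, and known limitations.

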