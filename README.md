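# oltseq

Integrated genomic analysis of matched primary and post-transplant
recurrent liver tumors.

When hepatocellular carcinoma recurs after orthotopic liver
transplantation, the recurrent tumor grows inside a donor organ: a biopsy
of it is a mixture of recipient-derived tumor cells and donor-derived
normal cells. oltseq is for analysts working with the five-specimen design
that study setting produces — primary tumor (`P_T`), its adjacent normal
(`P_NAT`), recurrent tumor (`R_T`), donor-liver adjacent normal (`R_NAT`),
and recipient blood (`P_B`) — and implements the full chain from raw
allele counts to prognostic candidate genes:

- **Tumor origin** — a clonal-relationship (CR) statistic on shared
  somatic variants, `CR = |P ∩ R| / |P ∪ R|`, with a Poisson
  chance-sharing null over the callable territory
  (`clonal_relationship()`).
- **Donor-cell contamination** — two independent estimators of the donor
  fraction α: a binomial maximum-likelihood fit to germline-SNP allele
  fractions at informative loci, where the mixture expectation is
  `f(α) = ((1−α)·g_R + α·g_D)/2` (`estimate_contamination_germline()`),
  and the somatic VAF-dilution estimator
  `α̂ = 1 − median(VAF_RT / VAF_PT)` over clonal shared variants
  (`estimate_contamination_somatic()`).
- **Somatic variants** — tumor/normal threshold calling with
  donor-difference masking (eliminating R_NAT-vs-P_B differences),
  shared/unique partitions with Welch VAF comparison, the six-class
  substitution spectrum, and the nonsilent-to-silent ratio.
- **Copy number** — binned log2 tumor/normal ratios, recursive
  segmentation with breakpoint-pair (CBS-style) candidates, a five-state
  purity-aware caller, joint breakpoints for matched specimens, and
  k-of-n cross-patient recurrent-region discovery.
- **Expression** — median-of-ratios size factors, per-patient
  `log2(P_T / P_NAT)` fold changes, a sum-conditioned negative-binomial
  exact test for replicate-free pairs, and the recurrent-vs-non-recurrent
  group contrast (|fold| > 2, raw p < 0.01, unadjusted by design).
- **Prognosis** — median and reference (mean − 2 SD of normal tissue)
  dichotomization, in-package Kaplan–Meier / log-rank / Cox PH (Efron
  ties, separation flagged), deletion-by-under-expression candidate
  integration, and a region-wide survival screen with balance flags.

A synthetic cohort generator (`simulate_cohort()`) emulates the whole
design with ground truth — HWE germlines, clonal somatic variants with
binomial read sampling, recurrent tumors as recipient-tumor/donor-normal
mixtures with known α, a planted shared deletion carrying a planted
under-expressed gene, NB expression counts, and proportional-hazards
recurrence times — so every estimator is validated against planted truth.

## Worked example

```r
library(oltseq)

cohort <- simulate_cohort(sim_config(seed = 11))
cohort
#> <oltseq_cohort>
#>   21 patients (9 recurrent, 4 with full specimen sets)
#>   donor contamination alpha: 0.8, 0.06, 0.55, 0
#>   planted gene G0863 (log2FC -1.50) in chr4:3e+07-6e+07
#>   580 somatic truth variants; 1000 x 42 counts matrix

res <- run_recurrence_pipeline(cohort)
res
#> <oltseq_pipeline>
#>   origin calls: recipient, recipient, recipient, recipient
#>   contamination (combined range): HCC01 80-80%; HCC02 6-6%; HCC03 55-56%; HCC04 0-1%
#>   2 catalog regions; 40 shared-del genes; 1 under-expressed; candidates: G0863
#>   survival per candidate:
#> # A tibble: 1 × 7
#>   gene  n_low n_high logrank_p cox_hr   cox_p flag_monotone
#>   <chr> <int>  <int>     <dbl>  <dbl>   <dbl> <lgl>
#> 1 G0863    11     10   0.00347   18.7 0.00965 FALSE
```

Reading the output: all four recurrent tumors are called recipient-origin
(shared somatic variants are orders of magnitude beyond chance sharing);
the combined germline/somatic contamination ranges recover the planted
donor fractions (0.80, 0.06, 0.55, 0) to within a point or two; the
cross-patient catalog finds the shared deletion, whose gene list
intersected with the under-expressed set yields exactly the planted gene;
and the median split of that gene's per-patient fold changes (11 low / 10
high) separates recurrence-free survival (log-rank p = 0.003, Cox HR for
the low group 18.7 adjusted for HBV, grade, age and sex — a wide-interval
estimate, as expected at n = 21).

Individual steps compose with pipes and tidy tools:

```r
folds <- per_patient_fold_changes(cohort$counts, cohort$samples)
fit <- cox_fit(cohort$clinical$time, cohort$clinical$event,
               data.frame(low = as.numeric(cohort$clinical$group == "low")))
tidy(fit)
#> # A tibble: 1 × 7
#>   term  estimate    hr    se ci_low ci_high p_value
#>   <chr>    <dbl> <dbl> <dbl>  <dbl>   <dbl>   <dbl>
#> 1 low       3.08  21.8  1.07   2.67    178. 0.00405
autoplot(km_fit(cohort$clinical$time, cohort$clinical$event,
                cohort$clinical$group))
```

The packaged clinical fixture mirrors the 21-patient transplant cohort's
published table (9 recurrence events within 24 months; non-recurrent
patients censored at 24 months):

```r
cl <- read_clinical_table(oltseq_example("clinical_21.tsv"))
sum(cl$event)
#> [1] 9
```

See `vignette("oltseq-methods")` (source under `vignettes/`) for the
models, assumptions, parameter defaults and known limitations.

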