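---
title: "Models and methods behind oltseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oltseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

oltseq analyzes matched primary and post-transplant recurrent liver tumors.
Each patient contributes up to five specimens: the primary tumor (`P_T`),
its adjacent normal tissue (`P_NAT`), the recurrent tumor (`R_T`), adjacent
normal tissue from the transplanted donor liver (`R_NAT`), and recipient
blood (`P_B`). Because the recurrent tumor grows inside a donor organ, its
biopsy is a cell mixture of recipient-derived tumor and donor-derived
normal tissue; most of the package's statistical machinery exists to
recognize and undo the consequences of that mixture.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic cohort generator does and does not emulate.

## Tumor origin: the clonal-relationship statistic

Whether the recurrent tumor truly descends from the primary is decided from
shared somatic variants. We define the clonal-relationship (CR) value as
the Jaccard index of the two somatic call sets on the
`(chrom, pos, ref, alt)` key,

$$\mathrm{CR} = \frac{|P \cap R|}{|P \cup R|},$$

with a chance-sharing null in which the number of shared variants is
Poisson with mean $|P|\,|R| / C$ for $C$ jointly callable bases —
the expectation under independent placement of both sets over the callable
territory. The origin is called `recipient` when the Poisson tail
probability is at most $10^{-6}$ *and* CR is at least 0.05; both
thresholds are arguments of `clonal_relationship()`. Two unrelated tumors
share essentially no exact somatic keys, so the test is insensitive to the
exact thresholds; the CR floor guards against trivially significant but
biologically negligible overlap in very large call sets.

## Donor-cell contamination

Two independent estimators target the donor fraction $\alpha$ of the
recurrent-tumor biopsy.

**Germline-SNP maximum likelihood.** At a germline locus where the
recipient dosage $g_R$ and donor dosage $g_D$ differ (an *informative*
locus), the alt-allele fraction of the mixture has expectation
$f_i(\alpha) = \big((1-\alpha) g_R + \alpha g_D\big)/2$, observed through a
symmetric error channel $f' = f(1-\varepsilon) + (1-f)\varepsilon$. The
estimator maximizes $\sum_i \log \mathrm{Binom}(a_i \mid d_i, f'_i(\alpha))$
over $\alpha \in [0,1]$: a 0.001 grid scan followed by golden-section
refinement of the best cell, with the boundary values 0 and 1 compared
explicitly so that the noise-free boundary cases return exactly 0 or 1.
The 95% interval is the profile-likelihood set
$\{\alpha : \ell(\alpha) \ge \ell_{\max} - 1.92\}$. Loci inside
copy-number-aberrant segments of `R_T` are excluded (the formula assumes
two copies per cell); the pipeline excludes every imposed segment with
$|\bar L| > 0.1$. The estimator requires at least 30 informative loci at
depth 20+; a donor genetically identical to the recipient at the panel
(no informative loci) is reported as not-estimable rather than zero.

**Somatic VAF dilution.** Contamination dilutes every somatic variant
allele fraction in `R_T` by $(1-\alpha)$ under equal purity of the two
tumors' recipient compartments. Restricting to clonal shared variants —
primary VAF at least $0.8 \cdot \pi_{PT}/2$, copy-number-neutral — the
estimator is $\hat\alpha = 1 - \mathrm{median}_i(\mathrm{VAF}_{RT,i} /
\mathrm{VAF}_{PT,i})$, clamped to $[0,1]$, with a seeded percentile
bootstrap over loci for the interval. The median guards against residual
subclonal structure; at least 10 clonal variants are required. Purity is
an input; `estimate_purity_crude()` offers
$\min(1,\,2\cdot q_{0.95}(\mathrm{VAF}))$ when no external estimate exists.

`combine_contamination()` reports the span of the available point
estimates, the two-method range format in which such estimates are usually
quoted; with one estimator it collapses to a point.

## Somatic calling and donor masking

`call_somatic()` applies a conventional threshold cascade (tumor VAF ≥
0.05, alt reads ≥ 4, both depths ≥ 20, matched-normal VAF ≤ 0.01, all
config-exposed), with `P_B` as the germline reference and `P_NAT`
available as a secondary exclusion filter (VAF > 0.05). For the recurrent
tumor, donor germline leaks into the call set in proportion to $\alpha$;
`mask_donor_differences()` removes calls at loci where the `R_NAT`
genotype differs from the `P_B` genotype, which is exactly the set of loci
at which donor cells can masquerade as somatic signal. Loci covered by
neither panel are retained but flagged. Downstream summaries — the
shared/unique partition with its Welch VAF comparison, the strand-collapsed
six-class substitution spectrum, and the nonsilent-to-silent ratio — are
deterministic tabulations on the called sets.

## Copy number

Binned coverage is compared between tumor and its matched normal as
$L_b = \log_2\!\big((t_b\,S_n/S_t + c)/(n_b + c)\big)$ with a count-scale
pseudocount $c = 0.5$; the library-size ratio $S_n/S_t$ makes global
scaling cancel. Segmentation recursively accepts the most significant
change-point candidate among single breakpoints *and* interior
breakpoint pairs (an interior run tested against its combined flanks),
scored by the Welch t p-value, accepted below $10^{-3}$ with at least 5
bins per resulting segment. Pure single-breakpoint recursion provably
misses weak centered events — the first split of a centered bump is
diluted by both flanks — which is the classical motivation for circular
binary segmentation; the pair search restores that sensitivity while
remaining exactly checkable against exhaustive search on small tracks.

States come from a five-level nearest-mean classifier with
purity-parameterized centers: $\log_2(1-\pi/2)$ for hemizygous and
$\log_2(\max(1-\pi, 0.05))$ for homozygous deletions (the floor avoids
$\log 0$), mirrored for amplifications, ties breaking toward neutral. For
a contaminated recurrent tumor the effective aberrant-cell fraction
$\pi_{RT}(1-\hat\alpha)$ is used, with $\hat\alpha$ from the germline
estimator.

For matched specimens the pipeline imposes *joint breakpoints*: the union
of change points found in either specimen is imposed on both tracks before
state calling (`impose_breakpoints()`). A deletion carried by both tumors
but heavily diluted in `R_T` (at $\alpha = 0.8$ its expected log-ratio is
only about $-0.13$) is then detected by the cleaner `P_T` track, and the
`R_T` track only has to *estimate* the segment state — a far easier task
than de-novo detection at that signal size.

Cross-patient recurrence uses a per-bin vote: within each patient a bin is
categorized from its `(P_T, R_T)` state pair (shared/one-sided,
amplified/deleted); bins backed by at least `k` of `n` patients (default
3) merge into catalog regions, and genes overlap regions by at least one
base under half-open coordinates. GC and mappability correction is
deliberately omitted — the synthetic data carries no such biases — and is
a documented limitation for real coverage data.

## Expression

Size factors are plain median-of-ratios: the median over
all-sample-nonzero genes of the count over the gene's geometric mean.
Per-patient tumor effects are
$F_{gp} = \log_2\!\big((K_{g,PT}/s_{PT} + c)/(K_{g,PNAT}/s_{PNAT} +
c)\big)$, $c = 0.5$ — every patient serves as their own control, which is
what makes the 21-patient recurrent-versus-non-recurrent contrast a
contrast of *fold changes* rather than expression levels.

Within a single patient there is no replication, so the pair test borrows
its dispersion: method-of-moments per-gene dispersions from the pooled
normal samples, regressed as $\phi(\mu) = a_0 + a_1/\mu$ (floored at
$10^{-8}$). The test itself conditions on the pair total $k_A + k_B$ and
sums, over all splits of that total, the probabilities (independent NB
marginals with means proportional to size factors and trend dispersion) of
outcomes at most as likely as the observed split — two-sided by
construction, $p = 1$ for a zero total. It reduces to exhaustive
enumeration, which is exactly how it is tested for totals up to 30.

The group contrast applies a Welch t-test (Mann–Whitney by option) to each
gene's per-patient fold changes between recurrence groups; a gene passes
at $|\Delta| \ge 1$ log2 unit and raw $p < 0.01$ with *no* multiplicity
adjustment — the screen's purpose is to feed a downstream intersection
with recurrent deletion regions, not to be a standalone discovery list,
and the sample sizes would not support FDR control. The candidate list is
the intersection of shared-deletion genes with under-expressed genes,
ordered genomically.

## Survival

Two dichotomization rules are provided: the within-cohort median (the
median value itself goes to the low group, so 21 distinct values split
11/10) and the reference rule, mean minus $k$ SDs of a normal-tissue
distribution (default $k = 2$), for cohorts with an external reference.
The Kaplan–Meier estimator, the two-group log-rank test, and Cox
proportional-hazards regression are implemented in the package:
Newton–Raphson with step-halving on the partial likelihood, Efron tie
handling (Breslow by option), convergence at $|\Delta \ell| < 10^{-8}$
within 50 iterations. Monotone likelihood (separation — e.g. one group
without events, a real risk at 21 patients) is detected from diverging
coefficients and *flagged*, never suppressed: the hazard ratio and Wald
interval are then reported but unstable, and the likelihood-ratio test is
the better summary. The `survival` package is used in the test suite as an
independent cross-check of all three procedures, never as the
implementation.

The region screen dichotomizes every gene in a region by the reference
rule, fits the multivariate Cox model (low-group indicator plus HBV,
grade, binary age, sex by default), ranks by coefficient p-value, and
flags genes whose smaller group holds under 5% of patients — such top
ranks rest on a handful of subjects. Covariate encodings: HBV ordinal
0/1/2 when three carrier levels exist and binary otherwise, grade and
stage ordinal, age binarized at a configurable cut (default 49).

## The synthetic cohort

The generator's defaults fix the emulated study conditions once: 21
patients, 9 recurrent within a 24-month window, the full five-specimen set
for 4 recurrent patients; donor contaminations (0.80, 0.06, 0.55, 0) for
those four, spanning near-replacement to zero (the zero case doubles as
the recipient-equals-donor negative control); tumor purity 0.8; mean depth
100 per site and per 0.5-Mb coverage bin; sequencing error $10^{-3}$; a
truncal clone (fraction 1) plus a subclone (0.55), giving primary-tumor
VAFs near 0.40 for shared/truncal and 0.22 for subclonal variants; effect
classes drawn so the nonsilent-to-silent ratio is 2.8; 1000 genes with
log-normal baselines and NB dispersion 0.1; a planted hemizygous deletion
(chr4:30–60 Mb) shared by `P_T` and `R_T` in 3 of the 4 full-specimen
patients, with a planted gene inside it under-expressed by $2^{-1.5}$ in
recurrent patients' tumors; recurrence times exponential with hazard ratio
7 for the low-expression group over a baseline hazard of 0.008/month,
chosen so the expected number of 24-month events matches the 9-of-21
design rate; administrative censoring at 24 months.

Modeling choices worth knowing: genotypes are Hardy–Weinberg at uniform
MAFs in (0.1, 0.5); depth is Poisson per site and bin; the error channel
is a symmetric alt/ref flip; inside the planted deletion the mutated
allele sits on the retained haplotype with probability 0.5, and the VAF
algebra follows the cell mixture exactly (so a retained truncal mutation
at purity 1 reaches VAF 1); indels are simulated as flagged SNVs with
extended alleles — no realignment artifacts; clones are a flat set, not a
phylogeny; counts have per-sample log-normal library factors but no batch
structure; survival covariates are drawn independently of outcome, so
adjusted and unadjusted hazard ratios estimate the same quantity.

What passing tests on this cohort do **not** show about real data: no GC
or mappability structure in coverage, no strand or context bias in errors,
no subclonal copy number, no germline relatedness between recipient and
donor, no informative censoring. The generator validates the estimators'
statistical behavior under their stated assumptions; it cannot validate
robustness to artifacts it does not model.

A note on end-to-end power: at 21 patients, a median split, and roughly
nine 24-month events, the two-group log-rank test has limited power even
at a hazard ratio of 7 — across the plausible baseline-hazard range its
rejection rate at 0.05 plateaus around three-quarters, and at the
event-rate-matched default it is lower still. Single-cohort significance
of the planted gene is therefore the expected-majority outcome, not a
near-certain one; the candidate-list recovery (deletion ∩
under-expression) is the robust part of the pipeline at this sample size.
This mirrors the motivating study design, whose 21-patient hazard-ratio
estimate carried a very wide confidence interval and reached significance
in the Kaplan–Meier analysis but only a trend after multivariate
adjustment.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open internally and in BED output; 1-based
variant positions are converted at the boundary. The variant identity key
is `(chrom, pos, ref, alt)`; multiallelic records must be pre-split.
Degenerate inputs are flagged rather than silently dropped: all-tied
dichotomization values, empty low groups, groups too small for a Welch
test, zero-total count pairs, separated Cox fits.

The test suite exercises the estimators at the scales stated in their
contracts — 500-locus panels at depth 100 for contamination recovery
(20 seeds per $\alpha$), 60-bin tracks against exhaustive segmentation
search, totals up to 30 against exact-test enumeration, 500 null
simulations for log-rank calibration, $10^4$ null genes for exact-test
calibration, and 20 full-cohort seeds for the end-to-end property —
chosen as the smallest sizes at which the asymptotic claims are expected
to hold cleanly.
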