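---
title: "Detecting recessive lethal alleles through a deficit of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recessive lethal alleles through a deficit of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
library(dplyr)
```

## The model

Genotypes that kill embryos or fetuses are depleted among living study
participants, so they cannot be found by case-control association: there
are no homozygous cases to collect. What survives in population data is an
*absence* — fewer homozygotes than the allele frequency predicts. This
package implements a scan built on that signature.

For a biallelic variant with alternate allele frequency `p_i` in population
`i` of size `n_i`, Hardy-Weinberg equilibrium (HWE) predicts `n_i * p_i^2`
homozygotes. The frequency is estimated from phased haplotypes,
`p_hat_i = (alternate haplotypes) / (2 n_i)`; for the rare variants of
interest this estimate is driven by non-carriers and heterozygotes, so a
depletion of homozygotes barely perturbs it — which is exactly why the
expected count remains a valid yardstick under selection against
homozygotes. Across cohorts the expectation adds:

    lambda = sum_i n_i * p_hat_i^2

and the observed homozygote count `O` is compared against it:

* **tested**: `lambda > 0.5` (below that the expectation is uninformative);
* **strong deficit**: `O <= 0.1 * lambda` — ten percent or less of the
  predicted homozygotes. The inclusive boundary follows the headline
  definition ("10% or less"); the strict variant differs only on
  measure-zero boundary cases.
* **Poisson test**: for rare variants `O` is approximately Poisson with
  mean `lambda`, so the one-sided deficit p-value is `P(X <= O)`,
  Bonferroni-corrected per variant class.

### Why calibrate against intergenic variants

Inbreeding and population structure inflate homozygosity, and genotyping or
imputation artifacts can deflate it; neither respects HWE. Rather than
model those forces, the scan measures them empirically in a variant class
where selection on homozygotes is negligible: intergenic variants (by
default those more than 5 kb from any annotated gene, with larger
exclusion distances — 50/100/250/500 kb — available). After grouping tested
units into half-open expected-count bins
`[0.5,1) [1,2) [2,3) [3,5) [5,8) [8,13) [13,250) [250,Inf)`, the false
discovery rate of the strong-deficit call among protein-altering variants
is

    FDR = f_intergenic / f_pav,     PPV = 1 - FDR

where each `f` is the fraction of tested variants in the bin with a strong
deficit. The machine output reports the ratio uncapped (it can exceed 1 in
noisy bins) so that PPV remains its exact complement; display output caps
it at 1. Confidence intervals for the ratio of the two deficit rates treat
the counts as independent Poisson draws and condition on their sum: a
Clopper-Pearson interval for the binomial proportion is mapped through
`theta/(1-theta) * n_pav/n_intergenic`. The originally described interval
for this estimand is an approximate one whose formula is not reproduced in
the sources available to this package; the conditional-binomial interval
targets the same estimand, is exactly testable for coverage, and its name
is recorded in the output metadata.

### Class hygiene

Linked selection can drag a neutral variant's homozygosity down with a
selected partner's. Before scanning, each variant class is pruned against
all strictly higher classes (hierarchy intergenic < low < moderate < pLOF):
a variant leaves its class when its pooled-haplotype `r^2` with any
higher-class variant exceeds 0.8. pLOFs, at the top, are never removed.
`r^2` is computed on haplotypes pooled across populations — the exclusion
is hygiene, not inference, and stratifying it buys nothing.

Variants whose alternate-allele frequency exceeds 0.5 are excluded from
testing with a warning: the scan targets rare alleles, and above 0.5 the
`p^2` expectation tracks the major allele.

### Gene-level collapsing (geneLOF)

Individually rare pLOFs gain power when pooled: for each gene, qualifying
pLOFs (high-confidence, minor allele frequency below 2%, not on a curated
exclusion list) collapse into a biallelic gene-level genotype counting how
many of an individual's two haplotypes carry at least one qualifying pLOF.
Compound heterozygotes — two different pLOFs in trans — count as knockouts
exactly like true homozygotes; two pLOFs in cis count once. The 2% bound is
assessed per population: founder populations can carry pathogenic alleles
at elevated frequencies, so each cohort is collapsed with its own
frequencies (a pooled-frequency switch exists). Missing haplotype calls
count as unaffected, which is conservative for deficit detection, and
missingness is reported per individual-gene pair. The gene-level unit then
enters the same scan: carrier-haplotype frequency per population,
`lambda = sum n_i p_i^2`, observed = both-haplotypes-affected individuals.

### Downstream inference

Gene-set over-representation among deficit genes uses the two-sided Fisher
exact test on (strong deficit vs not) x (in set vs not), stratified into
expected-count `[1,5)` and `[5,Inf)` strata. The odds ratio reported is the
conditional MLE — the noncentral hypergeometric parameter at which the
expected table cell equals the observed one — solved here to a score
residual below 1e-8; p-values follow the standard exact convention of
summing the probabilities of tables no more probable than the observed.

Carrier couples — both partners heterozygous for a qualifying pLOF of the
same gene — have a one-in-four chance per pregnancy of a homozygous
conception. If the gene's homozygotes die in utero, these couples should
miscarry in excess, and couples with a single carrier should not. The
package identifies carrier couples from the geneLOF genotypes (a partner
who is themselves homozygous disqualifies the couple from the
heterozygous-carrier category), matches each to its 100 nearest
non-carrier couples by Euclidean distance on covariates standardised by
the pool standard deviation (birth year and pregnancy count by default;
ties broken by couple id so the match is deterministic), and tests both
ever-miscarried status and the pooled per-pregnancy miscarriage rate with
the exact 2x2 machinery. The matching metric is a package choice — the
procedure it mirrors states the covariates but not the distance — and is
configurable. Per-gene tests are Bonferroni-corrected for the number of
genes tested.

## The simulator

Every stage above is validated on simulated cohorts with known truth,
because the individual-level data such scans run on are not shareable.
The generator produces, from a single seed:

* **Phased haplotypes.** Alleles are Bernoulli(p) draws with configured
  per-population frequencies, in linkage equilibrium. Inbreeding is
  modelled as whole-genome identity by descent: individual `i` copies their
  first haplotype into the second with probability `f_i`. This reproduces
  the marginal law `P(hom) = p^2 + f p (1 - p)` exactly at every variant
  while keeping a phased representation; segmental IBD is deliberately not
  modelled because the scan consumes only marginal counts. The distribution
  of `f_i` across individuals is configuration, not an estimate (the data
  this emulates do not pin it down): dispersion 0 gives a constant, and a
  Beta with matching mean otherwise.
* **Selection.** A variant with survival fraction `s` keeps each of its
  homozygotes with probability `s`; the rest are replaced by freshly drawn
  non-homozygous individuals. The replacement redraws the genotype at the
  selected variant conditional on non-homozygosity, respecting the
  individual's IBD state — under linkage equilibrium this is
  distributionally equivalent to redrawing the whole individual, keeps
  population sizes fixed, and leaves other planted variants untouched.
  Frequency perturbation is second order for rare variants.
* **Couple histories.** Couples are distinct individuals of one
  population. Double-carrier couples miscarry each pregnancy with
  probability `m0 + (1 - m0) * (1/4) * pi`, everyone else with `m0`.
  Defaults are chosen to match the scale of the questionnaire cohort the
  analysis mirrors: pregnancies per couple `1 + Poisson(1.9)` (about 2.9),
  background miscarriage 10% per pregnancy, and a 3% background rate of a
  live-born child dying before age two.

What the simulator does **not** emulate: imputation uncertainty (hard
calls only — the statistical procedure operates on called genotypes),
genuine linkage disequilibrium (an optional correlated-pair mode exercises
the `r^2` exclusion), segmental IBD, demographic history and mutation age.
Passing tests therefore demonstrate the statistical machinery, not
robustness to imputation artifacts — in real data that robustness is
exactly what the intergenic calibration is for.

## Numerical and design choices

* Bins are half-open `[lo, hi)` exactly as printed above; expected counts
  at or below 0.5 are rejected from binning rather than silently dropped.
* Empty class-bin cells report `NA` fractions (unavailable), never zero.
* The conditional-MLE solver works on `log(psi)` with bracketed bisection
  (`uniroot`, tol 1e-12); observed cells on the edge of the conditional
  support give 0 or `Inf`, and degenerate margins give `p = 1` with an
  unavailable odds ratio.
* Monotonicity holds by construction: lowering `O` or raising `lambda`
  never un-flags a strong deficit.
* Coordinates: VCF positions are 1-based inclusive; BED masks are 0-based
  half-open; the conversion lives in one place. Distance to the nearest
  gene is measured in base coordinates (a variant 6 kb past a gene end is
  6000 bases away, not 5999).
* Multiallelic VCF records are decomposed, each alternate allele tested
  independently. Unphased genotypes are a hard error naming the record;
  `./.` is missing data, not a phase violation.

## Problem sizes used in validation

The bundled validation suite simulates two populations of 100,000
individuals with 2,000 neutral variants (split between intergenic and pLOF
with identical expected-count profiles) plus 50 fully lethal pLOFs planted
at expected counts between 6 and 30 — comfortably above the five-homozygote
detectability boundary, so that sampling noise on the estimated frequencies
cannot move a planted variant out of its stratum. Couple analyses use a
250,000-individual population (about 150 double-carrier couples per
replicate at a 1.8% allele frequency) with 20 simulation replicates, and
interval coverage uses 2,000 Poisson replicates. These sizes were chosen so
each property is measured with standard errors several times smaller than
the acceptance bands while a full run stays in the tens of seconds.

## A worked example

```{r example}
pops <- rbind(population_spec("iceland", 30000), population_spec("norway", 20000))
vars <- rbind(
  sim_variants(400, "intergenic", freq = sqrt(seq(1, 25, length.out = 400) / 50000),
               populations = c("iceland", "norway"), prefix = "int"),
  sim_variants(400, "plof", freq = sqrt(seq(1, 25, length.out = 400) / 50000),
               populations = c("iceland", "norway"),
               gene = sprintf("G%04d", 1:400), prefix = "neu"),
  sim_variants(5, "plof", freq = sqrt(seq(8, 20, length.out = 5) / 50000),
               populations = c("iceland", "norway"),
               gene = sprintf("G%04d", 401:405),
               survival_fraction = 0, prefix = "let")
)
cfg <- sim_config(pops, vars, gene_count = 405, seed = 2718)
panel <- simulate_haplotype_panel(cfg) |>
  apply_recessive_selection(seed = 2719)

scan <- deficit_scan(panel)
scan |> filter(strong_deficit) |> arrange(p_poisson) |> head()
```

The five planted lethals surface with `observed = 0` at their expected
counts; the FDR calibration confirms the neutral classes agree:

```{r fdr}
fdr <- fdr_calibrate(scan)
fdr |>
  filter(class == "plof", n_tested > 0) |>
  select(bin, n_deficit, n_tested, ref_fraction, fraction, fdr, ppv)
```

## Limitations

* The intergenic calibration assumes artifacts hit intergenic and
  protein-altering variants alike; systematic artifacts specific to coding
  sequence would evade it.
* Frequencies come from hard haplotype calls; dosage-weighted carrier
  expectations from imputation are accepted through an optional column but
  are not the default path.
* The scan detects *absence* and cannot distinguish embryonic lethality
  from severe early-life morbidity that prevents study participation;
  the carrier-couple analysis exists precisely to separate pregnancy loss
  from later mortality.
* Power is bounded by frequency: with 1.52 million individuals the
  detectability floor sits near a 0.18% MAF for pLOFs (five expected
  homozygotes); most recessive lethals are thought to be rarer.
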