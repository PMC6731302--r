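---
title: "Partitioning trait heritability across transposable-element annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait heritability across transposable-element annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teldsc)
```

## The model and its assumptions

`teldsc` estimates how the SNP heritability of a complex trait distributes
across overlapping genomic annotations — here centred on transposable
elements (TE), but nothing in the machinery is TE-specific. The model is the
stratified LD score regression: per-SNP heritability is assumed additive
over annotation memberships,

$$\mathrm{Var}(\beta_j) \;=\; \sum_c a_{cj}\,\tau_c,$$

where $a_{cj}$ is SNP $j$'s value for annotation $c$ (binary or continuous)
and $\tau_c$ is the annotation's per-SNP contribution. Because a GWAS
chi-square statistic at SNP $j$ picks up every causal SNP the marker tags
through linkage disequilibrium, the estimable regression is

$$\mathrm{E}[\chi^2_j] \;=\; N \sum_c \ell(j,c)\,\tau_c + 1,
\qquad \ell(j,c) = \sum_k a_{ck}\, r^2_{jk},$$

with $N$ the GWAS sample size and $r_{jk}$ the genotypic correlation in a
reference panel. The key assumptions are (i) additivity of per-SNP variance
in the annotations — flank annotations (below) guard the estimates where
this is locally misspecified; (ii) that the reference panel's LD matches the
GWAS population's; and (iii) a polygenic architecture, protected in real
data by capping very large chi-square statistics.

From one fit the package derives, for each annotation: the observed share of
heritability $\%h^2_g(c) = \sum_j a_{jc}\mathrm{Var}(\beta_j)/h^2_g$ and its
**enrichment** (that share over the annotation's share of common SNPs; 1
means "no different from a random SNP", values below 1 are depletions and
are reported as-is, including negative point estimates); the **standardized
effect size**

$$\tau^*_c = \frac{\tau_c \,\mathrm{sd}(c)}{h^2_g / M},$$

the change in per-SNP heritability per standard deviation of the annotation
in units of the genome-wide mean per-SNP heritability — unlike enrichment it
measures only signal *unique* to the annotation, conditional on everything
else in the model; and the **expected enrichment**, the enrichment implied
for a focal annotation by a conditioning model fitted *without* it (its own
$\tau$ set to zero). Observed above expected means the annotation carries
heritability beyond what its overlap with the conditioning annotations
explains.

All standard errors come from a genomic block jackknife: the regression SNPs
are cut into 200 contiguous blocks with equal SNP counts, the fit is redone
leaving each block out, and every derived quantity (enrichment, $\tau^*$,
expected enrichment, excess overlap) is recomputed per leave-one-out fit so
that ratio nonlinearity is propagated honestly. Enrichment is tested against
1 by a jackknife-t with 199 degrees of freedom; $\tau^*/\mathrm{se}$ is
referred to the standard normal.

## Annotation construction

Interval inputs (BED tracks, RepeatMasker `.out` files) are converted to SNP
annotations under one convention, stated once and tested: intervals are
0-based half-open $[\mathrm{start}, \mathrm{end})$, SNP positions are
1-based, and a SNP at position $p$ lies inside iff
$\mathrm{start} < p \le \mathrm{end}$. On top of plain membership the
package builds:

* **flank annotations** — SNPs within a window of an element boundary but
  outside every element (default 500 bp; 100/200/500/1000 available). Every
  focal annotation should enter a joint fit together with its flank, so
  that boundary misspecification is absorbed by the flank's own
  coefficient.
* **age quintiles** — each TE-resident SNP inherits its element's milliDiv
  score (mutations per kilobase against the element consensus; larger =
  older). SNPs covered by elements that disagree take the older value by
  default (`younger`/`mean` by flag; the choice only matters for nested or
  overlapping elements). Quintile cuts are ranks of the per-SNP milliDiv
  distribution — per-element cuts are available by flag, since either
  reading of "quintiles of TE age" is defensible.
* **k-mer footprints** — all genomic windows within a Hamming distance
  (0 or 1) of a query k-mer, scanned on both strands via
  `Biostrings::matchPattern` and property-tested against a naive full scan.
  Ambiguity codes count as mismatches. Both-strand scanning is an
  assumption: motif occurrence is taken as strand-symmetric, matching a
  read-mapper-based definition of "region matching the k-mer".
* **mappability restriction** — the `-unique` companion of an annotation
  keeps only SNPs whose 35-mer mappability value at the SNP position equals
  1. Position-value lookup (rather than any-overlapping-35-mer) is the
  implemented reading; positions absent from the track count as
  non-unique.
* **random controls** — annotations with exactly the template's interval
  length multiset, placed uniformly, resampled (up to 100 times) until the
  control's %SNPs is within 10% relative of the template's. Controls match
  length only — not GC, gap content or chromatin context — because their
  job is to be size-matched and otherwise unconstrained nulls.

Annotations spanning less than 0.4% of common SNPs are tagged
*expected-only*: the stratified regression is unreliable for very small
annotations, so `observed_enrichment()` refuses them (unless forced) and
`expected_enrichment()` is the supported summary.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| LD window | 1 Mb one-sided | bases | physical stand-in for the conventional 1 cM window when no genetic map is supplied |
| r² adjustment | $r^2 - (1-r^2)/(n_\mathrm{ref}-2)$ | — | approximately unbiased for $\rho^2$; without it, panels of a few hundred samples inflate every LD score and break null calibration |
| jackknife blocks | 200 | blocks | equal *SNP-count* contiguous blocks (equal-bp available); block length must exceed the LD correlation length for the jackknife to be valid |
| regression weights | on | — | product of an overcounting weight $1/\max(1, \ell_\mathrm{tot})$ and a heteroskedasticity weight $1/(2(N\ell_\mathrm{tot}\bar\tau + 1)^2)$, one re-weighting pass; switchable to unweighted |
| intercept | free | — | the model's "+1" is recovered as a fitted value; constrainable to 1 |
| chi-square cap | $\max(80, 0.001N)$ | — | excludes outlier association statistics (and the MHC region) in real-data analyses |
| MAF threshold | 0.05 | — | "common SNPs": the heritability set over which $M$, sd(c) and %SNPs are computed |
| size gate | 0.4% of common SNPs | — | below it only expected enrichment is reported |

Two defaults deserve comment. The **free intercept** is right for real data,
where confounding inflates the test-statistic null. In *simulation*
analyses, however, the intercept is exactly 1 by construction, and at desk
scale (thousands of SNPs) the intercept column is nearly collinear with the
all-SNPs LD score, which destabilizes the base coefficient and hence the
heritability denominator of every enrichment ratio; the calibration studies
below therefore fix the intercept at its model-true value. Likewise the
**chi-square cap** exists to protect real analyses from non-polygenic
outliers; in model-faithful simulations with a few thousand SNPs the
per-SNP signal is legitimately large, so the cap is disabled there
(`chisq_cap = FALSE`) — applying it would truncate genuine signal.

## The synthetic cohort generator

The generator emulates the essential structure of a GWAS cohort. Haplotypes
are Gaussian-copula latents: within an LD block, latent correlation decays
as $\rho^{|j-k|}$; thresholding at the allele-frequency quantile gives the
haplotype alleles, and two haplotypes sum to the diploid dosage. This gives
closed-form control of LD while respecting allele frequencies. Note that
thresholding *attenuates* correlation: latent decay 0.9 yields observed
adjacent-dosage $r^2 \approx 0.51$ at MAF 0.5 (about 0.38 at MAF 0.05), not
$0.9^2$; the test suite freezes the attenuated values, which were verified
by brute-force simulation at $n = 10^5$. Effect sizes follow the
annotation-additive model exactly (or a flat polygenic mode
$\beta \sim N(0, h^2_g/n_c)$ in which total genetic variance is $h^2_g$ by
construction), phenotypes are $Y = X\beta + e$ with standardized $X$ and
$e \sim N(0, 1-h^2_g)$, and summary statistics are marginal-regression
chi-squares. All randomness flows from one config seed through named
substreams, so identical configs are bit-reproducible.

What the generator does **not** emulate: realistic minor-allele-frequency
spectra (frequencies are uniform on a range), population structure and
relatedness, imputation error, genetic maps (LD blocks are index-defined),
case/control ascertainment, and the 10-Mb-scale LD of real genomes. Passing
calibration on synthetic cohorts therefore demonstrates the estimator's
statistical correctness under its own model — not robustness to the
confounders real data add, which is what the intercept, the chi-square cap
and the flank annotations are for.

## Calibration study conditions

The packaged experiments (test suite and `scripts/acceptance.R`) run at:
$N = 20{,}000$ individuals, $M = 2{,}000$ SNPs at 1 kb spacing, 100 LD
blocks of 20 SNPs with latent decay 0.7, MAF $\sim U(0.05, 0.5)$,
$h^2_g = 0.5$, a focal annotation on 10% of SNPs with 5× per-SNP variance
(generating enrichment $5/1.4 = 3.57$), a 1,000-individual LD reference
subsample, 200 jackknife blocks, fixed intercept. The genotype panel is
generated once per experiment and the trait (effects + environment) redrawn
per replicate, matching the fixed-genotype replicate design of reference
simulations. With decay 0.7 the LD correlation length (2–3 SNPs) sits well
below both the jackknife block length (10 SNPs) and the LD-block length, so
block resampling is valid. Under these conditions the enrichment estimate
covers its generating value within 3 jackknife SEs in 20/20 replicates, the
jackknife SE matches the empirical SD across replicates (ratio ≈ 1.0 over
50 replicates), random size-matched controls give 95% CIs covering
enrichment 1 and $\tau^* = 0$ at nominal rates, and observed and expected
enrichment agree within 3 SEs whenever the focal annotation's true $\tau$
is zero given the conditioning set.

One experimental-design subtlety: null coverage of "enrichment = 1" is only
meaningful over *replicated traits*. For one fixed draw of effect sizes,
the realized heritability share of a 200-SNP control annotation fluctuates
around 10% with a ~10% coefficient of variation, so a single trait tested
against many controls would mix estimator error with architecture
realization. Each control replicate therefore draws a fresh trait.

## Numerical choices and degenerate inputs

* Noiseless inputs ($\chi^2 = N\ell\tau + 1$ exactly) are recovered to
  numerical precision for any weight choice; the weighted least squares is
  solved by normal equations with per-block moment caching, so the 200
  leave-one-out refits are exact downdates, not approximations.
* Rank-deficient designs (duplicate annotations) are rejected naming a
  collinear pair. Constant annotations get $\tau^* = 0$ with a warning
  (sd = 0). A non-positive estimated $h^2_g$ makes $\tau^*$ `NA` with a
  warning rather than an error, so pipeline runs on weak traits complete.
* Monomorphic SNPs are excluded from reference panels (logged); zero-variance
  SNPs are excluded from summary statistics (logged).
* Ties in element age at overlapping elements resolve to the older element
  by default; the alternative readings are flags, not silent choices.
* Excess overlap of annotation $A$ with itself is $M/|A|$ by construction;
  leave-one-out blocks that empty an annotation contribute the full-sample
  value to the jackknife rather than an infinity.
* Meta-analysis uses DerSimonian–Laird pooling (via `metafor`), reducing to
  inverse-variance fixed effects when the between-trait variance estimate
  is zero; a single trait is passed through with a warning. When two data
  sets measure the same trait, only the larger-$N$ one enters
  (`dedupe_traits()`); detecting duplicates (e.g. by genetic correlation)
  is input metadata, not computed here. The trait-class contrast is an
  unpaired z on the two pooled means — an assumption, since nothing pins
  down a pairing between classes.

## Known limitations

Per-chromosome LD-score computation is in-memory (no out-of-core
streaming); there is no genetic-map interpolation (the window is physical);
no liability-scale case/control phenotypes, imputation or relatedness in
the generator; no MAF-bin "expected (MAF+LD)" denominator variant; and the
baseline-LD-style conditioning annotations are consumed as a precomputed
matrix, not derived. The quintile, mappability and strand conventions noted
above are documented choices where the field's descriptions are ambiguous.
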