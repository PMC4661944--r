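---
title: "Haplotype-based QTL mapping in Collaborative Cross cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based QTL mapping in Collaborative Cross cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccqtl)
```

## The problem and the data model

The Collaborative Cross (CC) is a panel of recombinant inbred mouse lines
descended from eight founder strains (A/J, C57BL/6J, 129S1/SvImJ,
NOD/ShiLtJ, NZO/HlLtJ, CAST/EiJ, PWK/PhJ, WSB/EiJ).  Each line's genome is
a near-homozygous mosaic of founder haplotypes, and because every line can
be phenotyped repeatedly, modest cohorts (a few dozen lines, a handful of
animals each) support genome-wide association at a mapping resolution of
1-2 Mb.  `ccqtl` implements the analysis workflow for such cohorts:

1. broad-sense heritability and covariate effects from nested linear
   models;
2. a weighted genome scan of covariate-adjusted line means on founder
   descent probabilities, with permutation-derived genome-wide thresholds
   and regional heritability at each called locus;
3. merge analysis -- imputing catalogued variants from founder
   probabilities and their strain distribution patterns (SDPs) to nominate
   candidate causal variants;
4. simulation-based confidence intervals for QTL location;
5. a synthetic cohort generator with known ground truth, used by the test
   suite to validate every stage.

The central data object is the founder probability tensor: for each line
and marker, eight non-negative dosages of descent from each founder,
summing to 2 (the additive, diploid collapse of the founder-pair descent
probabilities).  The package consumes such tensors directly; inferring
them from array genotypes by hidden-Markov reconstruction is out of scope.

## Heritability from nested residual sums of squares

For a trait $y$ measured on animals grouped into lines, three nested
least-squares fits are compared: the null model $F_{00}$ (intercept only),
the covariate model $F_0$ (intercept, sex, age), and the line model $F_1$
(covariates plus the line label as a fixed factor).  Broad-sense
heritability is the RSS ratio

$$H^2 = \frac{RSS(F_0) - RSS(F_1)}{RSS(F_{00})},$$

with significance from the ANOVA $F$ test of $F_1$ against $F_0$.  The
line label is a *fixed* factor: this matches the RSS arithmetic above, and
no variance-component (REML) estimator is provided -- the RSS ratio is the
estimator this workflow defines.  Two conventions follow the published
practice for such tables: reported $-\log_{10}P$ values ("logP") are
clamped at 15, and a constant trait yields $H^2 = 0$ with a degeneracy
flag.

Covariate effects are analogous RSS fractions.  Here the literature
definition is ambiguous: the covariate effect is described as fitting each
covariate *separately*, yet the printed expression,
$(RSS(F_{00}) - RSS(F_1))/RSS(F_{00})$, involves the full line model and
therefore absorbs the genetic variance into the "covariate" effect.  Both
readings are implemented in `covariate_effect()`: the default `"single"`
mode fits intercept + the one covariate and reports
$(RSS(F_{00}) - RSS(F_{0,\mathrm{single}}))/RSS(F_{00})$, which is a pure
covariate quantity; the `"strict"` mode reproduces the printed expression
verbatim.  The discrepancy is surfaced here rather than silently resolved.

An important property of the fixed-factor RSS estimator at small
within-line replication: with $k$ lines and $r$ animals per line, the line
factor absorbs noise worth $(k-1)$ of roughly $rk$ residual degrees of
freedom, so the *expected estimate* exceeds the population variance
fraction.  The generator therefore calibrates its line-level variance to a
*target estimate* by inverting the balanced one-way ANOVA moments
(`line_sd_for_h2()`); at the 31 x 5 design a target of 0.2 is close to the
noise floor of the estimator, which is why published CC heritabilities
below ~0.2 should be read with care.

## The haplotype scan

Line means are adjusted for covariates (residuals of $F_0$ plus the grand
mean) and regressed, at every marker, on the founder dosage columns with
weights equal to the per-line animal counts.  Because the eight dosages
sum to 2, the founder effects are only identified up to a constant; the
WSB/EiJ column is omitted so that all effects are expressed relative to
WSB and $\hat\beta_{WSB} = 0$ exactly.  The marker's logP is the
$-\log_{10}P$ of the $F$ test of this 8-parameter weighted fit against the
weighted-mean null.  A rank-deficient marker (founder descent monomorphic
across the cohort) is reported at logP 0 rather than an error.

Scanning *line means* rather than animal-level rows, with line sizes as
weights, is a deliberate choice: the line is the unit of genetic
replication, and the weighting recovers the information lost by
averaging.  No kinship/mixed-model correction is applied -- CC lines are
(nearly) equally related by design, and the emulated workflow did not use
one.

Genome-wide significance is empirical: the line labels of the mean vector
are permuted (weights travelling with their means, so the weight-design
pairing is broken consistently), the genome is rescanned, and the maximum
logP recorded; thresholds are percentiles of that null maximum
distribution over (by default) 200 permutations.  The permutation unit is
the *line*, the exchangeable unit under the null of no genetic effect;
animal-level shuffling would break the within-line correlation structure
and anticonservatively narrow the null.

QTL calls are contiguous super-threshold runs, one call per run at its
maximum, ties broken to the lowest bp.  Two runs on one chromosome remain
separate calls only when the valley between them dips below the
95th-percentile threshold; otherwise they merge -- this keeps genuine
proximal QTL pairs apart without fragmenting a single broad peak.
Regional heritability at a call is the heritability RSS ratio recomputed
with the peak marker's founder dosages (animal-level, covariates
retained) in place of the line factor.

`subset_scan_sweep()` exposes, as an explicit logged procedure, the
practice of rescanning on subsets of lines (never fewer than 28) to
detect loci masked by particular lines; the maximising subset is reported
alongside all others, never silently substituted for the full-cohort
scan.

## Merge analysis

A catalogued variant partitions the eight founders by the allele each
carries (its SDP).  The expected dosage of allele $a$ in line $L$ is the
sum of the line's founder dosages over the founders carrying $a$, taken at
the marker nearest the variant (the assignment distance is recorded; the
underlying workflow does not specify how inter-marker variants map onto
the pruned grid, so nearest-by-bp is used and surfaced in the output).
This is exactly the additive collapse of the founder-pair double sum
$G_{pi}(a,b) = \sum_{s,t} X_p(a,s) X_p(b,t) F_{Li}(s,t)$, and the test
suite checks the equivalence against the brute-force pair sum.

The merged model regresses the weighted line means on $k-1$ allele dosage
columns ($k$ alleles, most frequent allele as reference).  Since these
columns are linear combinations of the founder columns, the merged model
is a sub-model of the haplotype model: its RSS is never smaller (asserted
at run time), but with fewer parameters it can reach a *higher* logP --
and a variant whose merged model matches or exceeds the haplotype peak
logP is consistent with being the causal variant.  `candidate_filter()`
applies exactly that filter.  Variants whose total imputed minor-dosage
mass across lines is below 0.5 are flagged monomorphic and not tested.

## Confidence intervals for QTL location

The primary method resamples residuals at the peak: permute (without
replacement) the residuals of the peak-marker weighted fit, re-attach
them to the fitted genetic values, rescan the markers within ±5 Mb of the
peak, and record the argmax position; over `n_sim` (default 1000)
replicates the central L% of the argmax distribution is the level-L
interval.  Quantiles are inverse-ECDF (type 1), so endpoints land on
marker positions, and the interval is widened if needed to contain the
peak; nesting of the 50/90/95% intervals is asserted on every run.

Two documented ambiguities in the source workflow are handled explicitly:

* *Recombination formula.*  The published resampling formula multiplies
  the permuted residual by an exponentiated fitted value,
  $Z_{iK} = \hat t_i \exp(\hat\mu + \sum_s X_{Kis}\hat\beta_s)$, which is
  dimensionally surprising for a trait measured on a linear scale and is
  most plausibly a typesetting artifact of $\hat t_i + (\cdot)$.  The
  default mode is additive (`fitted + permuted residual`); a
  `"multiplicative"` mode implements the printed form.  No attempt is made
  to guess further -- both are exposed, the default is logged in the
  pipeline run log.
* *Neighborhood width.*  The source text gives both "within 7-10 Mb" and
  "3.5 to 5 Mb"; the per-side reading (±5 Mb) is the default and the
  parameter is configurable.

`qtl_ci_li()` provides the quick comparison method: a closed-form
profile-support interval that walks out from the peak until the logP
drops by $\chi^2_1(L/100) / (2\ln 10)$.  The cited quick method is not
restated in the source workflow, so this standard chi-square calibration
of the profile drop is used; it is flagged `method = "li2011"` and is
intended only as a cross-check of the simulation intervals (they should
correlate, with the profile intervals typically slightly wider on sparse
marker grids).

## The synthetic cohort generator

The generator produces the study conditions the package is validated
under, not a tunable benchmark:

* **Design**: 31 lines, 5 mice per line, sexes drawn at 86M:74F, ages
  uniform on 10-13 weeks.
* **Genomes**: founder mosaics with a homogeneous Poisson breakpoint
  process at 0.05 breakpoints/Mb per line (the density observed in
  genotyped CC genomes, ~135 events per 2.5 Gb); founders uniform per
  segment.  The true CC breakpoint process (funnel structure,
  interference) is not modelled -- scan correctness does not depend on
  it.
* **Heterozygosity**: lines are assigned inbreeding generations 11-37;
  the residual heterozygous fraction decays geometrically from 0.20 at
  generation 11 to 0.001 at generation 37 (matching the 80-99.9%
  homozygosity range of such cohorts) and is realised as intervals
  carrying one dose each of two founders.
* **Descent uncertainty**: within ±200 kb of a breakpoint, dosage is
  linearly interpolated between the flanking founders (1/1 at the
  breakpoint itself), emulating the short uncertainty window of
  haplotype reconstruction.
* **Traits**: grand mean 12, male offset +3, age slope 0.3/week,
  line-level polygenic SD 3.5, residual SD 2.5 -- a BV/TV-like trait
  (per cent scale) spanning roughly 2-30 with heritability near 0.6 at
  the 31 x 5 design.  QTL are additive founder-effect vectors with the
  WSB entry fixed at 0.
* **Variant catalogue**: SDPs uniform over non-constant assignments,
  biallelic by default with a 20% multiallelic fraction.
* **Mendelian control**: an albino-like recessive variant (carried by
  the four classically albino founders) thresholds the imputed causal
  dosage into a binary line trait, providing a positive-control scan
  scenario.

Coordinates are 0-based half-open bp; markers are points; all randomness
flows through explicit seeds, with compound generators deriving sub-seeds
by fixed offsets.

What the generator does *not* emulate -- and what passing tests therefore
do not certify on real data: genotyping error and HMM reconstruction
artifacts; the X/Y chromosomes; funnel-correlated founder sharing between
lines; non-additive (dominance, epistatic) QTL; non-Gaussian trait
distributions.

## Problem sizes and numerical choices

The validation suite runs on a reduced genome of 10 chromosomes x 100 Mb
with 1 marker/Mb (~1,000 markers), a scale at which the 200-cohort
calibration studies (each with a 200-permutation threshold, or a
200-replicate CI) complete in minutes while preserving every structural
property of the full-genome analysis; the Mendelian control uses a 4 Mb
grid, at which flanking recombinations localise a noiseless binary trait
to within two markers.  Dosage sums are validated to 1e-9; oracle
equivalence of the scan's compiled path against explicit normal equations
is required to 1e-8, and of imputation against the founder-pair double
sum to 1e-12.  Rank-deficient designs fall back to a pseudoinverse fit
with the effective rank entering the F-test degrees of freedom.  Marker
pruning averages founder columns over non-overlapping windows of
consecutive markers and renormalises rows to 2, with the window-midpoint
bp as the representative position.

## A worked example

```{r example, eval = FALSE}
library(ccqtl)
cohort <- sim_cohort(seed = 1,
                     model = cc_trait_model(
                       qtl = list(list(marker = "m_2_0050",
                                       beta = c(0, 0, 0, 0, 0, 0, 2.5, 0)))))
h <- heritability(fit_nested_models(cohort$phenotypes, "BVTV"))
m <- adjusted_line_means(cohort$phenotypes, "BVTV")
scan <- scan_haplotypes(m, cohort$tensor)
th <- perm_thresholds(m, cohort$tensor, n_perm = 200, seed = 2)
calls <- call_qtls(scan, th)
ci <- qtl_ci_sim(m, cohort$tensor, calls[1, ], n_sim = 1000, seed = 3)
dos <- impute_dosages(cohort$tensor, cohort$catalogue,
                      region = list(chrom = calls$chrom[1],
                                    start_bp = calls$peak_bp[1] - 5e6,
                                    end_bp = calls$peak_bp[1] + 5e6))
mg <- merge_scan(m, dos, scan = scan)
candidate_filter(mg, calls$peak_logp[1])
```

`run_pipeline()` chains the same stages, writes every artifact as TSV and
a JSON run log (seed, config echo, timings, the decision flags above),
and is byte-reproducible given its seed.

## Known limitations

* The fixed-factor RSS heritability is design-dependent (see above); it
  is the estimator this workflow defines, not a variance-component
  estimate.
* Nearest-marker variant assignment degrades when the marker grid is
  much sparser than the catalogue; the recorded assignment distance
  should be checked before interpreting merge logP at isolated variants.
* The profile-support ("quick") intervals inherit the marker grid's
  granularity and are unreliable on chromosomes with few markers; the
  simulation intervals are the primary method.
* Scans assume autosomes; sex-chromosome dosage is not modelled.
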