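---
title: "hapcohort: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hapcohort: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind each stage of the
package, the tunable parameters and why their defaults are what they are,
what the synthetic cohort generator does and does not emulate, and the
numerical choices made where the methodology was genuinely open.  It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The synthetic cohort: a stated world

The generator encodes the statistical structure of a low-frequency
regulatory-haplotype locus in a stratified case-control design:

* **Haplotype panel.** Three nested haplotypes over `n_sites = 19`
  biallelic SNVs: HAP1 is all-reference, HAP3 all-alternate (Hamming
  distance 19), and HAP2 carries the alternate allele at the first
  `n_hap2_diffs = 15` sites.  The nesting forces distance additivity
  (15 + 4 = 19) and, downstream, the HAP1–HAP2–HAP3 chain topology of the
  median-joining network.  Which 15 of the 19 sites distinguish HAP1 from
  HAP2 is not identified by the locus literature; the first-`k` convention
  is an arbitrary but harmless choice because every statistic used is
  invariant to site permutation.
* **Stratum frequencies.** Three strata named EA/AA/AS with default
  case/control sizes 773/576, 182/181 and 160/160.  Control haplotype
  frequencies are EA (0.55, 0.35, 0.10), AA (0.15, 0.70, 0.15),
  AS (0.20, 0.65, 0.15): the protective haplotype common in EA and rarer
  elsewhere, the risk haplotype low-frequency (0.10–0.15) everywhere.
  These are plausibility choices fixed once, not fitted values.
* **Case sampling.** Retrospective (case-control) sampling: each
  haplotype with a stated odds ratio gets the carrier-odds transform
  `f' = f·OR / (f·OR + 1 − f)`; haplotypes without a stated OR absorb the
  residual mass in proportion to their control frequencies.  This makes
  the per-haplotype carrier-chromosome OR *exact by construction*
  (e.g. control frequency 0.10 at OR 1.5 gives case frequency 1/7), which
  is what lets parameter-recovery tests pin their targets.  Defaults:
  OR(HAP3) = 1.5 (risk), OR(HAP1) = 0.7 (protective).
* **Genotypes** are always the exact sum of the two drawn haplotypes'
  allele vectors (an invariant asserted in tests).  An optional per-site
  mutation rate (default 0) creates rare recombinant-like network
  intermediates; it is off by default so the OR construction stays exact.
* **Expression.** The target gene follows
  `baseline − effect_per_score × score + N(0, noise_sd)` with score
  HAP1 = 0, HAP2 = 1, HAP3 = 2 summed over the two copies.  Defaults
  baseline 10 RPKM, effect 1, so risk homozygotes (score 4) sit at 6 RPKM,
  a 40% reduction.  `noise_sd = 1` (10% CV at the baseline) is a
  realistic residual for a moderately expressed gene.  Twenty DE genes at
  fold 2 between cases and controls, and a reference-stable pool sharing a
  common mean and variance, complete the matrix.
* **Serology.** Log-normal antigen backgrounds (sdlog 0.5) times a
  per-sample array factor that is also carried by the `__control__`
  channel, so control-channel normalization removes it exactly; designated
  antigens are multiplied by their shift (default Sm × 6) in risk
  homozygotes.

**What a green test establishes — and what it does not.** The generator
emulates frequencies, odds ratios, dose effects and multiplicative assay
artifacts.  It does *not* emulate realistic LD decay beyond the
three-haplotype (+ mutation) model, genotyping error, batch structure,
library-size or gene-length effects in RPKM, count noise, or antibody
cross-reactivity.  Recovery of a parameter here demonstrates correctness of
the estimator under the stated model, not robustness to the full messiness
of real cohort data.

## 2. Quality control

Sample filters retain `call_rate ≥ 0.85` and `mean_depth ≥ 25`: the
thresholds are phrased as exclusions ("< 85%", "< 25×"), so boundary values
are kept.  The Hardy–Weinberg filter excludes variants with control-group
exact-test p < 0.001; the exact test enumerates all heterozygote counts
compatible with the allele counts (Levene–Haldane conditional distribution)
and sums the probabilities of tables no more probable than the observed one
(no mid-p).  The exact test is the default because low-frequency variants
dominate a locus like this and the χ² approximation is unreliable in sparse
cells; the χ² variant is available for speed.  HWE is tested per stratum
(minimum p across strata) since pooling controls across ancestries would
itself induce Wahlund-type departures; pooled mode is a flag.  The common
threshold is MAF ≥ 0.05 (inclusive).

## 3. Single-variant association

The allelic test is the Pearson χ² on the 2×2 allele-count table with the
Haldane–Anscombe +0.5 correction (all cells) for the OR when any cell is
zero, and a Woolf confidence interval.  Genomic control uses the
median-based estimator λ = median(χ²)/0.4549364 and divides the statistics
when λ > 1 only (no deflation, the standard convention).  Which variants
enter the λ estimate is configurable (`lambda_on`), defaulting to common
variants.  Note that in a single-locus panel where most variants tag a true
signal, λ estimates reflect genuine association, not just stratification —
the calibration tests therefore use a null simulation.  BH-FDR is the
step-up rule with enforced monotonicity.  The CMH statistic is computed
without continuity correction by default (the original software's default
is unknowable; the corrected variant is a flag).  Sex correction is
exposed as stratified CMH by sex rather than logistic regression, matching
the stratified-analysis framing; logistic modelling is a non-goal.
Conditional analysis re-tests every variant with CMH strata defined by the
peak variant's genotype classes.

## 4. Haplotype estimation and association

`em_haplotype_frequencies()` is a maximum-likelihood EM under
Hardy–Weinberg pairing.  Phase enumeration is progressive (site by site):
each sample carries its compatible ordered partial-haplotype pairs, and
when the global pair count passes `prune_trigger` (20,000) an interim EM
fit prunes pairs whose posterior falls below `prune_tol` (1e-6) of the
sample's best pair.  On small problems no pruning ever triggers, so the
algorithm reduces exactly to full enumeration — this is what the
2-site brute-force-grid oracle tests exercise.  At 19 sites the progressive
scheme is what makes the ~2600-sample default cohort tractable; the
alternative (full 2^18-pair enumeration for a HAP1/HAP3 heterozygote) is
not.  Missing genotypes are marginalized in the enumeration; samples
missing more than 20% of tag sites are excluded.  Initialization is the
product of single-site allele frequencies; convergence at max |Δf| < 1e-8
or 1000 iterations; the observed-data log-likelihood is asserted
non-decreasing every iteration.  All-double-heterozygote data sit exactly
at the likelihood-flat 0.25 saddle under this init, and the output is
flagged `low_confidence` (mean best-pair posterior < 0.6).

Haplotype association rounds expected chromosome counts to integers
(Haploview-style) before the per-stratum 2×2 tests, combined across strata
with the CMH machinery; fractional-count mode is a flag.  Estimated
haplotypes are labelled by Hamming-nearest panel matching (ties to the
lexicographically first label) with an `OTHER` fallback beyond
`max_mismatch = 2` — nearest-match without a cutoff would force every
mutation-generated stray onto a panel label.  Diplotype assignment is the
maximum-posterior phase; the dose trend is a linear regression of
case status on the additive score, chosen over rank-based trend tests
because it is closed-form, deterministic, and matches the dose-effect
framing.

## 5. Median-joining network

The construction iterates: (1) a minimum-spanning network — all
Kruskal-minimal links between components under Hamming distance, relaxed by
ε (default 0, the parsimony-favouring choice) — then (2) sitewise-majority
(Steiner) medians of connected triplets (two linked pairs), added as
zero-frequency nodes, until no novel median appears; finally medians on no
shortest path between observed haplotypes are removed.  Majority ties
resolve toward the reference allele, deterministically.  Nodes are sorted
canonically by bit-vector before iteration, so shuffled input yields the
identical graph.  An exhaustive-triplet mode exists for tests.  Reduced
median networks, weighted sites and layout are out of scope; export is
GraphML/DOT via igraph.

## 6. Expression analyses

cis-eQTL regression uses a per-gene rank-based inverse-normal transform
(`qnorm((rank − 0.5)/n)`) followed by OLS residualization against
covariates (sex, stratum), then simple regression on allele dose.  The
inverse-normal front end buys invariance to monotone transforms of raw
expression; it also means a covariate that *fully* determines expression
leaves exactly zero residuals only when expression is constant within
covariate classes (tied ranks).  The t statistic is reported (Z and t are
interchangeable at these panel sizes).  Stimulation state is treated as a
separate analysis stratum, not a covariate.

The internal-standards DE procedure works on log2(RPKM + 0.1):

1. **Reference group**: candidates with mean RPKM > 2; genes whose
   variance exceeds the pooled candidate variance by a one-sided F test at
   α = 0.05 are dropped iteratively until stable (only high variance is
   penalized — low variance is the desired property).  Fewer than 20
   survivors is an error: the residual pool could no longer calibrate the
   associative test.
2. **Two-step normalization**: per-sample median alignment over the
   reference genes, then inversion of the per-sample affine distortion
   fitted against the *model's fixed* mean reference profile.  Fitting
   against the fixed profile (rather than one recomputed from the current
   matrix) is what makes the procedure exactly idempotent.  When the
   reference profile is flat (R² < 0.3), the slope is unidentifiable and
   only the shift is removed — this situation arises by construction with
   the generator's common-mean stable pool.
3. **Tests and filters**: pooled-variance Student t between groups
   (p < 0.05), the associative t of the case residuals (deviations from
   the averaged control profile) against the entire reference residual
   pool (p < 1e-4), fold of un-logged group means (pseudo-floor 0.1)
   > 1.5, and mean RPKM > 2.  A gene passes only if it clears all four.

The compound thresholds make the null pass rate effectively zero (measured
at < 0.002 genes per 1000-gene simulation in the acceptance suite).

## 7. Serology

NFI values are divided by the per-array anti-IgG/IgM control channel and
re-anchored at the cohort median control, which removes any per-sample
multiplicative distortion up to one global scalar — all downstream folds
are invariant to it.  Group comparison is Welch's t on log(NFI + 1),
log-scale because the assay is multiplicative; folds use group means
(medians by flag; the original analyses do not say which).  Enrichment is
flagged at fold > 5.  Antigen clustering is average linkage on correlation
distance, reported as a leaf order only.

## 8. Numerical and engineering notes

* All randomness flows from explicit integer seeds; derived seeds stay
  below 2^31.
* Counts are promoted to double before the χ² products (2×2 tables from
  ~40,000 chromosomes overflow 32-bit integers).
* `stats::mantelhaen.test`, `stats::p.adjust` and closed-form enumeration
  oracles appear only in the test suite, as independent references for the
  package's own implementations.
* VCF reading is delegated to VariantAnnotation; writing is a simple
  VCF 4.2 emitter (one biallelic record per site, GT only), and the
  writer→reader round trip is itself a test.
* The 102-kb region metadata (chr5:10,678,000–10,780,000) only positions
  the simulated records; no coordinate-dependent logic exists.

## 9. Known limitations

* The EM's progressive pruning is heuristic: adversarial site orders with
  many equally-supported partial phases could in principle prune a true
  haplotype; the clean three-haplotype world and the ≤ 25-site contract
  keep this remote.
* No logistic/mixed-model association, no imputation, no Gabriel-interval
  LD blocks, no genome-wide eQTL scanning, no read-level simulation.
* The two-step normalization recovers only affine per-sample distortions
  on the log scale; nonlinear (e.g. intensity-dependent) distortions are
  out of scope.
* Reported p-values are asymptotic except the exact HWE test.
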