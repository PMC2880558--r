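---
title: "Separating reactive from causative transcripts with a co-twin design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating reactive from causative transcripts with a co-twin design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The inference problem

Transcript abundance in a disease-relevant tissue correlates with a complex
trait for two very different reasons: the gene may sit upstream of the
trait (its expression, modulated for instance by a cis-regulatory variant,
contributes to trait variation), or its expression may simply respond to
the trait. A cross-sectional correlation cannot tell these apart. The
co-twin design can, to a useful approximation: monozygotic (MZ) co-twins
are identical at the DNA sequence level, so in pairs strongly discordant
for BMI any systematic intrapair expression difference must be downstream
of the acquired obesity (or of the exposures that produced it) — such
transcripts are *reactive*. Transcripts that correlate with BMI across
unrelated individuals but show **no** intrapair difference in discordant
pairs are the interesting remainder: candidates for being *causative*,
e.g. through cis-variants that both raise expression and nudge BMI.

`cotwin` implements this screen and its downstream genetic corroboration:

1. **Intensity filter.** Probes with intensity ≥ 50 (normalized array
   units) in at least half the samples of a dataset are retained; the
   half-of-samples rule is inclusive, `ceiling(0.5 * n)` for odd `n`. The
   filter is applied to each dataset independently, before ratio
   formation, since the two datasets were normalized separately.
2. **Co-twin normalization.** One obese/lean intensity ratio per probe per
   pair. Ratios cancel genotype, sex, age and shared environment.
3. **Intrapair test.** The phrase "non-parametric Welch t-test" used by
   array-analysis GUIs of the era is self-contradictory for paired ratios;
   on one-ratio-per-pair data the only coherent default is a one-sample
   *t* of mean log2 ratio against 0 on `n_pairs − 1` df (two-sided). A
   Welch unequal-variance two-sample mode on the raw obese vs lean
   intensities (Welch–Satterthwaite df) is provided as a sensitivity
   analysis. The liberal threshold *P* < 0.05 is a design feature: the
   cost of letting a reactive transcript slip into the causative list far
   exceeds the cost of discarding a genuine candidate.
4. **BMI correlation.** Pearson *r* per probe in the unrelated sample;
   two-sided *P* from the *t* transform on `n − 2` df, threshold
   *P* < 10⁻⁴ (stringent, to keep the final candidate list specific). No
   multiple-testing correction anywhere: the design works with fixed
   nominal thresholds, and the downstream enrichment test is what carries
   the inferential weight.
5. **Set logic.** causative = C \ R; C ∩ R is kept as the *reactive
   control set* for the genetic comparison. Probes collapse to genes by an
   any-probe rule with precedence causative > correlated-and-reactive >
   reactive > unclassified.
6. **Genetic corroboration.** SNPs within ±1 kb of each classified gene
   (symmetric, strand-free; positions 0-based half-open throughout the
   package, so a gene `[start, end)` with flank `f` captures positions in
   `[start − f, end + f)`). Per cohort: ln(BMI) is regressed on age within
   each sex (plus optional covariates such as disease status), residuals
   standardized to mean 0, sd 1 (denominator `n − 1`), and regressed on
   allele dosage under an additive model; *P* from the *t* distribution on
   `n − 2` df. Cohorts combine by fixed-effects meta-analysis with
   inverse-variance weights; the meta *z* uses the normal reference, the
   standard practice, and the difference from *t* is negligible at the
   sample sizes involved. The base of the BMI logarithm is irrelevant
   because standardization removes scale.
7. **Enrichment.** Q-Q coordinates pair the *i*-th ascending observed *P*
   with `(i − 0.5)/n`; the χ² uniformity test bins P-values into 20
   equal-width categories (so 0.05 is a bin edge), reducing the bin count
   automatically to keep expected counts ≥ 5, and refuses fewer than 10
   P-values. Best-SNP-per-gene pruning (smallest overall *P*; ties broken
   lexicographically by SNP id) guards against one high-LD gene inflating
   the profile.

### The "overall P" decision

The sex-stratified analysis yields women's and men's P-values per SNP; how
these were combined into a single overall value is not fully specified by
the design we follow. `cotwin` computes the overall *P* from a pooled
analysis: both sexes' standardized residuals are concatenated within each
cohort, associated, and meta-analyzed. This is the simplest reading
consistent with residuals being "used as outcome measures", and it treats
the sexes symmetrically. It is a package decision, not a reproduction of
an undocumented formula; the sex-specific columns are reported alongside
so either convention can be inspected.

## The simulator

Nothing in the original design prescribes a generative model — it analyzed
real cohorts — so the simulator is this package's own construction, built
to reproduce the qualitative structure the classification exploits and the
published study's marginal conditions:

* 13 discordant MZ pairs, obese co-twin ~22% heavier;
* 77 unrelated adults with BMI ≈ 26.6 ± 4.1 kg/m² (log-normal, so planted
  SNP effects are linear on the analyzed ln scale);
* a reduced-scale GWA panel of 4 cohorts × 500 samples standing in for a
  consortium two orders of magnitude larger — chosen so a full run takes
  seconds while leaving the meta-analysis genuinely multi-cohort.

Per gene class (defaults 20 causal, 20 reactive, 200 null):

* **Causal gene:** log-expression `x = μ + b·u + c·C + ε`, with `u` the
  standardized dosage of its single cis-SNP (binomial(2, f), f uniform on
  [0.05, 0.5]) and `C` a constitutional factor shared within an MZ pair.
* **BMI liability:** standardized ln(BMI) `z = α·C + κ·Σ u + η`, with the
  causal SNPs jointly explaining 20% of variance and `C` 40%.
* **Reactive gene:** `x = μ + δ·z_own + ε`, responding to the
  individual's *own* BMI — so it differs within discordant pairs.
* **Null gene:** baseline plus noise. Baselines are uniform on the log
  scale (100–3000 intensity units for signal genes, 10–3000 for null
  genes, so a realistic fraction of null probes fails the ≥50 filter).

`b`, `c` and `δ` are solved in closed form so that the cis-SNP explains
`snp_h2 = 0.3` of causal-gene variance, each causal gene attains
`|r| ≈ 0.45` with BMI among unrelated individuals, and reactive genes show
a median obese/lean fold change of 1.3 at 22% discordance. The shared
factor `C` is what makes the configuration feasible: twenty mutually
independent genes cannot each correlate at 0.45 with one phenotype (the
squared correlations would sum past 1). Routing part of each causal
gene's trait correlation through a factor that is shared within a twin
pair preserves the design's central dichotomy — causal genes still show
zero expected intrapair difference, because co-twins share `C` and
genotype, while the discordance itself is purely environmental. Configs
that remain infeasible (e.g. `causal_r = 0.9` at default noise) raise a
parameterization error rather than silently missing their target.
Residual log-expression noise is 0.15 (log-normal intensities), chosen so
that a 1.3-fold planted change is detected in 13 pairs with high power —
the regime the published design evidently operated in, given that it
detected ~2,700 reactive transcripts.

What the simulator does *not* emulate: linkage disequilibrium (SNPs are
independent, one per gene), population stratification, probe-level
cross-hybridization, array batch effects, and any epigenetic mechanism.
Passing recovery tests therefore demonstrates the pipeline's logic and
numerics, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Correlation and association P-values are floored at the smallest
  positive double so they stay in (0, 1] even when the *t* CDF underflows.
* Zero-variance log-ratios: *t* = 0 with *P* = 1 when the mean is also 0;
  an error when the mean is nonzero (the statistic is undefined, and such
  data indicate duplicated columns).
* Zero lean-twin intensity with the default pseudocount 0 is a hard error
  naming probe and pair — GCRMA-style normalized intensities are strictly
  positive, so a zero denominator means a corrupt input. The pseudocount
  is configurable for other upstream pipelines.
* Monomorphic SNPs, SNPs below the MAF floor (default 0.01, configurable;
  guards against unstable estimates at simulation-scale n) and SNPs with
  fewer than 3 usable samples are flagged and excluded from meta-analysis
  rather than estimated.
* Missing dosages are an explicit sentinel (`NA` internally, `.` on disk),
  never 0; each SNP's association drops exactly its missing individuals,
  which is why per-SNP N varies.
* Coordinates are 0-based half-open everywhere internally; BED passes
  through unchanged, VCF positions are shifted on read. One convention
  avoids the classic ±1 flank bugs.

## Test design and problem sizes

The suite checks every statistic against an independent route:
`t.test`, `cor.test`, `lm`, `chisq.test` and `metafor::rma(method="FE")`
serve as oracles (tolerance 10⁻¹⁰ over randomized cases), brute-force
scans re-derive the filter and interval assignments, and a permutation
test cross-checks the correlation *P*. Calibration uses 10⁴ uniform
replicates of n = 500 for the χ² test's type-I rate and
Kolmogorov–Smirnov checks on ~500 null-SNP meta P-values (aggregated over
three seeds, since any single KS draw sits in its own 1% tail with
probability 0.01). Recovery runs 20 simulated studies with the unrelated
panel at n = 500 — at the published n = 77 the stringent 10⁻⁴ threshold
passes only about half the planted causal genes, which is faithful to the
original design's conservatism but makes rate estimates noisy. These
sizes are the package's chosen balance between statistical resolution and
a test suite that runs in a couple of minutes.

## Known limitations

* The co-twin logic is one-directional: a gene can be both causative and
  reactive; the design deliberately sacrifices such genes to protect the
  specificity of the causative list.
* With 13 pairs the reactive screen has limited power for small fold
  changes; transcripts reacting weakly will leak into the causative set.
  The liberal 0.05 threshold mitigates but cannot eliminate this.
* The enrichment χ² treats SNPs as independent units; in real data,
  linkage disequilibrium within a gene violates this, which is why the
  best-SNP-per-gene view is provided.
* Fixed-effects meta-analysis assumes a common effect across cohorts; no
  heterogeneity statistic is computed at this scale.
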