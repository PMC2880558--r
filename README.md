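# cotwin

`cotwin` nominates *causative* candidate genes for obesity from adipose
tissue expression data, for researchers combining transcript profiling with
genome-wide association (GWA) results. Correlation between a transcript and
body mass index (BMI) across a population mixes two kinds of genes: those
whose expression merely *reacts* to the obese state, and those upstream of
it. The package separates them with a co-twin control design and then asks
whether the putatively causative genes are enriched for SNPs associated
with BMI.

## The design

Two expression datasets enter the screen:

* **BMI-discordant monozygotic (MZ) twin pairs.** Co-twins are genetically
  identical, so after *co-twin normalization* — dividing the obese twin's
  expression value by the lean co-twin's, probe by probe — any systematic
  intrapair difference reflects a response to the acquired obesity.
  Transcripts with intrapair *P* < 0.05 (deliberately liberal, one-sample
  *t* on log2 ratios by default) form the **reactive** set *R*.
* **Unrelated adults spanning a wide BMI range.** Transcripts whose
  intensity correlates with BMI at Pearson *P* < 10⁻⁴ (deliberately
  stringent; *P* from *t* = *r*√(*n*−2)/√(1−*r*²)) form the correlated set
  *C*.

The classification is pure set logic: **causative** = *C* \\ *R*,
with *C* ∩ *R* the reactive control set. SNPs within ±1 kb of each
classified gene are tested for BMI association per cohort — linear
regression of sex-stratified, age-adjusted, standardized ln(BMI) residuals
on allele dosage under an additive model — and combined across cohorts by
fixed-effects meta-analysis with inverse-variance weights
(*w*ᵢ = 1/SEᵢ², β̂ = Σ*w*ᵢβᵢ/Σ*w*ᵢ, SE = 1/√Σ*w*ᵢ). Each gene set's
P-value distribution is then compared with Uniform(0,1) via Q-Q
coordinates and a Pearson χ² test on categorized P-values.

Because the original cohort data are not redistributable, the package
ships (a) the three published result tables as plain-TSV fixtures and (b) a
full genotype→expression→phenotype simulator
(`simulate_unrelated()`, `simulate_twin_pairs()`,
`simulate_cohort_panel()`) that plants causal, reactive and null genes with
known effect sizes, so the whole pipeline is testable end to end.

## Worked example

```r
library(cotwin)
cfg <- pipeline_config(seed = 1)
cfg$sim <- sim_config(n_unrelated = 500, seed = 1)   # well-powered screen
res <- run_pipeline(cfg, "results/demo")
res$enrichment
#>  set_label  n n_bins      chi2 df      p_value
#>  causative 17      3 34.000000  2 4.139938e-08
#>   reactive 23      4  1.521739  3 6.772621e-01
head(res$meta[order(res$meta$p_overall), ], 3)[,
     c("snp_id", "beta_meta", "se_meta", "p_overall", "n", "gene_set")]
#>    snp_id beta_meta    se_meta    p_overall    n  gene_set
#>  rs100005 0.2186052 0.03112730 2.172445e-12 2000 causative
#>  rs100006 0.2108267 0.03407484 6.125503e-10 2000 causative
#>  rs100017 0.2126647 0.03934240 6.463385e-08 2000 causative
```

Of 180 probes passing the intensity filter, 17 are labeled causative; the
SNPs in those genes show a strong excess of small meta-analysis P-values
(χ² uniformity *P* ≈ 4×10⁻⁸ over 2,000 simulated samples in 4 cohorts)
while SNPs in the reactive control set are indistinguishable from uniform
(*P* ≈ 0.68) — the planted causal architecture is recovered. Every
intermediate table (classification, SNP assignments, per-cohort
association, meta-analysis, Q-Q coordinates) is written as TSV next to a
`manifest.json`, and the run is byte-reproducible from (config, seed).

A thin command-line wrapper is installed as `exec/cotwin`:

```sh
cotwin simulate --seed 1 --out simdata/     # write TSV/BED/dosage inputs
cotwin run-all  --seed 1 --out results/     # full pipeline
```

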