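# breedload

Quantifying between-breed mutational load, prioritizing candidate disease
variants, and testing candidate-marker disease associations in dog breed
panels (or any small, bottlenecked diploid populations genotyped against
an outgroup).

Closed stud books put dog breeds through severe, recent bottlenecks.
`breedload` asks three questions about the genomic consequences:

1. **Did some breeds accumulate more deleterious variation than others?**
   For a breed pair (A, B) and derived-allele frequencies
   `f_A`, `f_B` at outgroup-polarized sites, the package computes the
   sharing sums `L_{A¬B} = Σ f_A (1 − f_B)` and
   `L_{B¬A} = Σ f_B (1 − f_A)` and their ratio

   ```
   R_{A/B} = L_{A¬B} / L_{B¬A}
   ```

   — the relative rate at which the two breeds accumulated derived
   mutations since their split (R = 1 under equal accumulation). The
   homozygosity-based variant `R²_{A/B}` substitutes observed
   homozygous-derived fractions for frequencies, a recessive-load proxy.
   Both come with 50-block weighted block-jackknife standard errors,
   Z-tests against 1, Bonferroni correction, per-site-class stratification
   (synonymous / nonsynonymous / LoF / moderately / highly conserved by
   PhyloP), and re-estimation after masking putative sweep regions.

2. **Which variants look like breed-specific risk candidates?** Per-site
   Weir–Cockerham F_ST (multi-allelic aware) averaged over a focal
   breed's pairs, V_ST for copy-number variants, then staged filters:
   high-frequency derived + average pairwise F_ST ≥ 0.7 + conservation,
   gene-proximity prioritization against curated and
   disease-downregulated gene lists, interval scans, and merging of
   top-5% composite-likelihood-ratio windows into selection regions.

3. **Do candidate markers associate with disease?** Linear probability
   models (`lm`, deliberately not logistic) for case-control screens,
   factorial genotype×age(×sex) interaction models for graded disease
   status, young-case/old-control subsampling for late-onset phenotypes,
   group allele frequencies, two-locus LD (D′, r²) by EM from unphased
   genotypes, and regression of breed-level incidence (first claims per
   10,000 dog-years at risk) on breed allele frequencies.

A seed-reproducible Wright–Fisher simulator (`sim_config()`,
`simulate_breed_panels()`, `simulate_cohort()`, `simulate_cnv()`)
generates breed panels with bottleneck-shifted frequencies, class-labelled
annotations, outgroup genotypes, late-onset disease cohorts and
copy-number matrices, so every stage is testable without downloads.

## Worked example

Simulate the relaxed-selection scenario — one breed with a ten-fold
tighter bottleneck (Ne 50 vs 500 for 75 generations) and additive
selection s = 0.01 against derived alleles at highly conserved sites —
then measure load:

```r
library(breedload)

study <- simulate_breed_panels(sim_config_bottleneck(seed = 1))
ds <- polarize(study$dataset, study$outgroup)
ds
#> polarized_dataset: 50000 site records, 40 samples in 2 breed(s)
#>   polarity: 50000 polarized / 0 unpolarized
#>   annotations: attached

r_ab(ds, "breedB", "breedA", "high")
#> R_{breedB/breedA} at high sites (n = 25000)
#>   value = 1.0978  (95% CI 1.0585-1.1370)  se = 0.02003
#>   Z = 4.881  p = 1.06e-06  Bonferroni (family 1) p = 1.06e-06

r_ab(ds, "breedB", "breedA", "synonymous")
#> R_{breedB/breedA} at synonymous sites (n = 25000)
#>   value = 1.0144  (95% CI 0.9832-1.0456)  se = 0.0159
#>   Z = 0.904  p = 0.366  Bonferroni (family 1) p = 0.366
```

The bottlenecked breed carries ~10% more derived alleles at constrained
sites (Z = 4.9): with a ten-fold smaller Ne, drift overwhelms weak
selection and deleterious variants persist. The synonymous (neutral)
class stays at R = 1 — the excess is a selection effect, not an artefact
of the demography or the estimator.

Association on a simulated late-onset cohort — the genotype×age
interaction is what flags an early-onset risk allele:

```r
cohort <- simulate_cohort(sim_config(seed = 21, cohort = list(n = 400)))
interaction_models(cohort, "NEBL_2", outcome = "status")
#> Linear model for MMVD_status (n = 400)
#>                beta     se       t      p
#> (Intercept) -0.2295 0.0902 -2.5448 0.0113
#> NEBL_2      -0.1988 0.0870 -2.2852 0.0228
#> age          0.0860 0.0086 10.0136 0.0000
#> NEBL_2:age   0.0175 0.0083  2.1121 0.0353
#> adj. R^2 = 0.4057
```

Risk-allele carriers start lower but their affection probability rises
faster with age (positive `NEBL_2:age` term) — the signature of
genotype-dependent disease onset age.

For real data, `read_genotypes()` takes a VCF plus a sample→breed TSV,
`polarize()` takes the outgroup VCF, `attach_annotations()` a per-site
effect/PhyloP TSV, and `run_pipeline()` orchestrates everything from a
single config (list or YAML) into TSV reports with a parameter-echoing
JSON run log.

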