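---
title: "Methods: derived-allele load, differentiation scans and candidate-variant association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: derived-allele load, differentiation scans and candidate-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedload)
```

# Overview

`breedload` implements three cooperating analyses for multi-breed diploid
genotype panels polarized against an outgroup:

1. **Mutational load comparison** between population pairs via
   derived-allele sharing ratios ($R_{A/B}$ and the homozygosity-based
   $R^2_{A/B}$) with weighted block-jackknife standard errors;
2. **Differentiation scans and candidate prioritization**: per-site
   Weir–Cockerham $F_{ST}$, copy-number $V_{ST}$, conservation-stratified
   filtering and selective-sweep window merging;
3. **Case-control association** of candidate markers with a late-onset
   disease: linear probability models, genotype-by-age interaction models,
   young-case/old-control subsampling, two-locus LD by EM, and across-breed
   incidence regression.

A frequency-level Wright–Fisher simulator generates seed-reproducible
inputs with the statistical structure these analyses assume, so the whole
pipeline is testable without external data.

# The load statistics

For each site $i$ usable in both breeds, let $f_{A,i}$ and $f_{B,i}$ be
derived-allele frequencies. The sharing sums are

$$L_{A\nsubseteq B} = \sum_i f_{A,i}\,(1 - f_{B,i}), \qquad
  L_{B\nsubseteq A} = \sum_i f_{B,i}\,(1 - f_{A,i}),$$

and $R_{A/B} = L_{A\nsubseteq B} / L_{B\nsubseteq A}$. Each term is the
probability that one chromosome drawn at random from each breed carries
the derived allele in the first breed and the ancestral allele in the
second, so $R_{A/B}$ compares the rates at which derived (potentially
deleterious) mutations accumulated in the two breeds since their split;
under equal accumulation $R_{A/B} = 1$, and
$R_{A/B} \cdot R_{B/A} = 1$ exactly.

The published verbal description ("observed in breed A but not in breed
B") is ambiguous between this frequency-weighted form and a strict
presence/absence count. We default to the frequency form — it is the
expectation of the one-allele-per-breed sampling scheme of the statistic's
original formulation and is insensitive to sample-size-dependent detection
of rare alleles — and ship a presence/absence mode
(`r_ab(..., mode = "presence")`) for sensitivity analysis.

$R^2_{A/B}$ replaces allele frequencies by the observed fraction of
individuals homozygous for the derived allele. Observed rather than
HWE-expected ($f^2$) homozygosity is used because breed panels are inbred;
this makes $R^2$ a direct contrast of realized homozygous (recessive-
exposure) burdens. Sites fixed for the derived allele in the whole panel
still enter the sums; they contribute only through the partner breed's
deficit, which is the desired behaviour.

**Usable sites.** A site contributes to a pair's sums only when it is
polarized and fully called in both breeds (`min_called` defaults to all
$2n$ alleles, matching the convention used for frequency spectra; it is
configurable). Sites are dropped pairwise (complete-case per pair), so
different pairs may use slightly different site sets.

**Polarization.** The outgroup individual's genotype decides orientation:
homozygous reference means the alternative allele is derived, homozygous
alternative means the reference allele is derived, and heterozygous or
missing outgroup genotypes leave the site unpolarized and excluded from
the load sums. Excluding rather than guessing avoids biased polarity at
the cost of some data; the simulator's `polarization_error` dial exists to
probe sensitivity of $R$ to residual misorientation.

## Weighted block jackknife

Per-site terms are correlated along the genome, so naive binomial errors
would be anticonservative. Standard errors are instead obtained by
splitting the contributing sites, in genomic order, into 50 contiguous
blocks of approximately equal site counts, recomputing the ratio with one
block deleted at a time, and combining the replicates with the weighted
delete-one jackknife of Busing and colleagues (weights proportional to the
number of sites removed). Blocks hold equal numbers of sites rather than
equal physical spans so that every replicate removes a comparable amount
of information. Significance is the two-sided normal p-value of
$Z = (R - 1)/\mathrm{se}$, and Bonferroni correction uses an explicit
family size. The family is not dictated by the statistic itself; we
default to the number of breed pairs within one site class (28 for eight
breeds) and expose it as a parameter.

Degenerate cases are defined rather than silent: a statistic constant
across replicates has se = 0 (self-comparisons report $Z = 0$, $p = 1$);
fewer usable sites than blocks, or a zero denominator sum, are errors.

## Site classes

Effect classes come from SNPeff-style categories; loss-of-function is the
fixed ten-category list (codon insertions/deletions and combinations, exon
deletion, frameshift, splice acceptor/donor, start lost, stop gained).
Conservation classes cut the 100-vertebrate PhyloP score. Two published
cutoff conventions exist for the same analysis — moderate $[2, 5)$ / high
$[5, \infty)$ versus moderate $(2, 5]$ / high $(5, \infty)$ — and both are
selectable (`classify_sites(..., convention =)`); the default is the
Methods-section convention $[2,5)/[5,\infty)$, which we take as the
operational definition since it is the one stated in procedural terms.

## Masked re-estimation

To separate hitchhiking from relaxed selection, `masked_r_ab()` removes
sites overlapping a BED mask (e.g. the top composite-likelihood-ratio
sweep regions) and re-estimates $R$, re-partitioning the remaining sites
into the full number of jackknife blocks.

# Differentiation and prioritization

**$F_{ST}$.** The Weir–Cockerham (1984) two-population $\theta$ is
computed from per-breed allele counts and per-allele heterozygote counts;
for multi-allelic sites the variance components are summed over alleles
before the ratio is formed. Negative per-site estimates are retained when
averaging (truncation would bias means upward); sites monomorphic for the
same allele in both breeds are undefined and excluded from averages. A
breed's per-site differentiation from all others is the arithmetic mean of
its pairwise values ("average pairwise $F_{ST}$").

**$V_{ST}$.** For continuous copy numbers,
$V_{ST} = (V_T - V_S)/V_T$ with $V_T$ the pooled variance of the pair and
$V_S$ the size-weighted mean of within-breed variances. Population
(denominator $N$) variances are used throughout so that identical
distributions give exactly zero rather than a small negative artefact of
the $n-1$ correction.

**Stage-1 filter.** A candidate in a focal breed must have (i) derived
allele frequency at least `freq_min` in the focal breed *and* strictly the
highest among breeds, (ii) average pairwise $F_{ST} \ge$ `fst_min` (both
default 0.7), and (iii) PhyloP $\ge 2$ for SNVs/indels (structural
variants use $V_{ST} \ge 0.7$ plus conserved-element overlap instead).
The published criterion gives the differentiation and conservation
cutoffs but no explicit frequency cutoff beyond them; we chose 0.7 — the
same level as the differentiation threshold — plus the strictly-highest
requirement, and expose both as parameters. The filter is idempotent and
records provenance labels on every kept record.

**Gene-proximity prioritization.** Coding mode keeps candidates at highly
conserved sites (PhyloP$_{100} > 5$) within 5 kb of a curated
heart-function gene; regulatory mode keeps candidates at moderately or
highly conserved sites (PhyloP$_{100}$ *or* PhyloP$_{46} \ge 2$) within
5 kb of a gene from a disease-downregulated list. Both gene lists are user
inputs — they are curated knowledge, not derivable from the genotypes.
Gene spans are extended by 5,000 bp with half-open arithmetic, and
distance is measured to the nearest point of the span. `region_scan()`
additionally restricts to conserved non-coding candidates inside an
explicit interval (1-based start, exclusive end).

**Sweep-window merging.** Given tiled 10-kb windows with composite
likelihood ratio scores, the top 5% (ties at the threshold all included)
are selected, adjacent selected windows are concatenated, and concatenated
runs separated by at most 100 kb are aggregated. Output regions are
sorted, non-overlapping and idempotent under re-aggregation.

# Association models

All association fits are ordinary least squares via `stats::lm()`, *also
for binary outcomes* (linear probability models). This deliberately
mirrors the published analysis style rather than substituting logistic
regression; coefficients are on the probability (or severity-grade) scale.
Genotypes are coded additively as derived-allele counts 0/1/2, aligning
effect signs with the risk-allele framing; missing genotypes are dropped
per model (complete-case). Monomorphic markers are refused with an
explicit error rather than fitted as zero-variance covariates.

The model families are the univariate screens (`status ~ age`,
`status ~ sex`, `status ~ genotype`), the factorial interaction models
(`graded_status ~ genotype*age`, optionally `*sex`), and the young-case /
old-control design: because a late-onset disease censors young risk-allele
carriers, power is recovered by contrasting cases younger than a cutoff
with controls older than another, at progressively stricter thresholds
(nested subsets by construction).

**Two-locus LD.** Unphased genotype pairs are resolved by EM: only double
heterozygotes are phase-ambiguous and are split between the two phase
configurations in proportion to current haplotype-frequency products.
Initialization at linkage equilibrium makes the estimate deterministic;
convergence is a maximum frequency change below $10^{-8}$, with failure
after 1,000 iterations an error. $D' = D/D_{\max}$ and
$r^2 = D^2 / (p_A q_A p_B q_B)$ follow, and set-level summaries average
over all unordered marker pairs.

**Incidence regression.** Breed incidence is first claims per 10,000
animal-years at risk, with per-dog exposure accrued from the later of
insurance start and window start to the earliest of first claim,
withdrawal and window end (later claims ignored). The across-breed test is
a univariate OLS of incidence on breed allele frequency, with a
leave-one-breed-out mode because a single extreme breed can carry the
whole association.

# The simulator

`simulate_breed_panels()` is a frequency-level Wright–Fisher generator,
not a coalescent: every in-scope statistic is per-site (the only spatial
structure used downstream is the genomic ordering consumed by the
jackknife), so simulating allele-frequency trajectories is sufficient and
runs at desk scale. Per site: an ancestral derived-allele frequency is
drawn from a discretized neutral ($\propto 1/x$) spectrum on a 99-point
grid; each breed then evolves independently for its configured epochs —
per generation a deterministic selection decrement
($\Delta p = -(s/2)\,p(1-p)$ additive, $-s\,p^2(1-p)$ recessive) followed
by binomial resampling at $2N_e$ — and 20 diploids are drawn binomially
from the final frequencies. REF/ALT orientation is randomized per site and
the outgroup receives the true ancestral state (flipped with probability
`polarization_error`, default 0), so polarization is genuinely exercised.
PhyloP values are assigned so that `classify_sites()` reproduces the true
class labels.

Default study conditions, chosen once: two breeds of 20 diploids; 25,000
synonymous plus 25,000 highly conserved sites (so the neutral calibration
runs on $5\times10^4$ sites); breed formation lasting 75 generations —
roughly the 200–300 years of closed stud books at 3–4 years per
generation — at $N_e = 500$; the bottleneck scenario
(`sim_config_bottleneck()`) shrinks one breed to $N_e = 50$ (ten-fold
tighter) and applies additive $s = 0.01$ against derived alleles at
"high"-class sites. Under these conditions selection removes less
variation in the small breed (drift erodes $E[p(1-p)]$, the lever
selection acts on), which is exactly the relaxed-selection signature the
load statistic is designed to detect: $R \approx 1.10$ at constrained
sites with the synonymous class at 1, comfortably inside the 6–13% range
reported for heavily bottlenecked breeds.

The cohort generator draws ages uniformly on 4.8–15.9 years, sex
Bernoulli(0.5), marker genotypes binomial at configured frequencies
(defaults at intermediate frequencies, with one marker fixed ancestral to
exercise the monomorphic-marker path), and affection from
$\mathrm{logit}^{-1}(\alpha + \beta_g g + \beta_a\,\mathrm{age} +
\beta_{ga}\,g\cdot\mathrm{age} + \beta_s\,\mathrm{sex})$ with defaults
$\alpha = -5.5$, $\beta_a = 0.6$ (about 8% affected at age 5 rising past
90% at 15, a late-onset profile), $\beta_g = -1.2$, $\beta_{ga} = 0.15$,
$\beta_s = 0.2$. Severity grades among affected are assigned by ordered
thresholds on the linear predictor placed at the empirical quantiles
implied by the configured grade proportions (default 55/18/6 over 79,
matching a screened cohort's composition); quantile placement keeps the
grade mix stable across seeds while remaining deterministic given the
data. Because the generative risk is logistic while the fitted models are
linear probability models, parameter-recovery tests compare estimates to
the large-sample OLS estimand (obtained on a very large simulated
cohort), not to the logistic coefficient itself.

The copy-number generator draws Gaussian within-breed noise (σ = 0.3)
around breed means, with ten variants carrying a planted two-copy
between-breed shift that puts $V_{ST}$ above the 0.7 detection threshold.

**What the simulator does not emulate** — and hence what passing tests do
not demonstrate about real data: linkage and recombination (sites are
exchangeable given the layout; the jackknife's robustness to *local
correlation* is therefore exercised only structurally), sequencing and
genotyping error, call-rate structure, relatedness within panels,
admixture between breeds, and indel/structural-variant mutational
processes. Results on real panels additionally depend on annotation and
polarization quality, which the generator idealizes.

# Numerical choices and conventions

- Coordinates: VCF positions are 1-based; BED intervals and all internal
  interval arithmetic are 0-based half-open. `region_scan()` takes a
  1-based start with exclusive end.
- Multi-allelic records are decomposed into per-ALT records for frequency
  and load work but kept joint (all alleles) for $F_{ST}$.
- Heterozygosity is the observed heterozygote fraction over biallelic
  sites segregating in the full dataset (robust under inbreeding, where
  HWE-expected heterozygosity is not an observable summary).
- Top-fraction window selection takes everything at or above the
  $(1-\mathrm{top\_frac})$ quantile, so ties are all included.
- The EM tie-break when both phase configurations are impossible
  (denominator zero) splits double heterozygotes evenly; it can only occur
  transiently at degenerate starting values.
- Self-comparisons ($R_{A/A} = 1$ with se 0) report $Z = 0$, $p = 1$.

# Problem sizes

The test suite and the acceptance script run the calibration scenarios at
the default $5\times10^4$ sites (about 1.5 s per scenario), oracle
comparisons on tens of sites with $10^5$–$2\times10^5$ Monte-Carlo draws,
cohort recovery at $n = 400$ with a $2\times10^5$ reference fit, and
null-calibration batteries of 120 replicate cohorts. These sizes were
chosen so that every stochastic check has comfortable resolving power
while the whole suite completes in well under a minute.

# Known limitations

- The jackknife assumes enough contributing sites per block that
  leave-one-out ratios are stable; with very sparse site classes the
  block count should be reduced (the functions error rather than
  degrade silently).
- $R$ statistics assume shared polarization error between breeds cancels;
  breed-specific reference bias would not cancel and is not modelled.
- The linear probability models can predict outside $[0,1]$; that is
  accepted as the price of matching the published analysis style, and
  p-values rely on homoskedasticity that binary outcomes violate mildly.
- The incidence regression treats breeds as independent units; shared
  ancestry between breeds is ignored.
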