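---
title: "Methods: delineating cryptic taxa from population genomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating cryptic taxa from population genomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptaxon)
```

## What this package computes

`cryptaxon` implements the inference chain used to ask whether a set of
mosquito cohorts contains a hidden ("cryptic") taxon: populations that
conventional diagnostics call hybrids or intermediates, but that genome-wide
data reveal to be an old, isolated lineage. The chain runs from raw diploid
genotypes to a verdict in stages, each usable on its own:

1. **Preparation** — biallelic site filtering with an inclusive minor-allele
   frequency threshold (default 1%), optional random down-sampling, and
   linkage-disequilibrium pruning of dosages (r² > 0.01 in 500-SNP moving
   windows, step 250).
2. **Structure** — principal component analysis with the Patterson scaler
   and ancestry-informative-marker (AIM) fractions with the ">5% and <95%"
   intermediate rule.
3. **Diversity and divergence** — windowed π, Watterson's θ, Tajima's D,
   Hudson's F~ST~ (Bhatia ratio-of-sums estimator), D~xy~, folded site
   frequency spectra, and top-window gene annotation.
4. **Admixture tests** — three-population f3 (admixture and outgroup forms)
   and Patterson's D (ABBA–BABA), both with delete-one-block jackknife
   standard errors over SNP blocks.
5. **Diagnostic markers** — discovery of taxon-diagnostic SNPs by allele
   frequency difference (DAF), tiered at fixed / >98% / >85%, and individual
   classification by the percentage of panel alleles carried.
6. **Selection scans** — Garud H-statistics (H1, H12, H123, H2/H1) over
   haplotype windows, with the window size calibrated so the neutral 95th
   percentile of H12 is at or below 0.1.
7. **Copy-number variation** — GC-normalised windowed coverage decoded by a
   Gaussian hidden Markov model over copy-number states 0–12, run-length
   CNV calls, and presence/absence cohort frequencies.
8. **Target-site resistance** — per-cohort amino-acid substitution
   frequencies from annotated SNPs, retaining changes above 5% in at least
   one cohort.

Everything is exposed as ordinary functions over data frames: results come
back as tibbles, fitted objects have `tidy()`/`glance()` methods, and the
scan results have `autoplot()`/`plot_windows()` helpers.

## Statistical definitions and conventions

**Hudson's F~ST~ (Bhatia estimator).** Per site, with sample frequencies
$p_1, p_2$ and called-allele counts $n_1, n_2$:

$$N = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D = p_1(1-p_2) + p_2(1-p_1).$$

Window and genome-wide values are the **ratio of sums** $\sum N / \sum D$,
never the mean of per-site ratios; per-site sampling corrections make the
numerator unbiased, so self-comparisons centre on zero. Values are reported
unclipped — slightly negative window estimates are estimator noise and are
kept as such.

**D~xy~** is $\sum_s [p_1(1-p_2) + p_2(1-p_1)]$ per window divided by the
window's *accessible-base* count, not its physical span. Windows are built
to contain exactly 100,000 accessible bases each (configurable), so the
last window of a contig arm is the only short one.

**Tajima's D** uses the classical constants evaluated at the per-window
median called-allele count. Sample size varies per site when genotypes are
missing; the median is a robust single-n compromise and is documented here
because no single convention is standard. Windows with fewer than two
segregating sites or median $n < 4$ carry an `NA` sentinel, never a zero.

**f3 and Patterson's D.** The admixture-f3 of target $X$ against sources
$A, B$ uses per-site numerator $(x-a)(x-b) - x(1-x)/(n_x-1)$ and a
heterozygosity-scaled denominator $2x(1-x)\,n_x/(n_x-1)$; a significantly
negative value is evidence the target is a mixture. Significance comes from
a delete-one-block jackknife over contiguous SNP blocks:
$SE^2 = \frac{m-1}{m}\sum_j (R_{-j} - \bar R_{-\cdot})^2$, $Z = \hat R / SE$.
Two conventions deserve emphasis because the literature prints them
inconsistently:

* the admixture-f3 criterion is $Z < -5$ — a *negative* estimate more than
  five standard errors from zero; a large positive Z is the expected
  signature of a clean tree, not a detection;
* Patterson's D is oriented by its site-pattern anchor: a site with
  frequencies $(p_1,p_2,p_3,p_O) = (0,1,1,0)$ is pure ABBA and yields
  $D = +1$, so gene flow *into population 2 from population 3* produces
  positive D, and significance is $|Z| > 5$. Swapping P1 and P2 flips the
  sign exactly.

Sites where the outgroup is polymorphic are retained; the estimator is
fully frequency-based. The point estimate is invariant to block size (only
the SE needs at least two blocks); at the simulation scales used here
(50k–100k independent sites) blocks of 1,000 SNPs give ~50–100 blocks,
whereas the published analyses use 100k-SNP blocks over tens of millions of
linked SNPs — the invariance property is what makes these comparable.

**AIM fractions and the allelic percentage.** A sample's AIM fraction is
(number of taxon-A diagnostic alleles carried) / (2 × number of called
panel sites); the per-allele counting definition is adopted and documented
because the underlying resource never prints a formula. Cohorts are
"intermediate" when their mean fraction lies strictly between 0.05 and
0.95; the boundaries assign to the nearer taxon. The individual allelic
percentage is the same quantity × 100 over a DAF-discovered marker panel;
missing genotypes shrink the denominator rather than counting toward either
taxon, and classification uses strict cut-offs (>80% → taxon A, <20% →
taxon B, otherwise unassigned).

**DAF tiers.** Marker discovery first drops sites whose genotyping success
(fraction of samples with a called genotype, over both cohorts jointly —
the denominator is not specified upstream, so the joint convention is
documented here) is below 10%. Tiers are: `fixed` at $|\Delta AF| = 1$
exactly, `ge98` above 0.98, `ge85` above 0.85, strict inequalities. Panels
nest across tiers, and each marker is oriented toward the allele at higher
frequency in the focal cohort.

**H12 calibration.** "Optimal window size" is operationalised as the
*smallest* candidate whose genome-wide H12 95th percentile is at or below
0.1 — the published procedure plots the distribution and eyeballs it; a
deterministic rule is required for software. Windows are counted in SNPs
(not base pairs), genomic spans are reported for interpretation, and the
default scan step is half the window. When no candidate qualifies, the
largest is returned with an explicit `calibrated = FALSE` flag.

**Copy-number HMM.** Raw counts in 300-bp windows are normalised per
sample to copy-number scale within 1-percentage-point GC bins (bins under
100 windows merge with a neighbour). The chain has states 0–12; state $k$
emits Normal with mean $k \times \mathrm{baseline}/\mathrm{ploidy}$, where
the baseline is the sample's median normalised value and ploidy is 2, or 1
for males on the X. The shared emission SD is a median-absolute-deviation
estimate floored at 0.1; the transition matrix uses a single stay
probability $1 - 10^{-5}$, encoding that copy-number changes are rare along
the genome. Calls are maximal runs of ≥5 adjacent windows above ploidy
(amplifications) or below it (deletions, called symmetrically since cohort
frequencies count "any CNV amplification or deletion"); runs with mean
decoded-state posterior below 0.9 are flagged and excluded from
frequencies, samples with normalised-coverage variance above 0.2 are
excluded entirely. These five constants (stay probability, MAD-based SD,
GC band 0.2–0.8, posterior 0.9, variance 0.2) are under-specified by the
underlying procedure and fixed here as package defaults, each chosen to be
conservative at typical 30× short-read depth.

## The synthetic-data generator

Every stage is testable without the original sequencing resource because
the package ships a generator whose defaults *are* the study conditions:

* **Balding–Nichols divergence.** Taxon frequencies are Beta-distributed
  around a shared ancestral frequency $p \sim U(0.05, 0.95)$ with drift
  parameter $F$; under this model the expected Hudson F~ST~ between two
  taxa at drift $F$ is $F$ itself. The default $F = 0.03$ matches the
  interspecific divergence scale reported for these taxa (pairwise
  F~ST~ 0.018–0.035). The ancestral support excludes (0, 0.05) to avoid
  monomorphic inflation.
* **Divergence islands.** Real sibling taxa in this complex differentiate
  mostly in a few genomic islands holding near-fixed differences against a
  low genome-wide background; 2% of simulated sites therefore receive
  island drift 0.8. This is what diagnostic-marker discovery feeds on — a
  uniform-drift genome at $F = 0.03$ contains essentially no $|\Delta AF| >
  0.85$ sites, and a marker panel would be empty.
* **Admixture** is frequency-level mixing $p_X = \alpha p_A + (1-\alpha)
  p_B$; the scenario's admixed cohort mixes the cryptic taxon with the
  coluzzii-like taxon at $\alpha = 0.5$.
* **The introgression tree** places two sister populations (branch drift
  0.01 each over an internal branch of 0.01, i.e. mutual F~ST~ ≈ 0.02,
  like conspecific cohorts) against a source taxon at drift 0.05 and an
  outgroup at 0.3; "10% gene flow" replaces a tenth of the recipient's
  frequency vector with the source's.
* **Sweeps** replace a fraction of haplotypes with founder sequences
  across a flank; one founder is a hard sweep, several founders share the
  frequency for a soft sweep. The neutral background draws sites
  independently.
* **Coverage** is negative-binomial around mean depth 100 per 300-bp
  window (≈30× short reads) with dispersion 300, giving a normalised
  per-window SD near 0.23, modulated by a unimodal quadratic GC-bias curve
  peaking at GC 0.45; truth intervals scale the mean by CN/2.

What the generator deliberately does **not** emulate: linkage
disequilibrium from recombination (sites are exchangeable, so LD-pruning
and jackknife behaviour on real, linked data is exercised only
structurally), mutation-model detail, inversion polymorphism, and
sequencing error beyond missingness. Passing tests therefore demonstrate
estimator correctness and pipeline calibration under the stated sampling
models, not robustness to every artefact of real sequencing data.

## Problem sizes used by the checks

The verification suite and `scripts/acceptance.R` run at desk scale, chosen
once: 50k sites × 100 diploids per cohort for divergence and admixture
statistics (200 replicates for the clean-tree calibration, 100k sites for
introgression detection), a 20k-site three-taxa scenario with 50-diploid
cohorts and equal-sized hold-out cohorts for the classifier, 100 replicates
of 120 haplotypes × 1,200 SNPs for sweep recovery, and 30 samples × 4,000
windows with one implanted 7–14-window duplication each (plus one 4-window
decoy each, which must never be called) for the CNV caller.

## Numerical and degenerate-input choices

* Half-called genotypes ("0/.") become fully missing at construction; this
  avoids biasing allele counts and matches common practice.
* Coordinates are 1-based inclusive everywhere; BED input is 0-based
  half-open and converted on read.
* The MAF threshold is inclusive (≥) and MAF is computed globally over all
  analysed samples (the per-cohort alternative is not taken; the upstream
  description is ambiguous and the global choice matches pooled variant
  sets). Preparation order is MAF filter → down-sample → LD prune.
* LD pruning drops the *later* variant of an offending pair (matching the
  reference implementation's greedy forward scan); pairs with undefined
  correlation (zero variance, or fewer than two pairwise-complete samples)
  are treated as unlinked; a single pass is the default.
* PCA orients each component so its largest-magnitude sample coordinate is
  positive; zero-variance variants are dropped; missing dosages are
  mean-imputed before scaling.
* The folded SFS drops sites with any missing call by default so the
  spectrum has a single sample size.
* Gene–window overlap is inclusive on both ends: a gene ending exactly at
  a window's first base is reported.
* All stochastic operations take explicit integer seeds; the pipeline fans
  a single global seed out per stage by hashing stage names, and a re-run
  with the same config and seed is byte-identical (no timestamps are
  written into outputs).

## Scope and limitations

The package consumes already-phased haplotypes, an externally produced
genome accessibility/site-filter mask, and external gene annotation; it
does not call variants, phase, align reads, or fit explicit demographic
models (model-based ancestry estimation, graph-based tree fitting and
diffusion-approximation demographic inference are external tools whose
outputs can sit alongside these results). Amino-acid annotation handles
single-nucleotide changes against one transcript at a time;
multi-nucleotide codon changes are out of scope and flagged. The CNV
caller operates on windowed counts — breakpoint-resolution genotyping is
not attempted.
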