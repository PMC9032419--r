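---
title: "Models and methods behind karyodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodose)
```

`karyodose` analyses gene expression in aneuploid interspecies hybrids:
genomes in which two parental sub-genomes (labelled `Sc` and `Se`
throughout, after the *S. cerevisiae* × *S. eubayanus* lager yeasts that
motivate the package) coexist at unequal chromosome copy numbers, and in
which recombinant hybrid chromosomes switch sub-genome identity at a
breakpoint inside a gene. This vignette documents the statistical models,
the tunable parameters, the numerical conventions, and the limits of what
the validation studies can show.

## Coverage karyotyping

**Model.** Sequencing coverage is summarised as read counts per fixed-width
bin (default 500 bp, the resolution at which whole-genome coverage tracks
for these genomes are usually distributed). Bin counts on a chromosome with
copy number $c$ are treated as approximately Poisson with mean
proportional to $c$; after division by library size (reported as reads per
bin per million mapped reads) every chromosome copy contributes a constant
*haploid unit* $u$ of normalised coverage.

**Segmentation.** Copy-number changes within a chromosome (hybrid
chromosomes, segmental aneuploidy) are found by recursive binary
segmentation on the per-bin normalised values: the candidate split
maximises the reduction in within-segment sum of squared errors, and a
split is accepted when that reduction exceeds
$\mathrm{penalty} \times \log(n_\text{bins}) \times \hat\sigma^2$,
a BIC-style rule. $\hat\sigma^2$ is estimated robustly from the median
absolute first difference of the profile (first differences are almost
everywhere unaffected by the rare mean shifts being sought). Defaults:
`min_seg_bins = 20` (10 kb at 500-bp bins; shorter events are treated as
noise) and `penalty = 3`. For a true one-copy step at 50 reads per bin per
copy the SSE reduction exceeds this threshold by more than an order of
magnitude, while a flat Poisson profile stays well below it, so the
default is not delicate. On profiles of at most 30 bins the best single
split is verified in the test suite against exhaustive enumeration.

**Haploid unit.** The scale from normalised coverage to integer copies is
not identifiable from one segment alone (any $u/k$ fits equally well), so
$u$ is chosen by grid search minimising the length-weighted squared
distance of segment means from integer multiples,
$J(u) = \sum_s n_s (m_s/u - \mathrm{round}(m_s/u))^2$, subject to all
implied copy numbers being at most `max_cn` (default 8) and the largest
segment receiving at least one copy. Among candidates within 1% of the
optimum the **largest** $u$ wins, resolving the scale ambiguity in favour
of the smallest copy numbers; a genome with a single coverage level is
therefore called haploid, which is the documented behaviour for that
degenerate input.

**Integer calls and conventions.** Segment means are divided by $u$ and
rounded **half away from zero** — under noise, calls sit near $x.5$ and
round-half-to-even would alternate between neighbouring integers. Values
above `max_cn` are clipped with a warning. A chromosome's copy number is
the length-weighted mode of its segment calls (ties toward the lower
state), so a hybrid chromosome contributes one well-defined count to the
genome total even though its arms differ; this modal convention is the
package's own choice — whole-genome totals could alternatively count arms
separately. Breakpoints are segment boundaries with a CN change, assigned
to the gene whose body contains the boundary, else the nearest gene by
midpoint (ties to the lower coordinate). Genes take the CN of the segment
containing their midpoint; because coverage lives on parental reference
coordinates (as when reads are mapped to a combined two-species
reference), this automatically sums parental copies plus the matching arm
of hybrid copies. Coordinates are 0-based half-open throughout, BED and
bedGraph on disk.

Sub-genome assignment of genes on a hybrid chromosome follows the
breakpoint side containing the gene midpoint; the breakpoint-spanning gene
itself is labelled by the side holding the larger fraction of its length.
Assignment by percent sequence identity to the parents would need the
sequences themselves and is out of scope.

## Differential expression

The DE machinery is authored in the package rather than delegated, in the
DESeq2 parameterisation: counts are NB with variance $\mu + \alpha\mu^2$.

- **Size factors** are median-of-ratios: per sample, the median over
  genes (nonzero in all samples) of the count divided by the gene's
  geometric mean. Factors are identified only up to a common scale; all
  downstream use is through offsets, where the common scale cancels.
- **Dispersions** are method-of-moments,
  $\hat\alpha_g = \max\{(v_g - m_g)/m_g^2,\ 10^{-8}\}$ with $v_g$ the
  replicate-pooled within-group variance on normalised counts, then
  shrunk 50/50 toward a fitted trend $\alpha(\mu) = a_0 + a_1/\mu$
  (coefficients clamped non-negative). The 50/50 weight is a deliberate,
  simple stabiliser for triplicate designs; no Cox–Reid adjustment, LFC
  shrinkage, independent filtering or outlier replacement is performed,
  so results are close to, but not identical with, DESeq2 (a test checks
  log2FC agreement with DESeq2 at correlation > 0.98 on simulated data).
- **Testing** fits, per gene, a two-group NB GLM with log link and
  log-size-factor offsets by IRLS (vectorised across genes; convergence
  tolerance $10^{-8}$ on coefficients, 50 iterations, natural-log
  coefficients capped at ±30 with non-converged genes flagged and their
  p set missing). The Wald statistic log2FC/SE is referred to the
  standard normal.
- **Thresholds** follow the DEG rule exactly: fold-change boundary
  *inclusive* (log2FC ≥ 1 or ≤ −1), FDR boundary *strict*
  (BH-adjusted p < 0.05), so (log2FC = 1, padj = 0.05) is not a DEG but
  (1, 0.049) is. Detection keeps genes with CPM ≥ 0.5 in ≥ 1 library
  (inclusive); the pseudocount of 4 applies only to the log-CPM transform
  used for clustering/plotting, never to the DE model. Genes failing
  detection are removed before testing and therefore before BH, which
  sets the effective number of tests.

## Allele dosage and cross-strain regressions

Within a strain and condition, the two alleles of an orthologue pair are
contrasted with the same NB machinery, treating alleles as the two groups
over the same replicate samples (unpaired; the samples are identical so
pairing would only remove sample-level variance that the shared size
factors already absorb — this definition is the package's choice where a
convention is not otherwise fixed). log2FC > 0 means the Sc allele is
higher.

Pairs are grouped by the gcd-reduced copy-number ratio category
("3:1", "1:2", ...), and the **binned** regression — per-category mean
allele log2FC on $\log_2(\mathrm{CN}_{Sc}/\mathrm{CN}_{Se})$, weighted by
category size — is the primary fit, with an unbinned per-pair fit reported
alongside. Pairs with zero copies on either side have an undefined log
ratio; they are excluded from regression and counted separately. Under a
pure dosage response the slope is 1 and the intercept is
$-\log_2(\text{allele bias toward } Se)$. The cross-strain analysis is the
same regression applied to consolidated counts (orthologue pairs summed to
one row, unmatched genes passed through, all-zero rows dropped) with
strain as the contrast and total copy number
$\mathrm{CN}_{Sc}+\mathrm{CN}_{Se}$ per strain as the dosage variable;
size factors are computed jointly across both strains' samples.

## Representation and enrichment statistics

Sub-genome representation in a DEG pool is tested by a df-1 χ²
goodness-of-fit against the strain's detected-transcript proportions
(configurable to annotated-gene proportions); no continuity correction is
applied because the pools of interest are large, and a warning flags
expected cells below 1. Stars use inclusive thresholds (`**` for
p ≤ 0.001, `*` for p ≤ 0.05). Gene-set enrichment is an upper-tail
hypergeometric test over the detected-gene universe with the pathway
filters: overlap ≥ 4 genes, overlap > 25% of the set, p < 0.05; BH runs
over all tested terms before filtering, so a surviving term's adjusted p
never depends on the filter. The composition score of a term is the
observed Sc fraction of its (allele-level) overlap minus the expected Sc
fraction, bounded in $[-p_{Sc},\ 1-p_{Sc}]$, with exclusively-Se overlaps
flagged. Two-sided set tests and kappa-score term clustering, as some
enrichment GUIs perform, are deliberately not implemented.

## The synthetic hybrid genome generator

The generator is first-class, tested code and defines the package's
reference study conditions (defaults of `sim_config()`): 16 chromosomes
per sub-genome of 200 kb each, 32 orthologue pairs per chromosome placed
on a regular grid, parental copy numbers uniform on 1–6, two hybrid
chromosomes each carrying one breakpoint placed uniformly in the middle
80% of the chromosome and snapped strictly inside the nearest gene body
(mirroring intragenic recombination), 500-bp bins at 50 expected reads
per bin per copy, log-normal baseline expression (meanlog log 100,
sdlog 1) shared between the alleles of a pair, per-gene condition effects
$2^{N(0,1)}$, per-sample depth scaling lognormal (sdlog 0.2), NB counts
with dispersion 0.1 whose mean is proportional to allele copy number, and
triplicate samples. These values are what a small-genome aneuploid yeast
experiment realistically looks like; they are set once and the validation
studies run at them.

Counts are simulated at the count-matrix level — the analysis consumes
counts, and read-level simulation (mapping, GC bias, mappability,
sequence divergence between sub-genomes) is explicitly out of scope.
Consequences: coverage noise is exactly Poisson and counts exactly NB, so
passing recovery tests demonstrates correctness of the estimators under
their own model, not robustness to mapping artefacts, allele
cross-mapping, or dispersion misspecification in real hybrid data. A
single master seed drives per-stage substreams (genome, coverage, counts)
so adding a stage never perturbs earlier draws; all outputs are pure
functions of the configuration.

For two-strain studies, `simulate_counts(condition_effects = )` lets a
second strain reuse the first strain's gene-by-condition effects while
keeping its own karyotype and noise — two strains measured in one
experiment share regulatory responses; without this, condition effects
would act as per-gene noise uncorrelated with dosage and the cross-strain
regression would test nothing meaningful.

## Validation studies and their sizes

The acceptance suite (also recomputed by `scripts/acceptance.R`) runs:
ten simulated genomes (320 chromosomes, 40 reference-chromosome
breakpoints) for karyotype recovery; one 512-pair genome for the
within-strain dosage regression (≥ 5 ratio categories required); two
divergent-karyotype strains for the cross-strain regression, run
end-to-end through coverage karyotyping rather than generative truth; and
5000-gene null and balanced planted-effect simulations (3 vs 3,
dispersion 0.1) for the calibration of the Wald test. Planted effects are
balanced between up and down so that median-of-ratios normalisation
remains valid — one-sided planting of a fifth of the transcriptome
shifts the size factors themselves, which is a property of global-scaling
normalisation, not of the estimator.

## Known limitations

- The NB test is a simplified DESeq2: no Cox–Reid bias adjustment (MoM +
  trend shrinkage instead), no LFC shrinkage, normal rather than
  t reference for the Wald statistic. At 3 replicates the type-I error
  runs slightly above nominal (the calibration study brackets it at
  0.03–0.07 at nominal 0.05).
- Segmentation assumes approximately constant within-segment variance
  after normalisation; very shallow coverage or strong GC waves would
  need variance-stabilising preprocessing upstream.
- The haploid-unit search assumes at least two distinct copy-number
  states somewhere in the genome for a non-trivial scale; a perfectly
  euploid genome is called all-CN-1 by the largest-unit tie rule.
- Sub-genome assignment ignores percent identity (no sequence data), and
  enrichment ignores term-term dependence.
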