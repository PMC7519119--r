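---
title: "Methods: CNV-methylation QTL mapping with permutation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV-methylation QTL mapping with permutation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmqtl)
```

## The model and its assumptions

Copy-number variants (CNVs) are germline gains and losses of DNA
segments; each individual carries an integer copy-number state
(typically 0--4 around the diploid state 2) at each variable locus. A
CNV is a *methylation quantitative trait locus* (CNV-mQTL) when its
genotype correlates, across individuals, with the methylation fraction
(beta-value, in $[0,1]$) of a CpG site. The association statistic is
Spearman's rank correlation

$$\rho = \mathrm{cor}\big(\mathrm{rank}(g), \mathrm{rank}(\beta)\big),$$

with average ranks for ties and a two-sided p-value from the
large-sample approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
degrees of freedom. Rank correlation makes no linearity or
dose-response-shape assumption; it only asks for monotonicity, and it
is invariant to any monotone recoding of the genotype. That invariance
settles an ambiguity in the underlying data: whether CNV "genotypes"
are integer copy numbers or array probe ratios is immaterial, because
the two are monotone recodings of one another. Missing genotypes are
handled pairwise-complete; missing phenotypes are rejected at load.

### Proximal and distal pairing

Candidate pairs are classified against a 2 Mb window centered on the
phenotype's midpoint (`floor((start+end)/2)`; all coordinates are
0-based half-open, the BED convention):

* **proximal** -- the variant interval overlaps
  $[\mathrm{mid} - 1\,\mathrm{Mb}, \mathrm{mid} + 1\,\mathrm{Mb})$ by
  at least 1 bp. Overlap rather than a midpoint test decides
  membership because CNVs can span hundreds of kilobases; a
  window-straddling CNV would otherwise be misclassified.
* **distal** -- same chromosome, wholly outside that window.
* **untested** -- different chromosome. Trans associations are out of
  scope throughout.

### Permutation correction and FDR

Nominal p-values across thousands of correlated tests per phenotype
need an empirical family-wise reference. For each phenotype the
engine shuffles the phenotype vector across samples `n_perm` times
and records, per shuffle, the maximum $|\rho|$ over the phenotype's
tested variant set. Each pair's permutation p-value is the add-one
tail

$$p_{\mathrm{perm}} = \frac{1 + \#\{\max\text{-null} \ge |\rho_{\mathrm{obs}}|\}}{n_{\mathrm{perm}} + 1},$$

so p-values are never zero and floor at $1/(n_{\mathrm{perm}}+1)$.
Proximal and distal candidate sets are corrected as separate families,
mirroring the separate proximal/distal analyses; consequently the unit
at which the 1% error rate is controlled is the *(phenotype, mode)
family*, and a null phenotype tested in both modes has roughly twice
the per-family call probability. Calibration tests therefore count
false calls per family. Significance is strict inequality
(`perm_p < threshold`, default 0.01), and the scan-level FDR is the
expected-by-chance over observed ratio

$$\mathrm{FDR} = \min\!\Big(1, \frac{n_{\mathrm{tested}} \times \mathrm{cutoff}}{n_{\mathrm{significant}}}\Big).$$

Genome-scale analyses of this design use 10,000 permutations; the
package defaults to 1,000 (configurable) so the full workflow and test
suite run at desk scale, and every permutation stream is derived from
one seed keyed by phenotype id, making results reproducible and
independent of row order.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_half_width` | 1e6 | bp | the 2 Mb proximal window (1 Mb either side of the midpoint) |
| `n_perm` | 1000 | shuffles | desk-scale stand-in for the genome-scale 10,000 |
| `threshold` | 0.01 | perm. p | genome-wide significance convention for this design |
| `min_maf` | none | fraction | MAF is annotated, not filtered: rare-variant mQTLs are reported too |
| `flank` (shores) | 2000 | bp | CpG island shores are the 2 kb flanks |
| `window_bp` (Hi-C) | 5000 | bp | CpG extension that folds shore contacts into the pair signal |
| `iterations` | 1000 | permutations | matched-null sample size for both enrichment tests |

## LD and conditional analysis

LD between a CNV and a SNP is the squared Pearson correlation of the
raw genotype vectors; for each CNV only the best tag (largest $r^2$
among SNPs within 1 Mb of the interval's ends, ties to the lower
coordinate) is reported. The conditional analysis asks whether a
CNV-CpG association survives adjustment for nearby SNP-mQTLs: it fits
ordinary least squares of the *rank-transformed* phenotype on the SNP
covariates plus the CNV term and reads the CNV coefficient's two-sided
t-test p. The rank transform keeps the spirit of the Spearman scan
while staying in a standard linear-model framework; with no covariates
the test reduces exactly to the marginal linear-model test. A
covariate collinear with the CNV ($r^2 = 1$, e.g. a perfect tag) makes
the CNV term non-identifiable: the result is flagged and counted as
*not* independent. When many SNP-mQTLs qualify, the strongest-$r^2$
ten (configurable) enter jointly -- a guard against overfitting at
cohort-scale $n$. Whether raw or transformed beta-values enter, and
how many covariates, are surfaced as arguments because the underlying
analysis choice is genuinely open.

## Matched-null enrichment tests

**Regulatory features.** The observed statistic is the number of query
regions (significant CNV-mQTLs) touching a feature track by $\ge 1$ bp
-- per-region counting, so a CNV touching three peaks counts once.
The null re-places each region uniformly on its own chromosome
(preserving per-chromosome feature density), keeping the exact count
and length multiset, 1000 times; enrichment and depletion tails are
both reported with the add-one estimator, and both count ties, so
$p_{\mathrm{enrich}} + p_{\mathrm{deplete}} \ge 1 + 1/(N+1)$. Random
regions may overlap each other (no rejection sampling) and no
assembly-gap exclusion is applied -- the simplest defensible null.

**Hi-C contacts.** Contact maps are sparse symmetric matrices of
KR-normalized signal per (bin, bin) at a fixed resolution; absent
entries are zero. A pair's signal is the *maximum* over all (CNV bin,
CpG bin) combinations after extending the CpG by the shore window --
maximum, because the tested statistic is non-zero/zero overlap and max
preserves it exactly under any refinement. The null draws, per
chromosome, random region sets matching the CNV and CpG length
multisets and re-pairs them so the midpoint-distance multiset matches
the observed one (anchor uniform, partner at the matched distance in a
random direction, off-chromosome placements resampled; distance
matching is honored to within one bin, since exact bp matching is
impossible after independent placement). The statistic is the count of
non-zero pairs; per-iteration log-ratios
$\log\big((\mathrm{obs}+1)/(\mathrm{null}+1)\big)$ (add-one smoothed
so zero null counts stay finite) summarize magnitude. Because the
count statistic takes only $\sim n_{\mathrm{pairs}}$ values, the
ties-inclusive estimator is *conservative* on null data -- its p-values
are valid but discretely super-uniform -- so calibration checks assert
that rejection never exceeds nominal rather than exact uniformity.
"Compartment" in some descriptions of such data denotes the binned
contact entries themselves, not A/B compartments; this package follows
the binned-contact reading.

## The synthetic cohort generator

The generators stand in for the study designs this pipeline targets:
population-cohort CNV genotypes, array beta-values, SNP panels,
RNA-seq expression, regulatory-mark peak tracks, and KR-normalized
contact maps. Defaults emulate the discovery geometry at desk scale:
77 samples, a common-variant MAF spectrum (0.05--0.5), CNV lengths
log-uniform on 1--100 kb, and a two-chromosome 5 Mb toy genome --
large enough that both proximal and distal placements exist,
small enough that the full workflow runs in seconds. Every generator
is a pure function of (config, truth, seed); one global seed fans out
into per-generator streams so any matrix can be regenerated alone.

Planted methylation effects follow
$\beta = \mathrm{logistic}(a \cdot \mathrm{state} + \varepsilon)$,
$\varepsilon \sim N(0, \sigma)$. The observational data this emulates
carry no generative model, so the slope $a$ is calibrated empirically
-- a pilot simulation over a log-spaced slope grid with common random
noise, inverted by monotone interpolation -- so that the expected
Spearman $|\rho|$ tracks the target magnitude (realized planted
$|\rho|$ lands within 0.15 of target at $n \ge 77$). The default
target grid $\{0.3, 0.4, 0.5\}$ matches the magnitudes typical of
reported CNV-methylation correlations (about $|\rho| \approx 0.3$ to
$0.5$); it is a modeling choice, not a property of the method. SNPs in
tunable LD copy a monotone recoding of the CNV dosage and resample
entries at rate $1 - \sqrt{r^2_{\mathrm{target}}}$; expression genes
are methylation-driven, CNV-driven, or null on the log scale.

What the generator does *not* emulate: realistic human LD block
structure, array probe noise, batch effects, cell-type mixtures, or
population stratification. Passing tests therefore demonstrate that
the statistics are correct and calibrated under a clean monotone
model -- not that any particular real dataset would yield a given
count of associations.

## Numerical choices and degenerate inputs

* Ties: average ranks everywhere; rank correlation of identical tie
  patterns is exactly 1.
* Constant vectors (monomorphic variants, flat phenotypes) make
  correlation undefined: scans skip them with a logged count,
  element-wise calls raise errors.
* $|\rho| = 1$ maps to nominal $p = 0$ (the t approximation's limit).
* The FDR estimator errors on zero significant phenotypes rather than
  returning infinity.
* Best-tag $r^2$ ties break to the lower-coordinate SNP; genic-context
  biotype ties break by the fixed priority protein_coding > lncRNA >
  pseudogene (the source data report disjoint percentages without a
  tie rule; the priority is this package's convention).
* PCA components are sign-canonicalized (largest-magnitude loading
  positive) so QC output is deterministic.
* Quantile normalization delegates to `limma::normalizeQuantiles`
  (tie-aware rank-wise means) and is idempotent.

## Problem sizes in the shipped workflow and tests

The analysis scripts and the test suite use 77 samples, 50 CNVs, 220
CpGs (500 for the null-calibration study), 1,000 permutations, and
1,000-iteration enrichment nulls on the 2 x 5 Mb toy genome; the
acceptance script re-runs the same study from a command-line seed.
These sizes were chosen so each stage completes in seconds while
keeping the permutation floor ($1/1001$) well below the 0.01 cutoff
and binomial error bars tight enough for the calibration assertions.

## Known limitations

* Only same-chromosome (proximal/distal) associations are tested; no
  trans scans, no cross-population meta-analysis.
* The conditional model is rank-OLS, not a mixed model; population
  structure must be handled upstream (the PCA check is diagnostic
  only).
* Matched-null placement ignores assembly gaps and mappability.
* Contact maps arrive already KR-normalized; no balancing is
  performed, and inter-chromosomal contacts are out of scope.
* Validation-cohort replication at small $n$ (e.g. 24) has low power
  under max-statistic correction; replication fractions from such runs
  are expected to be well below discovery recovery.
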