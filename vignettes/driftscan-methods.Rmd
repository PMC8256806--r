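---
title: "Methods: drift models, selection scans, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift models, selection scans, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Livestock populations kept under different breeding regimes — historic
versus modern lines, or lines kept at different farms — accumulate both
neutral divergence (drift) and directional divergence at loci targeted by
selection. `driftscan` asks, SNP by SNP, whether observed allele-frequency
differentiation among a set of related populations exceeds what drift
alone predicts, and packages the full workflow around that question:
genotype IO and QC, structure summaries, f-statistics, two complementary
selection scans, and annotation of the resulting regions.

## The drift model

All calibration in this package rests on the Balding–Nichols pure-drift
model. Given an ancestral allele frequency $p_0$ and a drift coefficient
$c \in (0,1)$ for one branch of a population tree,

$$ p \mid p_0 \sim \mathrm{Beta}\!\left(p_0 \tfrac{1-c}{c},\,
   (1-p_0) \tfrac{1-c}{c}\right), $$

so $E[p] = p_0$ and $\mathrm{Var}[p] = c\,p_0(1-p_0)$; fixed frequencies
(0 or 1) are absorbing. Composing branches multiplies the surviving
heterozygosity: after branches $c_1, c_2$ the cumulative coefficient is
$1-(1-c_1)(1-c_2)$. The simulator (`simulate_dataset()`) propagates
frequencies root-to-leaf along a Newick tree whose branch lengths *are*
drift coefficients, then draws genotypes as Binomial(2, $p_\text{leaf}$)
within each population (Hardy–Weinberg, no linkage disequilibrium).

The Beta kernel was chosen over a truncated-Gaussian variant because it
has the same first two moments without boundary mass-point bookkeeping
and is the standard parametric model in the FST literature.

Selection is modelled as excess differentiation on one branch: either an
inflated per-locus drift coefficient `c_sel` (the default — this is
exactly the alternative that FST/FLK outlier scans are powered against)
or a deterministic frequency push toward fixation (`mechanism =
"shift"`). Selected loci are placed in consecutive runs by default
(`cluster_size = 10`) because a real selective sweep drags a window of
linked SNPs, not an isolated marker; this matters for the smoothing
discussion below.

### What the generator does not emulate

No linkage disequilibrium, no mutation, no admixture, no ascertainment
bias of SNP-array content. A green test on this world establishes that
the estimators are correct *under the model they assume*; it does not
establish robustness to LD (which is why block-jackknife block sizes
exist at all) or to admixture between lines.

## Genotype handling

PLINK 1 binary trios are parsed at byte level (2-bit SNP-major codes;
dosage counts copies of allele2; `01` is the missing code). The missing
sentinel is `NA`, never 0. Population labels come from the `.fam`
family-ID column, overridable by a sample-to-population TSV. Only
autosomal biallelic SNPs are kept, and SNPs are sorted by (chrom, pos)
on load. QC applies SNP call rate, then sample call rate, then MAF, with
defaults 0.90 / 0.90 / 0.01 — conventional SNP-array practice; the exact
thresholds are configurable and nothing downstream depends on them.

## Structure: GRM and SVD

The VanRaden genomic relationship matrix is $G = ZZ'/k$ with
$Z_{ij} = x_{ij} - 2p_j$ (cohort-wide frequencies, mean imputation of
missing dosages) and $k = 2\sum_j p_j(1-p_j)$; the per-SNP contribution
to $k$ is maximal at $p = 1/2$. Since $G$ is symmetric PSD, its SVD is
its eigendecomposition; components are reported both as raw orthonormal
vectors and scaled by singular values (either may be plotted; both are
emitted because the choice is cosmetic).

## f-statistics

Per-SNP contributions use Patterson-style finite-sample corrections with
haploid counts $n$:

$$ f_2(A,B) = (\hat p_A - \hat p_B)^2
   - \tfrac{\hat p_A(1-\hat p_A)}{n_A - 1}
   - \tfrac{\hat p_B(1-\hat p_B)}{n_B - 1}, \qquad
   f_3(O;A,B) = (\hat p_O - \hat p_A)(\hat p_O - \hat p_B)
   - \tfrac{\hat p_O(1-\hat p_O)}{n_O - 1}. $$

The identity $f_3(C;A,B) = [f_2(A,C) + f_2(B,C) - f_2(A,B)]/2$ holds
exactly, corrections included, and is asserted to $10^{-10}$. A subtlety
worth recording: $f_3(O;A,A)$ does **not** equal $f_2(O,A)$ under these
corrections — they differ by exactly $\hat p_A(1-\hat p_A)/(n_A-1)$,
because $f_2$ corrects both samples and outgroup-$f_3$ only the
outgroup.

Standard errors use the weighted delete-one-block jackknife over
contiguous blocks of 500 SNPs (never spanning chromosomes; ~12.5 Mb at
25 kb array spacing, beyond livestock LD range). On iid simulated SNPs
any blocking is valid; the default matters only for real, linked data.

## The FST route

The default per-SNP estimator is the Weir–Cockerham ANOVA theta on
allele counts, which realizes the "between-population variance over
total variance" definition with sample-size corrections and supports
any number of populations of unequal size; a `plain` uncorrected
variance ratio is available for the literal reading (it equals 1 at a
fixed difference). Genome-wide summaries use the multi-locus form
(components summed over SNPs before the ratio): the naive mean of
per-SNP ratios is biased low (about 0.083 at a true 0.1 in the
two-population calibration) while the multi-locus estimator is centred
on the truth.

Smoothing is a centred sliding mean over 9 SNPs (step 1, truncated at
chromosome edges). The window size is a package default — reported
regions in this literature are contiguous SNP runs, implying SNP-indexed
smoothing, but no canonical width exists. Nine SNPs (~200 kb at array
spacing) trades single-locus sensitivity for region-level power: a swept
window of 10 loci is detected essentially always in the power
calibration, whereas isolated high-drift loci can realize small net
frequency shifts under the U-shaped Beta kernel and are missed roughly a
quarter of the time by unsmoothed single-SNP ranking.

The region threshold is the genome-wide empirical 95th quantile (type-7
interpolation) of smoothed values, strict inequality (so a constant
input yields no regions); flagged SNPs separated by at most 2
below-threshold SNPs merge into one region, reported 1-based inclusive.

## The FLK route

FLK extends the Lewontin–Krakauer test by modelling the covariance of
population allele frequencies under drift: at a neutral SNP,
$\hat{\mathbf p} \sim (p_0 \mathbf 1,\; p_0(1-p_0)\,\mathbf F)$, where
$\mathbf F$ is the kinship matrix of the populations —
$F_{ij}$ is the drift shared on the root-to-leaf paths of $i$ and $j$.
With $\hat p_0 = (\mathbf 1' \mathbf F^{-1} \hat{\mathbf p}) /
(\mathbf 1' \mathbf F^{-1} \mathbf 1)$ (GLS),

$$ T_{LK} = (\hat{\mathbf p} - \hat p_0\mathbf 1)'\,
   [\hat p_0 (1-\hat p_0) \mathbf F]^{-1}\,
   (\hat{\mathbf p} - \hat p_0\mathbf 1) \;\sim\; \chi^2_{r-1} $$

under neutrality ($r$ populations). On a star tree with equal drift the
statistic reduces to the classic LK form. SNPs whose $\hat p_0$ leaves
(0,1) are excluded and counted, not assigned $p=1$.

$\mathbf F$ is estimated from Reynolds genetic distances (ratio-of-sums,
scaled to be additive in drift units) via neighbor-joining, rooted on a
designated outgroup that is then dropped, reading $F_{ij}$ off the
rooted ingroup tree. Two deliberate choices:

* the distances are **not** corrected for binomial sampling noise — the
  statistic consumes sample frequencies, so the kinship must describe
  their covariance, sampling noise included;
* negative NJ branch lengths are clamped to zero, and a
  non-positive-definite $\mathbf F$ is diagonally jittered by $10^{-8}$
  (both warned).

Calibration on a 4-population, 20,000-SNP pure-drift world: with the
exact simulator kinship the statistic's mean is ≈ 3.07–3.09 against the
theoretical 3 (the small excess is binomial sampling noise not in the
true-kinship covariance) and the 95th-percentile exceedance ≈ 0.044–0.049;
with the estimated kinship the mean is ≈ 2.75–2.77 — the Reynolds
denominator slightly overestimates distances between closely related
pairs, inflating $\mathbf F$ and making the test mildly conservative,
the same behaviour accepted in the established FLK implementations.

## FDR control

q-values follow Storey: $\hat\pi_0(\lambda) = \#\{p > \lambda\} /
(m(1-\lambda))$ on $\lambda = 0.05, \dots, 0.95$, extrapolated with a
cubic smoothing spline (df = 3) at $\lambda = 0.95$, fallback fixed
$\lambda = 0.5$, capped at 1; then step-up minima of
$\hat\pi_0\, m\, t/\mathrm{rank}(t)$. The default significance cut-off
is q ≤ 0.15, configurable. On uniform p-values $\hat\pi_0$ lands in
[0.9, 1.1]; on a 5%-alternative spiked mixture the empirical FDR at
q ≤ 0.15 averages ≈ 0.15.

## Annotation and enrichment

Intervals are closed and 1-based internally; BED input (0-based
half-open) is converted on read. Overlap requires ≥ 1 shared bp by
default (touching endpoints count), computed by a per-chromosome sorted
sweep and verified against a quadratic all-pairs oracle in the tests.
Enrichment is the one-sided hypergeometric (Fisher) tail per category,
with `expected = list_size × category_background_frequency` and fold
enrichment observed/expected. The background gene universe is an
explicit required argument — enrichment answers depend on it more than
on anything else, so the package refuses to guess one. No multiplicity
correction is applied to enrichment rows by default (raw p-values are
reported, as is conventional for pathway tables); q-values can be layered
on by the caller.

## Numerical and degenerate-input policy

* Monomorphic SNPs: excluded from the GRM denominator, FST quantiles,
  and FLK; never silently scored 0.
* A population with zero calls at a SNP has an undefined frequency
  (`NA`), not 0.
* Constant jackknife contributions report SE = 0 with flagged (NA)
  z and p, not an infinity.
* WC theta may be slightly negative; the raw value is kept internally
  (`fst_raw`) and clamped at 0 only for display.
* Quantile thresholds use strict ">" so ties never flag everything.
* All simulation randomness flows from one seed; stage seeds in the
  acceptance script are fixed offsets of the master seed.

## Known limitations

SNP-level FLK only (no haplotype-cluster extension); no LD-aware null;
no admixture modelling (an admixed population inflates both scans);
enrichment ignores GO-graph structure and gene-symbol synonymy. The
desk-scale default scenario (7 populations, 5,000 SNPs, 20–40 diploids
per line) mirrors the shape of a historic-vs-modern pig-breed design but
is not a fitted model of any particular dataset.
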