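---
title: "Methods: exact tag-count testing and ripening expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact tag-count testing and ripening expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgexact)
```

# The problem

Early de novo transcriptome studies of non-model fruit sequenced one pooled
cDNA library per ripening stage — no biological replicates — and asked which
assembled gene-level units (UniGenes) change expression as the fruit ripens.
With a single count per gene per stage, replicate-based models (negative
binomial GLMs and their relatives) are not applicable; instead, the
community used an exact test built directly on the sampling of reads, then
profiled, clustered and network-analyzed the significant genes. `dgexact`
implements that downstream pipeline as tested, reusable functions, and pairs
it with a synthetic-data generator that plants known differential expression
so every stage can be validated against ground truth.

# Quantification

RPKM (reads per kilobase of transcript per million mapped reads) normalizes
a raw count $c_{g\ell}$ by gene length $L_g$ (bp) and library total
$N_\ell$ (clean reads):

$$\mathrm{RPKM}_{g\ell} = \frac{10^9\, c_{g\ell}}{N_\ell\, L_g}.$$

The denominator uses the per-library total of clean reads as recorded in the
count container; whether to count mapped or sequenced reads is a data-entry
decision made upstream, with mapped totals the default reading. The
transform is exactly invertible, which the tests exploit as a conservation
check: $\sum_g \mathrm{RPKM}_{g\ell} L_g N_\ell / 10^9$ must return the
library's counted reads to $10^{-6}$ relative.

Magnitude is discretized on a 10-bin doubling scale (0–10, 10–20, 20–40, …,
1280–2560, over 2560) for map coloring. The printed band edges do not state
inclusivity, so bins are half-open $[lo, hi)$ with the top bin
$[2560, \infty)$: a total partition with no gaps or overlaps, and the only
convention under which every probe value has exactly one bin.

# The exact two-library test

Conditional on a gene's count $x$ in library 1, its count $y$ in library 2
is modeled by

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\left(1 + N_2/N_1\right)^{x+y+1}},$$

a proper distribution over $y$ (it is the negative-binomial law with size
$x+1$ and success probability $N_1/(N_1+N_2)$, a fact the tests use as an
independent cross-check). The two-sided p-value folds the cumulative lower
tail $S = \sum_{i=0}^{y} p(i\mid x)$: $2S$ when $S \le 0.5$, otherwise
$2(1-S)$, clamped to $(0, 1]$.

Numerical strategy:

- point probabilities are evaluated in log space with `lgamma`, finite and
  positive for counts to $10^6$ and beyond;
- the cumulative sum uses the stable recurrence
  $p(i+1\mid x) = p(i\mid x)\,\frac{r\,(x+i+1)}{(i+1)(1+r)}$, $r = N_2/N_1$,
  accumulated by log-sum-exp;
- when $S > 0.5$, the complement is **not** computed as $1 - S$ (which loses
  all precision when $S \to 1$); the upper tail is summed directly by
  continuing the recurrence past $y$ in chunks until the geometric remainder
  bound is negligible. This keeps relative accuracy near $10^{-12}$ across
  the whole grid $x, y \le 200$, verified against exact rational arithmetic;
- p-values that would underflow to zero are reported as the smallest
  positive normal double so downstream FDR adjustment stays well defined.

Note that $p(y \mid x)$ conditions on library 1: swapping the roles of the
libraries rescales the point probability by $N_2/N_1$, so the statistic is
only symmetric at equal totals. The folded two-sided tail differs between
orientations only through the discrete tail convention.

Multiple testing is controlled by Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`, checked in the tests against a hand-executed step-up),
and a gene is significant iff FDR $< 0.001$ (strict, as the threshold is
stated) **and** $|\log_2 \mathrm{ratio}| \ge 1$ (non-strict). The log2 ratio
is computed on RPKM with a configurable floor (default 0.01) substituted for
zeros, so genes expressed in only one library get large finite ratios rather
than infinities. Genes significant in any pairwise stage comparison form the
DE union analyzed downstream.

# Profile groups, filter and clustering

For each DE gene the two consecutive ratios
$r_1 = \log_2(\mathrm{RPKM}_{s2}/\mathrm{RPKM}_{s1})$ and
$r_2 = \log_2(\mathrm{RPKM}_{s3}/\mathrm{RPKM}_{s2})$ place it in one of
four sign quadrants: I ($r_1 \ge 0 \wedge r_2 \ge 0$, up-regulated),
II ($\ge 0, \le 0$), III ($\le 0, \ge 0$) — both irregular — and IV (both
$\le 0$, down-regulated). The defining inequalities overlap at exact zeros,
so ties resolve by the fixed precedence I > II > III > IV; this makes the
groups a true partition (group counts always sum to the input size) at the
cost of assigning flat trajectories to group I. Ratios use screened
(floored) RPKM; group membership is computed for the whole DE union, while
the separate 32-fold filter (largest absolute stage step $< \log_2 32$) only
gates which genes enter global visualizations.

Trajectory clustering uses Euclidean k-means on $\log_2(\mathrm{RPKM}+1)$
per-gene standardized rows (constant rows map to zero), $k = 10$ by default,
with 10 random restarts keeping the best objective and a caller-supplied
seed for reproducibility. Standardization makes the clusters group *shapes*
rather than magnitudes, which is what profile clustering is after.

# Co-expression: PCC, Mutual Rank, top-k network

Correlation is computed across the three fruit-stage columns only; the
mixed-tissue reference library is excluded by default (a configuration
switch can include it) because stage comparisons are what the analysis
interprets. Genes with any zero RPKM are filtered before correlation, and
constant trajectories are dropped with a warning since their correlation is
undefined. With only three points a Pearson correlation is heavily
rank-degenerate (many pairs reach $\pm 1$); this is inherent to the design
and is deliberately not patched — Mutual Rank's tie-breaking (stable
gene-id order) keeps results deterministic regardless.

For each ordered pair, $\mathrm{rank}_{a\to b}$ is b's position in a's
neighbors sorted by descending correlation, and
$\mathrm{MR}(a,b) = \sqrt{\mathrm{rank}_{a\to b}\,\mathrm{rank}_{b\to a}}
\ge 1$, symmetric by construction. The network keeps an edge iff either
endpoint lists the other among its $k = 12$ best neighbors by ascending MR
(the union rule, matching the "for each gene" reading); consequently every
node keeps at least its own top-$k$ and none is isolated. Both MR and the
retention rule are verified against naive double-ranking on all instances
with up to 15 genes and on 50 random 100-gene instances. Sub-networks are
extracted as the induced subgraph on seed genes plus their direct
neighbors.

# KO-family aggregation

Family expression is summed over all catalog members sharing a KO id, per
stage, for both RPKM and raw counts. Family-level significance runs the
same exact test on the **summed raw counts** of each stage transition — not
on summed RPKM, since the test's sampling model applies to clean-read
counts; RPKM sums serve only the magnitude bins and ratio screens. A family
is `none` if no transition is significant, `up`/`down` if all significant
transitions agree in sign, and `irregular` otherwise. Selection files for
pathway viewers are three-column text (KO id, hex color, width token), with
a fixed 10-entry blue→red ramp indexed by the stage-1 magnitude bin, or the
four regulation-class colors (green none, red up, blue down, yellow
irregular).

# CIRG colorimetry

$\mathrm{CIRG} = (180 - H)/(L^* + C)$ with $C = \sqrt{a^{*2} + b^{*2}}$ and
$H$ the hue angle in degrees. The plain $\arctan(b^*/a^*)$ in the index's
definition is ill-defined for $a^* \le 0$, so the implementation uses the
four-quadrant arctangent mapped to $[0, 360)$; for ripening fruit
($a^* > 0$) the two coincide exactly. Averaging follows the measurement
design: CIRG per replicate reading, mean over replicates within a fruit,
mean (with standard error) over fruit within a stage.

# The synthetic-data generator

The generator emulates the study design, not any particular dataset: four
libraries (one mixed-tissue reference plus three ordered ripening stages)
of $5.3 \times 10^6$ clean reads; 40,000 genes with truncated-normal
lengths (mean 531 bp, sd 250, floor 100 bp, location-shifted so the
truncated mean lands on target); lognormal baseline expression
(sdlog 1.5, spanning the several-orders-of-magnitude dynamic range of real
RPKM tables); 10% of genes planted as differentially expressed in
proportions up : down : irregular = 0.25 : 0.40 : 0.35 (the ratio of the
four profile groups, with II + III as irregular); per-stage log2 steps
drawn from {1, 2, 3, 4}; 30% of genes carrying one of 400 synthetic KO ids.

Counts are drawn per library as Poisson around $N p_g$ with
$p_g \propto$ baseline × stage multiplier × length, normalized per library
(counts scale with transcript length because mapped reads are counted and
RPKM divides length back out). Setting `dispersion` $> 0$ draws the Poisson
mean from a gamma with that squared-coefficient-of-variation, giving
gamma-Poisson overdispersion; the default is 0 because the exact test's own
sampling model is simple Poisson-like sampling, and acceptance-style runs
use that default. Planted trajectories are geometric (a constant log2 step
per stage) for identifiability, and each is centered on its geometric mean:
planting then changes profile *shapes* without inflating any library's
composition. Without centering, stage-anchored multipliers up to $2^8$
inflate the last library's normalization several-fold, making every null
gene appear systematically "down" — a compositional artifact that
fixed-depth sequencing of a broadly stable transcriptome does not show
globally. The mixed library carries no multipliers and is excluded from DE
comparisons. Real libraries are a single pooled sample per stage, so the
simulator exposes replicates only for colorimetry.

Colorimetry trajectories darken and redden across stages (L* 30→15,
a* 14→13 with a mid-ripening chroma swing, b* 20→2.5) with Gaussian fruit
and replicate noise; the resulting stage CIRG means rise from about 2.3 to
6.0, matching the qualitative course of ripening color. Raw instrument
readings behind published CIRG values are typically not printed, so only
monotone increase — not specific values — is asserted.

What passing tests on this generator do **not** show: robustness to
overdispersion beyond the modeled gamma mixture, to mapping artifacts,
length biases within libraries, or to compositional shifts from genuinely
unbalanced regulation. The null-control and sensitivity results are
statements about the generator's conditions (Poisson sampling, the stated
depths and effect sizes), not about any real library.

# Problem sizes and numerical choices

The test suite validates the exact test against arbitrary-precision
rational arithmetic on the full $201 \times 201$ count grid at library-size
ratios $\{1/2, 1, 2\}$ (tolerance $10^{-10}$ relative), normalization of
$p(\cdot\mid x)$ to $10^{-9}$, false-positive control on twenty null
simulations of 10,000 genes at $10^6$ reads per library, and recovery of
planted effects of $\ge 3$ log2 units per stage (baseline expected counts
$\ge 50$) at sensitivity $\ge 0.95$ over ten seeds. The headline synthetic
study runs at the full default scale (40,000 genes, $5.3 \times 10^6$ reads
per library). Determinism is part of the contract throughout: identical
configuration and seed give bit-identical catalogs, counts, cluster
assignments and pipeline outputs.

# Known limitations

- No replicate-aware inference, dispersion estimation, or alternative DE
  tests: the exact test is the method implemented, with its known
  anti-conservativeness under biological variability.
- Three-point trajectories make correlation nearly rank-degenerate; network
  edges should be read as trend agreement, not fine-grained co-regulation.
- The family regulation call inherits the single-gene screen's thresholds;
  families mixing strong opposite regulation can appear `irregular` or
  cancel to `none` at the summed-count level.
- Pathway export targets a generic three-column selection dialect;
  viewer-version-specific syntax is out of contract.
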