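---
title: "Methods: correlation-based signature discovery and projection"
author: "mirSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-based signature discovery and projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirSig)
```

## The discovery model

The package targets a common experimental design in microRNA biology:
a cell line is transfected with mimics of one or more microRNAs (plus a
negative-control mimic), several replicates per group are profiled on an
expression array, and the goal is a gene signature of the microRNAs'
transcriptome-wide action that can be projected onto external tumor
cohorts. The statistical backbone has four layers.

**Normalization.** Raw (or log2) intensities are corrected sample by
sample against the median profile of all samples: for sample $j$ the
trend of $x_j - \mathrm{ref}$ as a function of $\mathrm{ref}$ is
estimated by robust locally weighted regression (LOWESS: locally linear
fits with tricube weights and robustifying iterations) and subtracted.
This removes smooth intensity-dependent distortions — background
offsets, saturation — without imposing identical distributions the way
quantile normalization would. Because subtracting trends moves the
per-gene medians, the correction is iterated against the re-computed
reference (at most 3 passes, stopping when the fitted trend amplitude
drops below 0.02 log2 units); one pass typically leaves a residual
trend of ~0.05–0.1 when distortions are strong, while the fixed point
is flat to well under 0.05. Analysis then proceeds on log2,
gene-median-centered values (the median, not the mean, is the centering
statistic: it is what the downstream fractional tree cut assumes and is
robust to the asymmetric tails that motivated the correction).

**Co-expression clustering.** Genes (and samples) are clustered
agglomeratively with the *uncentered* Pearson similarity
$s(x, y) = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}$,
distance $d = 1 - s \in [0, 2]$, and unweighted average linkage
(UPGMA). Uncentered correlation is scale-invariant but *not*
shift-invariant — after gene-median centering it rewards genes that
deviate from their median in the same samples with the same sign, which
is exactly the notion of co-regulation wanted here. An all-zero
(post-centering) profile is assigned similarity 0 ($d = 1$) by limit
convention. The linkage is computed by a nearest-neighbour-chain
agglomeration (exact for average linkage, which is reducible) in
compiled code, $O(n^2)$ time and memory, with deterministic
tie-breaking (reciprocal chain neighbour first, then smallest index) so
dendrograms are reproducible across platforms. Heights are
non-decreasing; the tests verify exact height agreement with a
brute-force $O(n^3)$ UPGMA reference.

Gene clusters are delimited by cutting the gene tree at a *fraction* of
the root merge height, default $1/5$. A fractional cut adapts to the
overall correlation level of the matrix; an absolute cut at $d = 0.2$
is available via `absolute = TRUE` for users who read the threshold as
an absolute distance — with typical root heights near 1 the two nearly
coincide. Clusters smaller than `minSize` (default 10; informative
co-expression clusters in this design have tens to hundreds of genes,
and smaller subtrees are mostly noise) are set aside.

**Collective tests instead of gene-wise multiplicity.** For each
cluster and each contrast, the per-sample mean over the cluster's genes
is computed and the two groups are compared with a two-sample Student
t-test (pooled variance; Welch via `varEqual = FALSE`). One test per
cluster removes the need for multiple-testing correction in the
unsupervised arm. The default selection threshold is $\alpha = 0.05$
per contrast. Note the power limit inherent to this design: the
within-cluster latent cofactor shared by a cluster's genes does not
average out of per-sample means, so with $n = 6$ per group, a unit
shift and cofactor spread 0.5 a single-contrast cluster is detected
with roughly 85–90% probability — a cluster differential in only one
contrast can occasionally fall at $\alpha = 0.05$ even when perfectly
recovered by the cut. Extracted clusters are annotated with a direction
pattern per contrast (`down@A|flat@B`, ...), the vocabulary in which
such clusters are described.

**Moderated t-statistics.** Gene-wise differential statistics use
empirical-Bayes variance shrinkage. With pooled residual variance
$s_g^2$ on $d_g = n_A + n_B - 2$ df, the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
$t_g = (\bar x_A - \bar x_B)/(\tilde s_g \sqrt{1/n_A + 1/n_B})$ is
referred to Student's t with $d_g + d_0$ df (standard normal at
$d_0 = \infty$; the classical pooled t at $d_0 = 0$, which the tests
exploit as an exact limit). The prior is estimated by moment matching
of log-variances: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, solve
$\psi'(d_0/2) = \overline{(e_g - \bar e)^2 G/(G-1) - \psi'(d_g/2)}$
(trigamma inverted by a monotone Newton iteration to $10^{-8}$) and
$\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2)$. A non-positive
right-hand side, or exactly identical variances, yields $d_0 = \infty$
with $s_0^2$ the (bias-corrected, respectively common) variance. Zero
variances are offset to half the smallest positive value and counted.
Multiplicity is controlled by Benjamini-Hochberg step-up FDR; gene
selection applies FDR < 0.05 and a 2-fold-change filter
($|\log_2 \mathrm{FC}| > 1$) by default, both configurable. The
independent cross-check in the test suite fits the same model through
limma and requires agreement of $t$ and $p$ to $10^{-8}$.

**Enrichment.** For a gene list and a term set, Observed is the term
frequency in the list and Expected its frequency on the whole chip (the
genes of the processed matrix — not the genome: the chip defines the
sampling frame). The fold-enrichment is their ratio, validated by a
one-sided (greater) Fisher exact test; depletion appears as fold < 1
and can be tested with the one-sided "less" alternative, two-sided on
request. `enrichMany()` adds an automatic "outside" list (background
minus the clusters) so that depletion outside the signature is visible
next to the enrichment within it, and BH-adjusts across the emitted
table.

**Signature and projection.** The signature is the union of the
differential clusters with per-gene cluster provenance; it can be
reduced to the genes that are targets of *both* microRNAs (shared
targets), a much smaller feature that inherits the clusters'
representativeness. Projection subsets an external cohort to the
matched signature genes (exact, case-sensitive symbol matching after
trimming; identifier harmonization is deliberately left to the user —
an error is raised below 20% match), gene-median-centers, clusters the
samples with the same metric and linkage, and splits them at the root
of the sample dendrogram: the root bipartition is the only
parameter-free reading of "left and right branch" (LB/RB). Branch
names are arbitrary (LB contains the first retained sample);
agreement with any external truth is therefore evaluated up to label
swap. Designated samples (e.g. healthy controls) can be excluded: they
are neither clustered nor used in statistics. Branch-differential
statistics run the moderated t over the *whole* transcriptome between
LB and RB at FDR < 0.01 with no fold filter.

## What the synthetic generator emulates — and what it does not

`generateDataset()` plants, for gene $g$ in sample $j$,
$$x_{gj} = \mu_g + a_g\,(\text{pattern}_c[\text{group}(j)] +
\sigma_z z_{cj}) + \varepsilon_{gj},$$
with $\mu_g \sim U(4, 12)$ (a log2-microarray-like dynamic range,
wide enough to exercise the intensity-dependent correction),
$a_g > 0$ the per-gene loading ($N(1, 0.2)$ floored at 0.1),
$z_{cj}$ a standard-normal latent factor shared by cluster $c$ in
sample $j$ (spread $\sigma_z = 0.5$), and
$\varepsilon_{gj} \sim N(0, \sigma_g^2)$ with
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$. The default prior
($d_0 = 4$, $s_0^2 = 0.05$) is a moderate-shrinkage regime in which
moderated and ordinary t visibly differ, so shrinkage is genuinely
exercised and the prior is recoverable from the simulated variances.
The default design is three groups of six samples (control, mimic A,
mimic B) and five clusters of 250–450 genes among 12,000, with shift
patterns covering the observed classes: down in one mimic only, up in
the other only, down in both, up in both, and opposite in the two
mimics. Target lists are Bernoulli memberships at a background rate
(default 0.10–0.15) multiplied inside cluster $c$ by a fold $\varphi_c$
(capped at probability 1), so realized fold-enrichments converge to
$\varphi_c$ with cluster size. Per-sample distortions are
$y = x + c_1 (x - \bar x) + c_2 (x - \bar x)^2$ with $|c_1| \le 0.08$
and $|c_2| \in [0.015, 0.035]$ (random sign) — smooth, monotone over
the simulated range, and large enough that uncorrected trends reach
0.3–1 log2 units. The external cohort shifts all signature genes by
$\pm\,\text{effect}/2$ (default effect 2) in two sample
subpopulations.

The generator does **not** emulate probe-level chemistry, scanner or
batch effects, correlated background genes, missing values, or the
identifier messiness of real platforms. Passing the recovery tests
therefore demonstrates the correctness and calibration of the
algorithms under their own model assumptions — not robustness to
annotation vintage or cross-platform effects, which on real data
dominate the variance of published gene counts.

One property of the inverse-chi-square noise deserves emphasis: its
heavy upper tail means a planted cluster always contains a minority of
genes too noisy to join their subtree below the 1/5 cut. Under the
default conditions the cut recovers ~80–85% of planted cluster genes
(recall), while the genes it does assign are assigned essentially
perfectly (adjusted Rand index ≈ 1 on the genes clustered in both
partitions — the agreement measure reported by the acceptance script,
alongside the recall). Cluster membership lists from real data should
be read the same way: reliable in what they include, not exhaustive.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `span` (LOWESS) | 0.4 | fraction of genes per local window; typical for robust scatterplot smoothing at chip scale |
| `iterations` (LOWESS) | 3 | robustifying reweighting passes |
| `maxPasses` / `tol` (normalization) | 3 / 0.02 | fixed-point refinement of the trend correction (log2) |
| `fraction` (tree cut) | 0.2 | of the root merge height; `absolute = TRUE` reads it as a distance |
| `minSize` (tree cut) | 10 | genes; smaller subtrees are treated as noise |
| `alpha` (collective test) | 0.05 | per-contrast cluster selection threshold |
| `fdrThreshold`, `foldThreshold` | 0.05, 2 | gene selection (BH q, anti-logged fold) |
| `fdrThreshold` (branch differential) | 0.01 | no fold filter |
| `effect` (external cohort) | 2 | total between-branch log2 shift on signature genes |

The LOWESS fit is computed on an anchor grid (spacing 1/1000 of the
abscissa range) with linear interpolation between anchors; on chip-sized
inputs this changes fitted values by far less than the 0.05 contract of
the normalization while keeping 40k-row matrices fast.

## Numerical and degenerate-input choices

- Distances are clamped to $[0, 2]$ against floating-point rounding;
  the distance of an all-zero profile is 1 by convention and such genes
  are never silently dropped.
- Linkage ties: reciprocal chain neighbour, then smallest index —
  deterministic dendrograms without a random tie-break.
- A gene constant in both groups gets $s_g^2 = 0$ and relies entirely
  on the prior (continuity of the shrinkage formula); equal means with
  zero pooled variance give $t = 0$, $p = 1$.
- `NaN` p-values propagate to `NaN` q-values and are excluded from the
  BH test count.
- Trigamma inversion starts from the asymptotic $x \approx 1/y + 1/2$
  and converges monotonically; $y \le 0$ maps to $d_0 = \infty$.
- Empty gene sets are retained with a warning (fold 0, q 1), an empty
  shared-target reduction returns an empty signature with a warning,
  and a projection matching < 20% of signature genes is an error that
  points at identifier harmonization.

## Design choices that were genuinely open

- **Log-space LOWESS.** Only "correction against a median profile" is
  specified by the procedure this package systematizes; the correction
  is performed on log2 intensities (MA-style), the standard scale for
  intensity-dependent bias, and matches the log2 scale of everything
  downstream. Linear-scale input is supported by transforming first
  (`log2AndCenter()` order is up to the caller).
- **Fractional vs absolute cut.** The 1/5 threshold is implemented as
  relative to the root height (robust to the matrix-wide correlation
  level), with the absolute reading one flag away.
- **Student vs Welch.** The collective test defaults to the
  equal-variance Student form; Welch is available by flag.
- **Probe collapse.** Keep the probe with the highest mean expression
  per gene (`"maxMean"`), a common convention when the true rule is
  unknown; `"mean"` averaging is provided.
- **Two-group contrasts only.** The design this implements is
  mimic-vs-control pairs; general design matrices would multiply the
  surface without serving the method.
- **Root bipartition for LB/RB.** The only parameter-free definition
  of two branches of a sample dendrogram; samples that would fall
  outside two dominant groups on real data (outlier subtrees) end up
  in one of the two branches and should be screened by inspecting the
  returned tree.

## Problem sizes used by the tests and the acceptance script

Module tests run on 500–2,000-gene instances for speed; the recovery
checks run the generator at its default 12,000 × 18 size. Oracle
comparisons use 200 random instances of ≤ 25 leaves against a
brute-force UPGMA, exhaustive hypergeometric tables for universes up to
N = 100 plus a seeded 2,000-table sweep up to N = 200, 50 simulation
seeds for prior recovery (G = 10,000), and 20 seeds for FDR calibration
(G = 4,000, 10% true effects). These sizes were chosen so the whole
verification runs in minutes on a laptop while leaving each statistical
check enough resolution to fail visibly if a formula were wrong.

## Known limitations

- Identifier harmonization (probe → symbol vintage, aliases) is out of
  scope; results on real cohorts are sensitive to it, and the projection
  API accepts pre-harmonized matrices only.
- The collective-test selection at $\alpha = 0.05$ is not corrected
  across clusters or contrasts by design (few tests), but users running
  many contrasts should account for that.
- Branch classification assumes two dominant subpopulations; cohorts
  with three or more expression programs will still be split in two at
  the root.
- The moderated-t implementation covers two-group comparisons without
  covariates, paired designs or array weights.
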