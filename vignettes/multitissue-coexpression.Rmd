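---
title: "Methods: multi-tissue two-condition co-expression network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue two-condition co-expression network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetonet)
```

## The analysis problem

`fetonet` targets a specific experimental design: several tissues profiled
by RNA-seq from the same individuals under two conditions — here written
`CON` (control) and `RES` (restricted), after the maternal-diet contrast in
fetal programming studies, with seven fetuses per group and three tissues
(cerebrum, liver, muscle) as the reference design. Differential expression
between the conditions is assumed to have been analysed elsewhere; the DEG
lists enter this package as *inputs*. What the package computes is the
layer above mean expression: which genes are tissue-specific, which
transcription factors change their wiring to DE/TS targets between
conditions, what the co-expression network across tissues looks like, and
which gene pairs and genes are differentially co-expressed or differentially
connected between the conditions.

## Preprocessing

Counts are CPM-transformed and a gene is dropped when its CPM is below 1 in
at least `ceiling(0.8 * n_samples)` samples. The 80% boundary is read
strictly: at 14 samples a gene low in 11 samples survives, one low in 12 is
removed.

Two normalization strategies coexist, because the downstream consumers
differ:

* **pooled** — all tissues and samples together; used by Tau, RIF and the
  tissue-to-tissue network, which all compare expression *across* tissues.
* **per-tissue** — each tissue separately, followed by a dispersion filter
  that removes genes below the 0.2 quantile of the per-gene coefficient of
  variation; used by the differential co-expression and differential
  connectivity analyses, which operate *within* a tissue.

Normalization is median-of-ratios size factors followed by
`log2(count/sf + 1)`. This is a deliberate simplification of a
fitted-dispersion variance-stabilizing transform: every method downstream
consumes a monotone, log-like, depth-corrected scale and none depends on the
exact variance profile of the transform. The dispersion measure (per-gene CV
of normalized values, filtered below the 20th percentile) is likewise a
stated choice: "quantile dispersion" has no unique definition, and the CV
quantile is the simplest measure that removes flat, uninformative genes
before pair-wise correlation work.

An optional covariate-adjustment step (off by default) removes an additive
fetal-sex effect per gene by OLS residualization, restoring the grand mean.
It is off by default because the reference analyses fold sex into the
DE model rather than into the network inputs.

## Tissue specificity (Tau)

For per-tissue mean profiles \(x_1,\dots,x_n\) (negative post-transform
values clipped to 0) with \(\hat x_i = x_i / \max_i x_i\):

\[ \tau = \frac{\sum_{i=1}^{n}(1 - \hat x_i)}{n - 1} \in [0, 1], \]

0 for uniform expression, 1 for single-tissue expression; genes with
\(\tau \ge 0.8\) are called tissue-specific (inclusive cutoff). Tau is
scale-invariant and label-permutation-invariant, which the test suite
asserts over random profiles. Home-tissue ties are broken by tissue-name
order; an all-zero profile yields `NA`, never 0.

## Regulatory impact factors

With per-condition TF-target correlations \(r_{1ij}, r_{2ij}\), target
condition means \(e_{1j}, e_{2j}\), abundance \(\bar a_j\), differential
expression \(d_j = e_{1j} - e_{2j}\) and PIF\(_j = \bar a_j d_j\):

\[ \mathrm{RIF1}_i = \frac{1}{n_t}\sum_j \mathrm{PIF}_j\,
   (r_{1ij} - r_{2ij})^2, \qquad
   \mathrm{RIF2}_i = \frac{1}{n_t}\sum_j (e_{1j} r_{1ij})^2 -
   (e_{2j} r_{2ij})^2. \]

The original RIF software is unpublished Fortran; these formulas are the
standard published statement of the two metrics (PIF-weighted squared
differential wiring; change in squared expression-weighted predictive
correlation) and are isolated in `rif_scores()` so an alternative variant
can be substituted in one place. Raw scores are exactly antisymmetric under
swapping the conditions and scale as \(c^2\) when all expression is scaled
by \(c\); both properties are asserted algebraically in the tests. Scores
are z-standardized over the TFs within a tissue and a TF is "key" when
either |z| passes the two-sided normal threshold at p ≤ 0.01. Because the
raw score distribution over a finite TF panel is skewed, the z approximation
is approximate; the null-calibration test bounds the empirical rate at
p ≤ 0.01 by 0.10 over 500 replicates of 200 null TFs. The target list is
the union of the DEG input and the TS calls, per tissue, using the pooled
normalization restricted to the tissue's samples.

## PCIT network inference

For each gene trio \((x, y, z)\) the three first-order partials

\[ r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}} \]

define the trio tolerance
\(\varepsilon = \tfrac13 ( r_{xy\cdot z}/r_{xy} + r_{xz\cdot y}/r_{xz} +
r_{yz\cdot x}/r_{yz} )\), and the association \(x\)–\(y\) is flagged
non-significant if for some \(z\):
\(|r_{xy}| \le |\varepsilon\, r_{xz}|\) and
\(|r_{xy}| \le |\varepsilon\, r_{yz}|\). Numerical guards: a ratio with
\(|r| < 10^{-12}\) in the denominator is treated as 1 (maximal redundancy),
and a flanking correlation of magnitude 1 eliminates the conditioned pair
outright. With only two genes no conditioning gene exists and the pair is
retained by convention.

Two implementations ship: a C++ trio sweep (`pcit()`) and a brute-force R
oracle (`pcit_ref()`); the acceptance suite requires bitwise-identical
masks on random correlation matrices up to 50 genes. One property of the
rule worth stating explicitly, because intuition suggests otherwise: in a
strong triangle where \(r_{xy} = r_{xz} r_{yz}\) exactly (a "purely
indirect" edge) with all three correlations large, the vanishing partial of
the indirect pair *lowers the trio tolerance*, and all three edges survive.
The rule only eliminates associations weak relative to
\(\varepsilon \times\) their flanks — which is why PCIT networks are dense.
Both implementations agree on this; the three-gene benchmark tests freeze
the oracle-computed outcomes.

Network edges are PCIT-surviving pairs with raw |r| > 0.9 (strict). The
threshold is applied to the raw correlation of surviving pairs, consistent
with standard PCIT usage; `threshold_on = "partial"` applies it to the
minimum absolute partial instead for sensitivity analysis. Condition-
specific networks additionally require a DEG or TF endpoint per edge.
Degree, the average local clustering coefficient (0 for degree < 2),
mean + 2 SD hub calls (no hubs under zero degree variance), and the
scale-free fit (R² of log10 frequency on log10 degree over distinct
positive degrees, `NA` below 3 distinct values) are computed through
igraph. The C++ sweep is \(O(n^3)\) time and \(O(n^2)\) memory; ~3,000
genes is a practical single-machine cap, beyond which inputs should be
pre-filtered (as the per-tissue dispersion filter does).

## Differential co-expression

Per tissue, all unordered pairs are tested with the Fisher z difference
statistic \(dz = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}\) against a standard normal, BH-adjusted;
pairs at q ≤ 0.05 are differentially co-expressed. Each condition maps to
{+, −, 0} by correlation sign and a within-condition p ≤ 0.05 (t test on
r), giving the composite class ("+/−", "0/+", ...); "0/0" rows are reported
but excluded from the eight-class summary. At \(n = 7\) per condition the
normal approximation is anti-conservative; a label-permutation mode
(`permute = B`, seed-controlled) is provided and recommended at such sizes.
The analytic mode is the default because it is deterministic and exact at
the simulated calibration sizes — the test suite verifies a [0.04, 0.06]
rejection rate at the null with r = 0.5 and n = 30 per group over 5,000
pairs. For high-dimensional tissues the pair universe can be restricted
post hoc to pairs touching a gene of interest (`restrict_to`), mirroring
how cerebrum-scale outputs are handled in practice.

## Differential connectivity

Connectivity is degree normalized by the network's maximum degree, so
K ∈ [0, 1]; \(DK_i = K_{CON}(i) - K_{RES}(i)\) is z-scored over the gene
universe and |z| ≥ 1.96 is significant. Two choices here were genuinely
open:

* **Gene universe.** The networks record every gene they were inferred
  over as a node (degree 0 allowed), and DK is scored over the union of
  the two node sets; genes connected in only one condition get K = 0 in
  the other (they are maximally rewired). At desk scale this matters: a
  planted rewired module is a sizable fraction of the *connected* nodes,
  and restricting the universe to connected genes makes its DK values the
  distribution's own bulk, which the ±1.96 SD rule can then never exceed.
  Scoring over all tested genes keeps the rewired group in the tail, which
  is also the regime the rule was designed for on full-transcriptome data.
  `drop_unshared = TRUE` restricts to genes present in both node sets.
* **Centering.** The z-score subtracts the mean DK by default
  (`center = FALSE` is one flag away); with roughly balanced rewiring the
  mean is near zero and the choice is immaterial, but subtracting it makes
  the ±1.96 rule calibrated when one condition is systematically denser.

DK is exactly antisymmetric under swapping the inputs, identical networks
give no calls, and exchangeable random networks flag ≈5% of genes — all
asserted in the tests. The union network tags nodes and edges CON / RES /
shared for rewiring visualisation in Cytoscape.

## The synthetic data generator

`simulate_dataset()` emulates the reference design: 3 tissues × 2
conditions × 7 fetuses by default (each fetus contributes one sample per
tissue; sex alternates M/F within condition), negative-binomial counts
(Gamma-Poisson, dispersion 0.05 — a typical RNA-seq gene-level value),
log-normal library sizes (mean 10⁶, CV 0.2), and a log-scale mean per gene
assembled from: a baseline drawn log-uniformly over 50–5,000 counts;
a tissue-specific elevation (home-tissue mean 300, off-tissue mean
300/`ts_fold` with `ts_fold = 300` — real TS genes are essentially silent
outside their tissue, and this keeps planted τ ≈ 0.91, safely inside the
0.8 call); a DE shift of 1 log2 unit in RES; and module structure.

Each module has one regulator and `module_size − 1` members tied to a
per-sample standard-Gaussian latent factor. The regulator carries the
factor with loading 1; member loadings are calibrated analytically so that
the *observed* log-scale regulator–member correlation — after biological
noise (sd 0.3 on the natural-log scale) and counting noise
(\(\mathrm{Var}(\log X) \approx 1/\mu + \phi\) by the delta method) —
equals the configured coupling. The calibration was validated against
direct simulation at 10,000 samples before the ±0.1 recovery tolerance was
frozen. Member–member correlation is then coupling² × (1 + v) — modules
with coupling ≥ 0.95 become near-cliques above the 0.9 edge threshold,
which is deliberate for the stable module (it keeps both condition
networks non-empty).

The default three modules plant one signal for each differential analysis:
couplings (CON → RES) of +0.8 → −0.8 (a sign flip: DC class "+/−" and the
dominant RIF1 signal), 0.95 → 0 (decoupling: the DK rewiring signal), and
0.95 → 0.95 (stable control). Module members also receive the DE shift and
are listed in the DEG truth: RIF weights each target by
PIF = abundance × differential expression over the DEG ∪ TS target list,
so a regulator whose targets were neither DE nor TS would have PIF ≈ 0
everywhere it is wired and could never rank — coupling the planted modules
to the target list is what makes regulator recovery a fair test of RIF
rather than a contradiction in the fixture. The sex effect (0.5 log2 on a
random 1% of genes) is confined to background genes so covariate exercises
never confound the planted structure.

What the generator does *not* emulate: read-level artefacts (GC content,
length bias, mapping ambiguity), batch effects beyond sex, compositional
library effects, between-fetus correlation across tissues (latent factors
are drawn per sample, not per fetus), or the long-tailed mean-variance
profiles of full transcriptomes. Passing tests therefore demonstrate that
the algorithms recover the statistical structure they model — planted
specificity, correlation changes, rewiring — not that any biological claim
about real tissues is reproduced.

## Problem sizes and determinism

The shipped fixtures use 600 genes, 3 tissues, and 7 + 7 fetuses (the
design's own size) for smoke and I/O tests, and a 30 + 30 variant for the
recovery tests, where per-pair correlation noise (sd ≈ 0.07 at r = 0.8) is
small enough that recovery rates are stable in the high 90s across seeds;
these sizes keep the whole suite under two minutes while leaving every
assertion comfortably away from its threshold. All randomness flows from a
single integer seed: the generator seeds its own RNG, the permutation mode
takes an explicit seed, and a pipeline rerun under the same seed is
byte-identical in every exported file (asserted in the acceptance tests).

## Known limitations

* The RIF formulas are the standard published reconstruction, not the
  unpublished original implementation; sample-size weighting variants
  cannot be ruled out and would slot into `rif_scores()`.
* The VST stand-in does not reproduce a fitted dispersion trend; variance
  at very low counts is less stabilized than under a model-based VST.
* The Fisher z test is anti-conservative at n = 7 per group; use the
  permutation mode for inference at the original design size.
* PCIT thresholds the raw correlation of surviving pairs by default; the
  alternative reading (thresholding the partial) is available but changes
  edge counts substantially on dense modules.
* Scale-free R² on small dense fixtures is fit over few distinct degrees
  and should be read qualitatively there; the statistic is meaningful on
  transcriptome-scale networks.
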