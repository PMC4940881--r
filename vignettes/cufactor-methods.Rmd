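---
title: "Methods: factorial classification, clustering, enrichment and network shells"
author: "cufactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial classification, clustering, enrichment and network shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufactor)
```

This vignette records how the pipeline models a 2×2 factorial
(strain × copper) transcriptome experiment, which choices were genuinely
open, why they were settled as they are, and what the synthetic-data
generator does and does not emulate.

## The per-gene model

Expression enters the pipeline on the linear scale (dChip-style summarized
intensities). Values at or below 1.0 linear units are clipped to 1.0 and
counted, because everything downstream takes log2. Arrays are rescaled
multiplicatively so every sample's median equals that of the baseline
array — the sample whose overall median is the median of the per-sample
medians (lower of the two central samples for an even count). Median
rescaling is scale-only: it leaves within-array contrasts untouched.

Per gene, the balanced 2×2 fixed-effects ANOVA is computed on log2 values
in closed form (vectorized across genes; `stats::aov` is used only as an
independent oracle in the test suite). With $r$ replicates per cell the
strain, copper and interaction sums of squares each carry 1 df against a
$4(r-1)$-df residual. Fold changes are deliberately computed on the
*linear* scale — ratios of cell means, as microarray fold changes are
conventionally reported — while testing happens on log2, which stabilizes
the variance. The model is unmoderated: no empirical-Bayes shrinkage and,
by default, no multiple-testing correction on the ANOVA p-values, matching
the conventional per-gene α = 0.05 workflow this pipeline reproduces.
With duplicate arrays this means each F test has only 4 residual df;
consequences are quantified below.

### The degenerate-gene limit

A gene with zero within-cell variance has no error term. Rather than
declaring every such gene untestable, the pipeline takes the exact
closed-form limit: an effect with positive sum of squares on noiseless
data is infinitely significant ($p = 0$), an effect with zero sum of
squares is absent ($p = 1$); the gene is still flagged `degenerate`. An
entirely constant gene therefore gets all $p = 1$, while a noiseless gene
with a planted effect is classified exactly by its planted pattern. This
is what makes the zero-noise round trip (generator → classifier → planted
labels, 100 % agreement) exact rather than approximate.

## Classification gates

Group labels follow interaction-first precedence: G4 (interaction
significant, any of the four contrasts ≥ 1.5), then G3 (both main effects,
interaction not significant, a deletion contrast *and* a copper contrast
at threshold), then G1/G2 (one main effect only, with a qualifying
same-factor contrast), else NS. Two points were genuinely open:

* **Either vs both copper levels for the G3 gate.** The default is
  "either" (one qualifying contrast per factor suffices), with a strict
  `g3_gate = "both"` mode in the configuration. "Either" mirrors how
  deletion-responsive genes are usually described — differential under
  copper deficiency *or* excess.
* **Direction labels.** Per-factor direction is the sign of the mean of
  the two same-factor log2 ratios; when the two contrasts disagree the
  gene keeps that dominant direction but is flagged
  `direction_inconsistent` rather than dropped.

## SOM clustering

Interaction-group genes are represented by the four design-cell means of
log2 expression, z-scored per gene (shape, not level). The map is a 2×3
rectangular grid — six clusters — trained by the classic online Kohonen
rule: prototypes initialized from randomly sampled data rows, 500 epochs,
learning rate decaying linearly from 0.5, Gaussian neighbourhood with
radius shrinking linearly from 1.5 grid units (floored at 0.05 to avoid a
vanishing kernel), best-matching unit by Euclidean distance, all under a
single seed so assignments are bit-reproducible. These hyperparameters are
fixed defaults, not fitted quantities; with six well-separated archetype
shapes and small perturbation the map recovers the planted partition with
adjusted Rand index 1.0.

## Enrichment statistics

All over-representation tests use the exact hypergeometric upper tail
computed by log-gamma summation. Two conventions exist in the wild:

* the standard over-representation p-value **includes** the observed
  count, $P(X \ge k)$ — this is the default;
* legacy `1 - cdf(k)` implementations (common in older MATLAB-based
  analyses) give the strictly-greater tail $P(X > k)$ — available as
  `include_observed = FALSE`.

For the worked shell-enrichment configuration (44 annotated among 161
shell genes; population 2354 with 417 annotated) the two conventions
straddle the 0.001 significance bound ($1.12\times10^{-3}$ vs
$5.77\times10^{-4}$), so the pipeline keeps the convention explicit
instead of burying it.

GO-style enrichment uses a **flat** gene→term map: no DAG ancestor
propagation. Tools that propagate annotations up the ontology will produce
different term-level results, particularly for broad terms — a documented
limitation, not a bug. TF-regulon enrichment restricts the population to
genes with at least one documented regulator, uses each TF's target count
within that population, and Bonferroni-corrects over the TFs actually
testable (≥ 1 target in the population) at α = 1e-4.

## Network shells and paths

Genetic-interaction networks are simple undirected graphs: self-loops
dropped, parallel edges merged with the union of their interaction-type
labels, orientation ignored (genetic interactions are symmetric in use).
Distance is unweighted shortest-path length; type labels never weight
edges. Around a focal gene the reachable nodes decompose into BFS shells;
shortest-path enumeration walks the predecessor structure and returns
every minimal path in lexicographic order, truncated with a flag at
10,000 paths. Shell-conditioned enrichment takes an *explicit* background
population — the classic recipe tests a responsive-subnetwork shell
against a complete-network shell population, and since sample and
population are then different sets, the observed count is clamped into
the test's support. Graph operations are delegated to igraph; the test
suite holds them against hand-rolled Floyd–Warshall, exhaustive-DFS and
set-filter oracles on random instances.

## qPCR quantification

Housekeeping candidates are ranked by coefficient of variation of linear
expression across all arrays (ascending; ties lexicographic). CV is the
simplest defensible stability metric; nothing in the pipeline depends on
a more elaborate geNorm-style pairwise variation. Quantification follows
2^−ΔΔCq with the geometric mean of the housekeeping Cq values as the
per-condition normalizer — applied to Cq values directly, as stated
workflows do, even though the geNorm convention applies it to relative
quantities; technical replicates are averaged arithmetically on the Cq
scale first, and biological samples enter as mean-of-means. The
antisymmetry $FC(A,B)\cdot FC(B,A) = 1$ is property-tested.

## What the generator emulates — and what it does not

`simulate_factorial_expression()` draws per-gene log2-additive effects on
a 2×2 design with duplicate arrays and Gaussian replicate noise, emitting
linear-scale values. Defaults are the study conditions the pipeline
targets: effect size 1.0 log2 units, noise sd 0.25 log2 units (replicate
variance is not published for such designs; 0.25 is a realistic
hybridization-replicate figure and is exposed in the spec), baseline
2^10, and class proportions following the relative group sizes observed
in a genome-scale deletion×copper study (210:733:57:17:22:10:305
responsive genes of 5667). Planted G4 genes are pure crossovers — copper
response $+e$ in one strain, $-e$ in the other — the canonical
strain-dependent copper response and the interaction morphology strong
enough (noncentrality 32 at the defaults) for the documented ≥ 90 %
recovery; a single-cell interaction of the same magnitude would have
noncentrality 8 and power only 0.57 with 4 residual df.

At the default conditions the expected recovery of planted non-null
labels is ≈ 0.92 — not higher, because uncorrected α = 0.05 testing with
4 df loses ~9 % of single-main-effect genes to false-positive secondary
effects (a deletion-only gene is misrouted whenever the copper or
interaction F fires, which happens for 1 gene in 11 even under the null).
That ceiling is a property of the published analysis design itself, which
the generator faithfully reproduces.

The generator does **not** emulate probe-level data, probe-set
summarization, inter-gene correlation, intensity-dependent
(heteroskedastic) noise, or array batch effects; passing tests therefore
validate the statistical machinery, not robustness to those artefacts.
Network simulation is Erdős–Rényi with minimal bridging to connectivity
(the simplest connected null; preferential attachment is deliberately not
the default), a planted Bernoulli annotation in one chosen shell, and
uniform interaction-type labels. Regulon simulation plants one enriched
TF by composing the query from its targets at a chosen overlap fraction;
overlap 0 degenerates to a uniform null draw used to calibrate the
false-positive rate. Cq simulation is the algebraic inverse of ΔΔCq, so
generator → quantifier is an exact round trip at zero jitter.

All generators derive child seeds deterministically from one global seed
(`derive_seed()`), so pipeline stages can be regenerated independently
without perturbing each other.

## Problem sizes and numerical tolerances

The test suite runs at the study's native scale where that is cheap
(5667-gene simulations for recovery and proportion checks; 10,000 null
genes for type-I calibration; 100 replicate seeds for network and
regulon Monte-Carlo) and at reduced scale for brute-force oracles
(random graphs ≤ 50 nodes for Floyd–Warshall, ≤ 16 for exhaustive path
enumeration — chosen so the oracles themselves stay exact and fast).
Closed-form comparisons use 1e-9 tolerances (ANOVA vs explicit sums of
squares, ΔΔCq round trips) or 1e-12 (hypergeometric tail vs frozen
exact-rational constants); Monte-Carlo assertions use bounds implied by
the binomial sampling error at the stated replication.

## Known limitations

* Flat annotation maps only — no GO DAG propagation, no ontology parsing.
* No amplification-efficiency (Pfaffl) correction in qPCR.
* No empirical-Bayes moderation; with duplicate arrays the per-gene error
  variance is estimated on 4 df and the group counts inherit the
  corresponding false-positive load.
* The SOM is a fixed-grid online implementation; batch SOM and
  alternative topologies are out of scope.
* BioGRID parsing targets the TAB 2.0/3.0 header dialects; earlier
  positional dialects are rejected with an explicit error.
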