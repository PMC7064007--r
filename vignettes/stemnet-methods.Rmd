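---
title: "Methods: co-expression screening for secondary cell wall regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression screening for secondary cell wall regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemnet)
```

## The problem

Grass stems accumulate most of their biomass as cell walls. The secondary
cell wall (SCW) — the thick, lignified wall deposited after cells stop
growing — determines standability, digestibility and the value of the stem
as a lignocellulosic feedstock. The transcription factors that switch SCW
deposition on are well described in *Arabidopsis* (MYB and NAC master
regulators), but identifying their functional counterparts in a C4 grass
requires expression evidence, not only sequence homology.

`stemnet` implements a screening strategy built on developing-internode
RNA-seq: genes whose expression rises and falls together across internode
development are grouped into co-expression modules; modules whose members
are enriched in cell-wall (CW) biosynthesis annotations, and whose
expression peaks coincide with the measured accumulation of hemicellulose,
cellulose and lignin, are treated as wall-building programs; MYB/NAC
transcription factors embedded in those modules — especially the highly
connected "hub" ones — are the candidate regulators.

## Pipeline overview

1. **Filter** — keep genes with more than `min_reads` (default 3) reads in
   at least `min_samples` (default 20) samples. The rule is strict
   (`> 3`, i.e. at least 4 reads); the boundary is unit-tested.
2. **Normalize** — TMM scaling factors (trimmed mean of M-values, 30%/5%
   trims, reference sample by upper-quartile proximity) followed by
   `log2(CPM + 1)` on effective library sizes. The pseudo-count is applied
   after scaling, so the output is exactly invariant to multiplying a
   sample's counts by a constant.
3. **Batch assessment** — per-gene ordinary least squares on sum-to-zero
   coded nuisance factors (year, block), reporting level coefficients and
   a root-mean-square global magnitude, and subtracting the fitted batch
   terms. Biological factors (stage, internode, regime) are deliberately
   left unmodeled.
4. **Network** — Pearson correlation, soft-thresholded adjacency at power
   `beta = 12`, topological overlap, average-linkage clustering of
   `1 - TOM`, static cut, eigengene merging, strong-correlation
   refinement, intramodular connectivity and hub ranking.
5. **Enrichment** — one-sided hypergeometric tests per GO term, a
   one-sided Fisher test against a curated CW gene list, keyword grouping
   (e.g. an `SCW` keyword bundling the secondary-wall biogenesis terms).
6. **Bait subnetworks** — for every MYB/NAC bait, the top 15 correlated
   genes and the top 15 of each of those, a union list of at most
   `1 + 15 + 15^2 = 241` genes, its CW GO-term count, and an ordinal
   enrichment category.
7. **Biochemistry** — Van Soest fractions reduced to wall components
   (hemicellulose = NDF − ADF, cellulose = ADF − ADL, lignin = ADL) and
   compared across stages with Welch tests, Holm correction and a compact
   letter display.

## The network model

For genes $i, j$ with expression correlation $r_{ij}$, the default
adjacency is the *signed-hybrid* form

$$a_{ij} = \begin{cases} r_{ij}^{\beta} & r_{ij} > 0 \\ 0 & r_{ij} \le 0 \end{cases}$$

with $\beta = 12$. Negative correlations carry no weight, so modules
group genes co-varying in the same direction. Two other variants are
available (`unsigned`: $|r|^\beta$; `signed`: $((1+r)/2)^\beta$). The
signed-hybrid default was chosen because it is the only variant under
which an adjacency cutoff of 0.1 at $\beta = 12$ corresponds to a
correlation of about 0.82 ($0.82^{12} \approx 0.092 \approx 0.1$), the
threshold pair this screening convention is built around; under the
`signed` form an adjacency of 0.1 would instead correspond to
$r \approx 0.65$.

The topological overlap of two genes combines their direct adjacency with
the adjacency they share through common neighbors:

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_j a_{ij}.$$

Modules are found by average-linkage clustering of $1 - \mathrm{TOM}$
with a **static** cut (height 0.99), removal of clusters smaller than
`min_module_size` (30), and iterative merging of modules whose eigengenes
(first principal component of the standardized module expression,
oriented to correlate positively with the module mean profile, unit norm)
correlate above 0.75. The full dynamic tree-cut algorithm is not
implemented: the static cut has two transparent parameters, behaves
identically on the planted-structure benchmarks used throughout the test
suite, and keeps the module definition easy to reason about. Its
parameters are exposed so users can tighten or relax the cut.

Module naming is deterministic: a fixed color palette assigned by
decreasing module size (ties broken by the lexicographically first member
gene). Ranking ties anywhere in the package break by descending score
then ascending gene ID.

**Strong-correlation refinement.** A gene is retained in its module iff
its best within-module adjacency reaches `adjacency_threshold` (0.1);
modules with fewer than `min_retained` (3) retained genes are dropped.
The quantifier — *at least one* partner at or above the threshold — is
the permissive reading; raising the threshold can only shrink retained
sets (property-tested).

**Scale-free topology scan.** For each candidate power the scan reports
mean connectivity and a signed fit index: the $R^2$ of the log–log
regression of the connectivity-bin *density* (frequency per unit
connectivity, over equal-count bins) on mean bin connectivity, signed by
the negative slope sign. Density rather than raw frequency is used
because equal-count bins have constant frequency by construction.

## Enrichment statistics

Per-term enrichment is the classic one-sided hypergeometric upper tail
$P[X \ge x]$; the custom-list test is the equivalent one-sided Fisher
exact test. Two deliberate simplifications:

* **Flat annotation.** GO terms are treated as independent flat labels;
  no ontology-graph ancestor propagation and no graph-based
  decorrelation (such as the weight-based refinements of graph-aware GO
  tools) is applied. P-values on real annotations will therefore be more
  correlated between related terms than a graph-aware method would
  produce.
* **No multiple-testing correction by default** — significance is a raw
  $p < 0.05$ call, matching the screening character of the procedure; a
  Benjamini–Hochberg option is available (`adjust = "BH"`).

The test universe is the set of genes surviving the expression filter
(the genes that could have appeared in any module), the standard choice
when none is stated.

## Bait subnetworks and categories

Each MYB/NAC bait seeds a two-layer neighborhood: its top 15 correlated
genes, then the top 15 of each of those, ranked by raw signed correlation
(for positive correlations this ordering is identical to ranking by
adjacency, since $x \mapsto x^{12}$ is monotone). The union list includes
the bait — that is what makes the disjoint-neighborhood maximum exactly
$1 + 15 + 225 = 241$. Neighbor pools are global, not restricted to the
bait's module, so a subnetwork can recruit genes across module
boundaries.

The count of significant CW GO terms in the union list maps to an ordinal
category with half-open bounds: `none` (< 3), `light` (3–5), `medium`
(6–11), `high` (≥ 12). The printed bounds this convention descends from
overlap at their endpoints (3–6, 6–12, 12–18); the half-open reading
keeps the classification total and monotone, with `high` unbounded above
because 18 was simply the largest observed count.

Baits can fail screening in two ways, reported explicitly:
`excluded_low_expression` (dropped by the read filter, hence absent from
the network) and `excluded_weak_correlation` (present but with no
within-module partner above the adjacency threshold).

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
It emulates:

* **The sampling design** — 191 internode samples over three years:
  2013 contributes 71 (internodes 12 and 16 × five stages × two water
  regimes × four replicates, with the top internode absent at the first
  stage and one replicate lost), 2014 contributes 72 (six internode
  levels partially crossed with three stages × two regimes × three
  replicates), 2015 contributes 48 (four levels × two stages × two
  regimes × three replicates). The single lost 2013 replicate is the one
  element not derivable from the design description; it is fixed in the
  default configuration so the total is reproducibly 191.
* **Planted co-expression modules** — each module draws a latent
  Gaussian bump over the ordered stage index (the simplest unimodal
  family matching single-peaked developmental expression), standardized
  over the realized samples. A member gene's log2 mean is
  `baseline + loading × latent + noise`; the per-module noise variance is
  calibrated analytically so the realized mean pairwise log-CPM
  correlation approximates the target `within_correlation`, *including*
  the negative-binomial counting variance
  ($\approx (\log_2 e)^2(\phi + 1/\mu)$). The first gene of each module
  carries the largest loading and is the planted hub. Defaults: five
  60-gene modules peaking at stages D1–D5, target correlation 0.9,
  amplitude 2 (log2 units), 1,700 background genes.
* **Counts** — negative binomial with dispersion 0.05 (a typical
  replicated-field-trial value) and log-uniform library sizes between
  0.5 and 2 million, small enough that the full pipeline runs in
  seconds; all sizes are configurable up to genome scale.
* **Annotations** — CW GO terms (20 BP + 8 CC) concentrated in the
  modules with a positive `cw_annotation_rate` (defaults: the two
  late-peaking modules at rate 1, mirroring SCW programs), three
  background terms per gene, a keyword map whose `SCW` keyword has four
  member terms, and designated MYB/NAC baits with clade labels.
* **Fiber trajectories** — per-component logistic accumulation over the
  stage index with the lignin inflection constrained to not precede the
  polysaccharides' (lignification trails polysaccharide deposition), a
  plateau near 30/25/6 %DM for hemicellulose/cellulose/lignin, and 1 %DM
  replicate noise. Generated values are quantized to 1/128 %DM — below
  any measurement resolution — which makes the NDF/ADF/ADL sums and
  differences exact in floating point, so the identity
  hemicellulose + cellulose + lignin = NDF holds to the bit.

What the generator does **not** emulate: technical lane replicates (it
models merged samples), water-deficit differential expression (the
screening procedure does not analyze treatment response), GC/length
biases, batch artifacts (these are planted explicitly in the batch tests
instead), and annotation incompleteness. Passing the planted-recovery
tests therefore demonstrates that the machinery is correct, not that
real internode data will yield modules this clean: realized correlations
in field data are weaker, module sizes far more skewed, and annotation
noise substantial.

## Numerical and testing choices

* Problem sizes: unit tests run at 60–400 genes; the planted-recovery
  and null-calibration checks run the full default 2,000-gene ×
  191-sample conditions (three and one seeds respectively), hub recovery
  runs 20 seeds on planted-module submatrices, and enrichment
  calibration draws 1,000 random sets from a 400-gene universe. These
  sizes give stable statistics while keeping a complete run to a couple
  of minutes on one core.
* Brute-force oracles back the closed-form paths: a triple-loop TOM, a
  double-loop connectivity, direct hypergeometric tail enumeration, and
  a reference batch-removal implementation.
* Degenerate inputs fail loudly: all-zero samples, constant genes
  (dropped with a warning in correlation, an error in eigengenes),
  fiber-ordering violations, baits missing from the annotation.
* Percentages in clade summaries round half away from zero; this is the
  convention that reproduces the worked 44/54 → 81% example, and base
  R's half-to-even rounding does not.
* `compare_stages` uses pairwise Welch t-tests with Holm correction — a
  conservative default for four-replicate field data — and a greedy
  insert-and-absorb compact letter display. The letter display is a
  presentation convention, not an inference procedure.

## Known limitations

* The static tree cut can fragment large diffuse modules that the
  dynamic hybrid cut would keep whole; for exploratory work on real
  data, sweep `cut_height` and `min_module_size`.
* Flat GO annotation overstates the number of independent CW terms when
  the ontology graph is deep; the CW term *counts* feeding the category
  classification are therefore only comparable between subnetworks
  annotated with the same vocabulary.
* Single-block correlation and TOM matrices are dense; beyond roughly
  20,000 genes, memory (not time) becomes the binding constraint, and a
  block-wise decomposition would be needed.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 1, simulate = TRUE,
                         output_dir = "stemnet_output"))
res$cw_modules          # which modules carry the dual CW evidence
head(res$evidence)      # baits ranked by enrichment category
```
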