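---
title: "Methods: drug-reversal ceRNA network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-reversal ceRNA network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernarev)
```

## The question the package answers

A three-group design — control animals, a disease model (for example the
methionine-and-choline-deficient, MCD, diet model of non-alcoholic
steatohepatitis), and disease animals receiving a treatment — yields two
contrasts: disease vs control, and treated vs disease. A transcript whose
disease-induced change is undone by the treatment shows a *reversal
pattern*: up in the first contrast and down in the second, or vice versa.
Under the competing endogenous RNA (ceRNA) hypothesis, lncRNAs and circRNAs
that share miRNA response elements (MREs) with an mRNA can sponge the shared
miRNA and co-regulate that mRNA, so reversal-pattern sponges and mRNAs
linked by shared seed-match sites are candidate mediators of the treatment
effect. `cernarev` implements this analysis end to end with a seeded
synthetic-data generator so every stage is testable without proprietary
array data.

## Preprocessing and differential expression

Intensities are quantile-normalized (every sample's distribution is mapped
onto the row-wise mean of the sorted columns; ties receive the mean of the
reference values at their tied ranks, the dominant convention). Group
comparisons use a two-sided Welch t-test on log2 intensities; fold changes
are ratios of normalized linear-scale group means. This split of scales is
deliberate: printed fold changes in this literature (values like 9.64 or
0.09) are linear ratios, while the t-test is better behaved on the log
scale. The DE gate is a linear fold change of at least 1.5 (or at most
1/1.5) together with p < 0.05. The fold-change boundary is inclusive and
the p boundary exclusive, so (1.5, 0.049) is called and (1.5, 0.05) is not.
No multiple-testing correction enters the gate — the convention this class
of microarray studies uses — but Benjamini–Hochberg q-values are reported as
an annotation column. Whether a moderated (empirical-Bayes) t-statistic was
preferable was genuinely open; plain Welch was chosen because it assumes
the least and the gate is fold-change-dominated at these effect sizes.

Features called in both contrasts form the dual-contrast (Venn) overlap,
and each such feature is classified `reversed-up`, `reversed-down`,
`concordant-up` or `concordant-down`. Heatmap ordering uses average-linkage
hierarchical clustering on 1 − Pearson correlation of log2 rows, with
features canonicalized by id so the tree does not depend on input order;
constant rows get maximal distance with a warning.

## Seed-match target prediction

Canonical miRNA sites only: with the seed defined as miRNA positions 2–8,
a transcript window is an `8mer` (reverse complement of positions 2–8
followed by A), `7mer-m8` (reverse complement of 2–8), or `7mer-A1`
(reverse complement of 2–7 followed by A). Each seed-core occurrence is
reported once with its strongest type (8mer > 7mer-m8 > 7mer-A1), with
0-based starts. No thermodynamic or conservation scoring is attempted —
the downstream rule only needs site presence, and affinity scores would
suggest a precision the data cannot support. circRNAs are covalently
closed, so scanning appends the first 7 bases and reports starts modulo
length; the circular site set therefore always contains the linear one.
Externally predicted site tables can be loaded in place of de novo
scanning.

## ceRNA network assembly

A sponge (lncRNA or circRNA), a miRNA and an mRNA form a triple when the
sponge and the mRNA each carry at least one canonical site for the miRNA
(shared MRE) and their fold-change signs agree in *both* contrasts
(direction concordance; magnitudes are ignored, since the hypothesis
speaks only to direction). miRNAs are not required to be differentially
expressed: the profiled species are mRNA/lncRNA/circRNA. The Methods
convention in this literature ("same-direction mRNAs were filtered out to
construct the networks") is read as *retained*, which the purpose clause
forces. Whether sponges and mRNAs must additionally be *reversed* (not
merely DE in both contrasts) is exposed as `require_reversal` (default
off): on real data the dual-contrast overlap is dominated by reversal
features anyway, and the looser rule is the one the Methods state.
Networks are tripartite by construction, every edge supported by a triple;
`validate_network()` re-checks any network, including hand-loaded ones.

## Enrichment and term networks

Gene-set enrichment is the upper-tail hypergeometric probability, with the
enrichment factor (k/n)/(K/N) used for ranking displays. The background is
all features measured on the array (all simulated features in synthetic
runs), not the genome — the conventional microarray choice. Terms are
linked when Cohen's kappa between their membership vectors is at least 0.4
(the ClueGO default), and functional groups are the connected components,
numbered by smallest term id. Iterative group-merging heuristics beyond
connected components are out of scope.

## Interaction modules

The interaction stage consumes a user-supplied two-column edge table (for
example a STRING export), induces the subgraph on the dual-contrast mRNAs
(isolated genes drop out, so the node count is smaller than the gene list),
reports hubs (degree ≥ 5), and detects dense modules with a from-scratch
MCODE implementation: vertex weight = (highest k-core of the closed
neighborhood) × (density of that k-core); seeds in descending weight;
expansion admits neighbors within 20% of the seed weight; haircut
iteratively trims singly-connected members; score = density × size;
modules with score > 4 are reported, node-disjoint, with id-based
tie-breaking for determinism. Defaults mirror the published plug-in's
(degree cutoff 2, node score cutoff 0.2, haircut on, fluff off).

## The synthetic-data generator

`sim_config()` defaults encode the emulated study conditions: 3 groups ×
12 samples; baseline log2 intensities N(8, 1.5) per feature (log-normal
linear intensities, microarray-like and strictly positive); additive log2
noise with sd 0.4; 30% of features DE in the disease contrast with planted
|log2FC| = 1.5 (linear ≈ 2.8×, inside the 1.5–10× range such studies
report); half of those reversed by treatment as equal-magnitude opposite
shifts (the treated group returns to baseline), the remainder held at the
disease level. Per-gene variance and array dynamic range are conventions,
not estimates — the emulated study reports neither. Sequence fixtures plant
perfect 8mer sites for planted sponge–miRNA–mRNA triples on rejection-
sampled backgrounds (capped at 1000 attempts) so that *no* unplanted
canonical site exists; a configurable fraction of circRNA sites is placed
across the back-splice junction (offsets L−6 … L−1, so the seed core
itself spans the junction and the site is invisible to linear scanning).
The recorded truth stores the *closure* of planted triples — every
sponge/mRNA pair sharing a planted miRNA's sites with concordant planted
direction — because recombinations of planted sites are legitimate
network content, not false positives. Gene-set and interaction fixtures
plant one enriched set (80% overlap with reversal mRNAs) and one clique
(default size 6) in an Erdős–Rényi background with mean degree 2.7,
matching the sparse texture such PPI subnetworks show.

What the generator does *not* emulate: probe-level effects, dye bias,
batch structure, correlated genes, non-canonical or thermodynamically
weak miRNA sites, and database noise in interaction tables. Passing
recovery tests therefore demonstrate the pipeline's correctness under its
own assumptions, not robustness to real-array artifacts.

## Numerical choices and degenerate inputs

Zero within-group variance with equal means yields p = 1 by convention
(p = 0 if the means differ). Quantile normalization of a single-sample
matrix is a warned no-op. Kappa with a constant marginal (empty or
all-background set) is defined as 0 with a warning. All site tables use
0-based, half-open coordinates; sequences are normalized to uppercase DNA
(U→T) at parse time; ambiguous bases never match. The RNG is
Mersenne-Twister throughout, with per-stage sub-seeds derived from the one
configured seed so each generator is a pure function of (config, seed)
regardless of call order.

## Problem sizes used in the shipped checks

The recovery study in `scripts/acceptance.R` and the test suite uses 20
replicate simulations at 12 samples/group with 150 mRNAs, 60 lncRNAs, 40
circRNAs, 8 miRNAs and 15 planted triples — large enough that recall and
false-discovery proportions are stable to a few percent, small enough to
re-run routinely. The effect-size realization check uses 1500 mRNAs so at
least 200 planted up-features contribute. These sizes are the package's
own reproducibility choices.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(list(
  simulate = list(),                       # sim_config() defaults
  groups = c("normal", "MCD", "QG"),
  outdir = "cernarev_output", rng_seed = 7))
print(res)
summary(res)                               # manifest counts
summary(res$networks$lncrna)               # per-sponge miRNA/mRNA counts
```

## Known limitations

Printed headline counts of the emulated study (thousands of DE features,
a 118-node PPI network, per-sponge target counts) depend on unreleased raw
arrays and on specific STRING/TargetScan snapshots, so they are not
reproduction targets; the package's claims are the rule-level and
recovery-level properties its tests compute. The DE stage offers no
covariates, pairing or variance moderation; MCODE's optional fluff step is
not implemented; enrichment is ontology-agnostic (any GMT).
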