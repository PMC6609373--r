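# cernarev

Drug-reversal ceRNA network analysis for three-group expression profiles.

## What it is for

Studies of a treatment acting on a disease model often profile mRNAs,
lncRNAs and circRNAs in three groups — control, disease (e.g. the
methionine-and-choline-deficient diet model of steatohepatitis), and
disease + treatment — and ask which disease-induced expression changes the
treatment *reverses*, and which lncRNA/circRNA sponges could mediate that
reversal by competing for shared miRNAs. `cernarev` implements that
analysis as a tested R pipeline for computational biologists who have such
matrices (plus transcript/miRNA sequences, a gene-set GMT and an
interaction table) or who want to study the method itself on simulated
data with known ground truth.

## The method in brief

* **Differential expression, two contrasts.** After quantile
  normalization, each feature is tested in contrast 1 (disease vs control)
  and contrast 2 (treated vs disease) with a Welch t-test on log2
  intensities; a feature is DE when its linear fold change satisfies
  FC ≥ 1.5 or FC ≤ 1/1.5 with p < 0.05. Features DE in both contrasts form
  the Venn overlap; up-then-down (or down-then-up) features carry the
  reversal pattern.
* **Seed matching.** Canonical miRNA sites (8mer, 7mer-m8, 7mer-A1; seed =
  miRNA positions 2–8) are scanned on mRNA 3′UTRs, lncRNAs, and circRNAs;
  circRNA scanning is back-splice-junction aware (starts reported modulo
  length).
* **ceRNA triples.** Sponge–miRNA–mRNA triples require a shared MRE (≥ 1
  site on sponge and mRNA for the same miRNA) and direction concordance —
  sign(log2FC) of sponge and mRNA equal in *both* contrasts. Networks are
  tripartite; merges flag nodes shared between sponge networks.
* **Enrichment.** Hypergeometric tail P(X ≥ k) over the array background,
  ranked with the enrichment factor (k/n)/(K/N); terms linked at Cohen's
  kappa ≥ 0.4 into functional groups.
* **Interaction modules.** Degree hubs (≥ 5 neighbors) and a from-scratch
  MCODE: vertex weight = highest-k-core of the closed neighborhood × its
  density, greedy seed expansion, haircut, score = density × n, modules
  with score > 4.
* **Synthetic truth.** A seeded generator plants DE/reversal features,
  exclusive seed-match sites (junction-spanning on circRNAs), one enriched
  gene set and one interaction clique, and records everything for
  recovery testing.

## Worked example

```r
library(cernarev)
res <- run_pipeline(list(
  simulate = list(),                     # sim_config() defaults: 3 x 12 samples
  groups   = c("normal", "MCD", "QG"),   # control, disease, treatment
  outdir   = "cernarev_output",
  rng_seed = 7))
print(res)
#> cerna_pipeline run
#>   DE overlap: mrna=46, lncrna=16, circrna=12
#>   ceRNA triples: lncrna=21, circrna=14
#>   PPI: 17 nodes, 6 hubs, 1 MCODE modules
head(res$reversals$mrna, 3)
#>     feature       pattern
#> 1 mRNA_0001 reversed-down
#> 2 mRNA_0009 reversed-down
#> 3 mRNA_0012   reversed-up
head(summary(res$networks$lncrna), 3)   # per-sponge miRNA / mRNA counts
#>     sponge n_mirnas n_mrnas
#> 1 lnc_0005        1       2
#> 2 lnc_0010        1       2
#> 3 lnc_0014        1       2
res$modules[[1]]$score                  # planted 6-clique recovered
#> [1] 6
```

Reading: of the simulated features, 46 mRNAs, 16 lncRNAs and 12 circRNAs
are DE in both contrasts; the sponge networks contain 21 + 14
shared-MRE, direction-concordant triples; the interaction stage recovers
the planted clique as one MCODE module of score 6. `cernarev_output/`
holds every stage's TSV/SIF/GraphML files, `planted_truth.json`, and a
`manifest.json` of counts and parameters; re-running with the same seed
reproduces all of them byte for byte.

On real data, replace `simulate` with an `inputs:` block of file paths
(expression TSVs + design, FASTA transcripts with `topology=circular`
tags, miRNA FASTA, GMT, edge TSV). A thin command-line wrapper is
installed at `inst/scripts/cernarev.R` (`run` and `simulate`
subcommands).

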