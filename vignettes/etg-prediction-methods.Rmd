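---
title: "Predicting enhancer target genes: model, features and design notes"
author: "etgpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancer target genes: model, features and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Enhancers regulate genes over large genomic distances, frequently skipping
their nearest neighbours, so assigning a target gene to an enhancer cannot
be done by proximity alone. `etgpair` scores every gene whose TSS lies
within 2 Mb of an enhancer as a potential target, using a random forest of
500 classification trees over four features, and calls targets where the
fraction of trees voting "target" reaches 0.95 (the default cutoff; it is a
tunable `etg_params()` entry). The promoter of a gene is the strand-aware
window from 1 kb upstream to 100 bp downstream of its TSS, and the
enhancer–gene distance is the minimum distance between the enhancer's
endpoints and the TSS.

## The four features

**Distance** is used raw in bp. Trees are insensitive to monotone
transforms, so no log transform is applied by default; the feature-ranking
methods that are scale-sensitive (the optional SVM and LASSO hooks)
standardise internally.

**Conserved synteny (CSS).** For each non-reference species *s* with
pairwise alignment block map available, the enhancer region and the gene's
promoter are lifted through the blocks (majority target chromosome by
reference overlap, per-block proportional interpolation, orientation
aware). If both regions map to the same target chromosome, `d_s` is the gap
in bp between the two lifted spans (0 if they touch); otherwise the pair is
non-syntenic in *s*. With phylogenetic distances `phi(r, s)` from the
reference *r*,

    CSS(e, g) = sum_s phi(r, s) * c_s / sum_s phi(r, s),
    c_s = max(0, 1 - d_s / Theta)       (linear kernel, default)
    c_s = 1[d_s <= Theta]               (indicator kernel, optional)

with `Theta = 2 Mb`. The per-species decay-and-weight form is this
package's documented reconstruction of the classical
phylogeny-weighted synteny score: the ingredients (`phi`, `d_s`, `Theta`)
are fixed, the kernel is pluggable because the aggregation's exact printed
form is not uniquely determined by its published description. CSS is in
[0, 1], monotone non-increasing in every `d_s`, and invariant under uniform
rescaling of `phi`; the test suite asserts all three properties.

**Function similarity (FSS).** The gene side uses its GO annotations
directly. The enhancer side is inferred through motif modules: sets of >= 2
DNA-binding motifs that co-occur in significantly many enhancers. The
bundled miner scans enhancer sequences with PWM log-odds (uniform 0.25
background, pseudocount 1e-3, both strands, occurrence = best score >= 80%
of the motif's maximal log-odds), enumerates frequent motif sets level-wise
(Apriori), tests each against the independence null with an exact one-sided
binomial, Bonferroni-corrects over all tested sets, and keeps maximal
significant sets. Externally discovered module/instance lists can be
imported instead (`read_motif_modules()`), since dedicated module-discovery
systems are out of this package's scope and the FSS pipeline only needs
module instances. For each module with an instance in enhancer *e*, all
enhancers carrying the module are collected, all genes within the candidate
window of those enhancers are pooled and de-duplicated, and each propagated
GO term is tested for over-representation against the gene universe
(one-sided hypergeometric, Benjamini–Hochberg at 0.05 — the published
procedure names no specific test, so the standard enrichment pair is used).
The enhancer's terms are the union of significant terms over its modules.
Term similarity uses information content, `IC(t) = -ln(n_t / n_root)` after
propagating annotation counts to ancestors, with the most informative
common ancestor (MICA):

    sim(t1, t2) = 2 * IC(MICA) / (IC(t1) + IC(t2))    (Lin, default)
    sim(t1, t2) = IC(MICA)                            (Resnik, optional)

Lin is the default because it keeps scores in [0, 1]. Two term sets are
compared by the best-match average (each term matched to its best
counterpart, means averaged over both directions); the aggregator is a
package choice, stated here because the source procedure leaves it open.
Similarity is computed within a GO namespace only; cross-namespace pairs
score 0 through the absence of a common ancestor.

**Activity correlation.** Mean per-bp DNase hypersensitivity signal of the
enhancer and of the promoter is extracted from one bedGraph per cell type,
and the two vectors across the panel are compared with Spearman's rank
correlation (average ranks on ties). A constant vector has no defined rank
correlation; it scores 0 so the feature is always populated — a silent
missing value would bias the forest. At least 3 cell types are required;
the panel is data, not a constant of the method.

## Classifier and training data

The forest uses 500 trees and library defaults for all other
hyperparameters (recorded in the model bundle); the score of a pair is the
fraction of trees voting positive. Training positives are experimentally
supported pairs; negatives are drawn uniformly without replacement from
(enhancer, gene-within-2-Mb) combinations whose gene is not a known target
of that enhancer. Published protocols built balanced sets of 2500/2500 from
mixed sources; the sampler takes the counts as arguments rather than
hard-coding any recipe. Training, sampling, and fixture generation all take
explicit seeds: fixed data plus fixed seed gives bit-identical scores.

## Evaluation harness

A predicted pair matches a known pair when the two enhancer regions share
at least 1 bp and the two promoter regions share at least 1 bp (half-open
intervals). A known pair recovered by several predictions counts once, and
a prediction matching several known pairs counts once, so recall can never
exceed 1. Recall, precision and F1 come from these counts with undefined
ratios reported as `NA`, never divided through. ROC AUC is computed in the
rank-statistic (Mann–Whitney) form, which handles score ties exactly;
pooled across enhancers by default. Hi-C support requires an enhancer–TSS
separation of at least 5 kb and a contact-matrix triplet at the 5-kb bin
pair covering enhancer and promoter (either bin order) with normalized
count at or above the chosen cutoff. The random-pair null redraws genes
within the window, and enrichment of the supported fraction is an exact
one-sided upper-tail binomial. An enhancer with >= 2 predicted targets is
"inconsecutive" when a non-target candidate lies strictly between two
targets in TSS order; enhancers with fewer targets are excluded from the
denominator.

## The synthetic study

`generate_fixture()` writes a complete toy dataset in every input format
the package reads (BED, GTF, FASTA, block-map and phylogeny TSVs,
MEME-minimal PWMs, OBO, GAF, bedGraph panel with manifest, contact
triplets, truth table), with one pseudo-random stream per artifact so that
changing, say, the cell-type count cannot perturb the gene layout, and
byte-identical regeneration under a fixed seed.

The default world has 4 chromosomes of 1 Mb, 250 genes and ~62 enhancers
per chromosome, and 2 planted targets per enhancer (each gene targeted at
most once): 500 true pairs, and with the default 3:1 negative sampling a
2000-pair labeled table — sizes chosen so the whole study (generation,
features, training, evaluation) runs in seconds. True targets are drawn
with an exponential distance decay (scale 25 kb). Synteny is planted by
placing a true pair's lifted elements adjacently in a species with
probability 0.45 per species, while background elements map to random
target positions with probability 0.5. Motif modules occupy chromosome
territories (each chromosome's enhancers carry one module, 92% carrier
rate, 3% random noise insertions per motif), the ontology has five
"pathway family" branches, and a target gene is annotated from its
enhancer's module branch with probability 0.8 versus 0.10 for background
genes. Promoter activity of a target correlates with its enhancer's latent
activity at 0.10 across 13 cell types; non-targets are independent.
Planted contacts are Poisson with mean 30 versus 2 for background.

These strengths are deliberately graded so the features separate true from
false pairs in the order distance > CSS > FSS > correlation, mirroring the
qualitative importance ordering reported for real data; the
single-feature AUCs they realize are roughly 0.95 / 0.89 / 0.68 / 0.58.
`truth_metrics()` recomputes this separation through the file readers and
is the generator's self-test. Setting a planted strength to zero (or the
decay scale effectively infinite) disables that channel;
`fixture_config_null()` disables all of them, which the suite uses to
check that held-out AUC collapses to chance.

What the toy world does *not* emulate: realistic genome composition or
size (1 Mb chromosomes versus 2 Mb candidate windows, so every same-
chromosome gene is a candidate), chromatin-domain structure, correlated
noise between features, assay biases in DNase or Hi-C, or the scale and
incompleteness of real GO annotation. Passing tests demonstrate that the
implementation recovers structure it is told to plant, not that the model
attains any particular accuracy on real data.

## Numerical and interface choices

- All internal coordinates are 0-based half-open (BED convention). GTF
  TSSs use the printed feature start for `+` genes and printed end minus
  one for `-` genes; the 1-bp convention ambiguity on `+` strands is
  immaterial to every downstream quantity.
- "Within 2 Mb" is inclusive; promoter windows clamp at position 0;
  trans-chromosomal pairs are never candidates (distance `Inf`).
- Block lifting breaks target-chromosome ties deterministically
  (largest reference overlap, then lexicographic chromosome name).
- Importance rankings break ties by feature order; constant features get
  importance 0 and rank last. Information gain uses 10-bin equal-frequency
  discretization, with low-cardinality features used as-is.
- Degenerate inputs fail loudly: inverted BED intervals, unknown strands,
  cyclic ontologies, annotations to unknown terms, one-class training
  sets, resolution-mismatched contact matrices, and feature-list
  mismatches when scoring all raise errors naming the problem.
- The run configuration is YAML. Tabular stage outputs carry `# key:
  value` provenance lines (including an input digest) above a standard
  header, and a failed stage removes its partial output.
- Model bundles are single files with the forest, feature list, seed and
  format version; loading refuses bundles without them.

## Problem sizes and runtime

The test suite and the acceptance script run entirely on generated data:
the default 2000-pair study for end-to-end checks, ten regenerated studies
for the importance-order check, and hand-sized worlds for every oracle
comparison. The full suite completes in about two minutes on one core.

## Known limitations

- The module miner is a deliberate simplification (Apriori + binomial);
  use the import path for modules from a dedicated discovery system.
- CSS depends on the quality of the supplied block maps; no chain/net
  construction is performed.
- Per-enhancer (rather than pooled) ROC evaluation is available only by
  grouping externally.
- bigWig signal input is not supported; convert to bedGraph first.
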