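---
title: "Methods: comparative mitogenomics and marker ranking with mitomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics and marker ranking with mitomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomarker)
```

## The problem

Mitochondrial phylogenetics in groups such as the parasitic copepods often
rests on one or two convenient genes (classically *cox1*), yet the 37 genes
of a typical metazoan mitogenome differ widely in length, variability,
selective constraint, and how faithfully a tree built from each gene alone
reproduces the phylogeny obtained from the whole mitogenome. mitomarker
implements the comparative toolkit needed to quantify those differences
from annotated mitogenomes and per-gene alignments: base composition and
strand skews, codon usage (RSCU) and amino-acid proportions under the
invertebrate mitochondrial code, nucleotide diversity overall and in
sliding windows, pairwise Ka/Ks by the Nei–Gojobori method, and the K tree
score of each single-gene tree against a reference topology — synthesised
into a per-gene marker-ranking report.

## Statistics implemented

### Composition and skews

AT and GC skews are `(A − T)/(A + T)` and `(G − C)/(G + C)`; both are
antisymmetric and bounded by ±1, and `skew()` defines 0/0 as 0. `N`
residues are counted but excluded from the denominators of all fractions
and skews, so partially ambiguous genomes do not bias composition.
Per-codon-position composition (`codon_position_stats()`) reads frame 0 and
drops a trailing incomplete codon.

Stop classification (`classify_stop()`) is positional: a final TAA/TAG on
an in-frame region; the tails `TA` (length ≡ 2 mod 3) and lone `T`
(length ≡ 1 mod 3) are the incomplete stops completed by polyadenylation;
everything else is `other`.

RSCU for codon *c* in a synonymous family of size *k* with counts *n* is
`n_c · k / Σ n`. Stop codons are excluded; start codons are counted as
ordinary codons — annotation of translation starts is not always reliable
enough to subtract one codon per gene, and the difference is at most 13
codons per genome. Amino-acid percentages use translated residues excluding
stops as the denominator, and leucine/serine are each reported pooled
across their two codon families, as comparative mitogenomics tables
conventionally do.

### Nucleotide diversity

`nucleotide_diversity()` is Nei's π: the mean over all `C(n,2)` sequence
pairs of the proportion of differing sites among the sites comparable in
that pair. The default `gap_mode = "complete"` removes every column with a
gap or `N` in any row before comparison, mirroring the complete-deletion
default of the widely used polymorphism software; `"pairwise"` keeps
per-pair information and is available by flag. Sliding windows
(`sliding_window_pi()`, defaults 200 columns at step 20) are defined on
alignment columns of the supplied (already filtered) alignment, not on
ungapped positions of any single sequence; only full windows are reported,
each indexed at its midpoint, and windows with fewer than `min_valid = 10`
comparable columns report missing rather than a spuriously confident 0.

`filter_columns()` is a plain gap/N-fraction column filter used as
pre-processing plumbing. It is deliberately not a reimplementation of
block-based alignment trimming tools; users who need conservative block
selection should trim externally and feed the result in.

### Ka/Ks (Nei–Gojobori 1986, Jukes–Cantor corrected)

Site counting follows NG86: each codon position contributes the fraction of
its three single-nucleotide changes that are synonymous; changes that would
create a stop codon count as nonsynonymous, which keeps `S + N = 3` per
codon. Differences between codons at Hamming distance *k* are averaged
over the *k*! substitution orderings, discarding orderings that pass
through a stop codon; in the rare case where every ordering does, the
average falls back to all orderings so the pair remains usable. Proportions
`pS = Sd/S` and `pN = Nd/N` are corrected with Jukes–Cantor
`d = −(3/4)·ln(1 − 4p/3)`; proportions at or beyond 3/4 are reported as
undefined (saturation) rather than clamped. The correction is the default
because it is the common default of the polymorphism software this
workflow replaces; raw proportions are available with
`jc_correction = FALSE`.

The gene-level ratio is `mean(Ka)/mean(Ks)` over pairs, not the mean of
per-pair ratios: per-pair ratios explode when a pair happens to have few
synonymous differences, while the ratio of means is stable and weights
pairs by information. Per-pair tables are returned for inspection.
Incomplete terminal stop codons should be trimmed
(`trim_incomplete_stop()`) before analysis; codons containing gaps, `N` or
a stop in either sequence are skipped pair-wise.

One subtle consequence of pathway averaging is worth knowing: two codons of
the same amino acid differing at two positions (TTA vs CTC, both leucine)
can average a nonsynonymous-passing ordering into their counts, so even
evolution with no accepted nonsynonymous change leaves a tiny positive Ka.
This is inherent to the estimator, not an artefact of this implementation.

### K tree score

To score a single-gene tree against a reference, both trees are pruned to
their shared leaf set (contracted paths sum their lengths) and unrooted;
each edge is mapped to the leaf-set bipartition it induces. Over the union
of bipartitions — with a split absent from one tree contributing length 0
there — the comparison tree is optimally rescaled toward the reference by
`K = Σ l_ref·l_comp / Σ l_comp²`, and the score is the Euclidean norm
`sqrt(Σ (l_ref − K·l_comp)²)`. The scaling direction (gene tree rescaled
toward the reference) follows the published definition of the score;
trivial (pendant) splits are included in the sums because their lengths
carry real signal about terminal-branch estimation. Support labels are
parsed and discarded; polytomies simply contribute fewer splits. The score
is invariant to rescaling the comparison tree and is not symmetric in its
arguments. `nj_tree()` (Saitou–Nei neighbor joining on p or Jukes–Cantor
distances, negative estimates clamped to 0) is provided so the scoring
stage can be exercised end-to-end without external likelihood software; it
is not a substitute for model-based inference.

### Marker ranking

`run_marker_eval()` ranks genes per criterion — π descending, Ka/Ks
descending, alignment length descending, k-score ascending — with ties
sharing the mean rank, and orders the report by the rank sum. The
directions encode the use case of resolving closely related taxa: more
variable, faster-evolving and longer genes carry more signal there, while a
lower k-score means a gene tree closer to the reference. Genes that lack a
criterion (rRNAs and tRNAs have no Ka/Ks) get
`rank_sum = 4 × mean(available ranks)`, which keeps rows comparable
without inventing a value. The composite is an unweighted synthesis of the
four published criteria rather than a published statistic, and the report
always carries the per-criterion columns so users can reweight.

## The synthetic-data generators

Every stage is testable without downloads because the package simulates its
own inputs.

* `simulate_tree()` draws Yule (pure-birth) or balanced topologies and
  rescales to a root-to-tip depth of 0.25 expected substitutions per site
  by default — deep enough that distances are informative, far from
  Jukes–Cantor saturation even at rate multiplier 2–3.
* `simulate_nt_alignment()` uses a single simplified substitution process:
  equal exchangeabilities with unequal stationary frequencies (an F81-type
  model), parameterised by a gene-specific rate multiplier and an AT bias
  (default 0.7, an AT-rich mitochondrial composition). Along a branch each
  site either persists or is redrawn from the stationary distribution,
  calibrated so the expected substitutions per site equal rate × branch
  length.
* `simulate_codon_alignment()` creates coding alignments with a target
  Ka/Ks by rejection: nucleotide-level proposals, stops always rejected,
  synonymous changes always accepted, nonsynonymous changes accepted with
  probability ω. This hit-and-accept scheme is adequate because the
  package estimates ω by counting (NG86), not by likelihood; it makes no
  claim to be an inferential codon model.
* `perturb_tree()` grades gene-tree discordance by random SPR moves plus
  log-normal branch jitter, and `make_toy_genbank()` emits small annotated
  circular records — with complement features, origin-spanning joins,
  incomplete stops and anticodon qualifiers — whose planted content is
  returned alongside the text, so the GenBank parser is checked against
  known truth.
* `simulate_study()` composes these into a complete marker-evaluation
  study: 18 taxa and 13 protein-coding genes with graded lengths, rates,
  ω and discordance chosen to mirror the qualitative gradients of real
  copepod mitogenomes (cox genes slow, concordant; nad4L/atp8 fast, short,
  discordant; nad2 fast, long, concordant). Gene lengths are scaled-down
  (18–191 codons) to keep a full 25-replicate study around a minute.

What the simulations do **not** emulate: indels and alignment error, rate
heterogeneity across sites, GTR-style unequal exchangeabilities, empirical
codon frequencies, base-composition heterogeneity across lineages, and
model-based gene-tree estimation error (gene trees in the synthetic study
come from neighbor joining). Passing the recovery tests therefore shows
that the estimators recover the parameters of this generating process, not
that they are robust to every pathology of real alignments.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; printed tables use GenBank's
  1-based inclusive convention.
* Ambiguity codes other than `N` are mapped to `N` on input, with a
  warning. Duplicated genes are kept with `_copy2` suffixes; downstream
  per-gene analyses use the first copy.
* Serine/leucine tRNA disambiguation uses the anticodon qualifier when
  present (GCT→S1, TGA→S2, TAG→L1, TAA→L2), then codon-family tags in the
  label; otherwise the label maps to `other` with a warning rather than a
  guess.
* Skews are printed to 3 decimals and contents to 0.1%, matching the
  conventions of comparative mitogenomics reports.
* The pipeline is deterministic given inputs and seeds; all simulators are
  pure functions of their seed.

## Problem sizes used by the test-suite studies

Parameter-recovery studies run at 12 taxa × 300 codons × 20 replicates per
ω (bounds ±0.05 at ω = 0.1, ±0.1 at 0.5, ±0.15 at 1.0), 20 replicates for
the π rate-ordering contrast, 50 seeds per SPR level for k-score grading,
and 25 replicates of the full 18-taxon, 13-gene study for top-marker
recovery. These sizes give stable means (across-replicate standard errors
an order of magnitude below the tolerance) while keeping the whole suite
in a few minutes.

## Known limitations

* The GenBank reader targets well-formed single-record flat files of the
  kind GenBank serves; it is not a validator, and records with exotic
  location operators (`order()`, external references) are out of scope.
* NG86 is a counting estimator: it underestimates ω under strong multiple
  substitution and does not model transition/transversion bias or codon
  frequencies. For site-level or branch-level selection inference use a
  likelihood codon model; the package deliberately reports the simple,
  widely comparable statistic.
* K tree scores depend on the quality of the input gene trees. The
  built-in NJ trees are for testing and exploration; published-grade
  scores should come from externally inferred trees.
* The marker rank sum is a transparent synthesis, not an optimality
  criterion; with few taxa the k-score column can dominate rank changes
  between runs of stochastic tree inference.
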