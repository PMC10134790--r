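---
title: "Mining LuxR solos from annotated genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining LuxR solos from annotated genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soloscan)
```

## The biological question

Quorum-sensing LuxR-family receptors normally come in pairs with a LuxI-family
acyl-homoserine-lactone (AHL) synthase: the synthase makes the signal, the
receptor binds it and regulates transcription. A *LuxR solo* (or orphan) is a
LuxR-family protein with no cognate synthase gene nearby. Solos are widespread
in proteobacteria and underlie eavesdropping on other species' AHLs, responses
to plant compounds (the PAB subfamily), and signaling through non-AHL molecules
such as photopyrones and dialkylresorcinols. `soloscan` implements, at desk
scale and on fully synthetic inputs, the complete in silico survey machinery
for these regulators: detection, clustering, genomic-context subgrouping,
residue-based ligand-class hints, and a summary phylogeny.

## The survey procedure

**Solo detection.** A LuxR-family protein is recognized purely by its
autoinducer-binding Pfam domain (PF03472); a LuxI-family synthase by PF00765.
A LuxR is a solo when none of the 4 genes upstream or 4 genes downstream on
its replicon encodes a PF00765 protein. The window is *ordinal* — measured in
gene ranks, not base pairs — because the criterion counts "surrounding genes";
it truncates at replicon ends and never wraps (plasmids and contigs are
independent replicons). Neighbor strand is ignored: only domain
presence/absence matters. Genes without a protein product still occupy window
slots. A protein carrying both domains is reported as a fused
synthase-regulator and excluded from solo calling — the survey criterion is
silent on fusions, and exclusion is the conservative choice.

**Pair topology.** For non-solo LuxRs the nearest in-window synthase defines a
pair, classified by strand and order alone: *tandem* (same strand),
*convergent* (pointing toward each other), *divergent* (pointing apart), and
*complex* when at least one gene intervenes. The literature describes
head-to-head and tail-to-tail pairs with a single term while calling their
transcription divergent; we report the orientation geometrically
(left gene `+` / right gene `-` is convergent) and keep the mapping explicit
here. Pairs under 3,000 bp of intergenic distance are flagged as genetically
linked, the canonical cassette distance.

**Sequence clustering.** Solo proteins are clustered by a single greedy
incremental pass in the style of CD-HIT: sequences are visited longest-first
and join the first representative they match at ≥ 80% identity with ≥ 80%
coverage of both sequences, else found a new cluster. The underlying
alignment is global Needleman–Wunsch with a linear gap model (match +1,
mismatch 0, gap −1). The 80/80 criterion does not fix the identity
denominator; we use the shorter sequence's length, the convention of the
referenced clustering tool, and expose it as a parameter. All comparisons use
the full dynamic program — at desk scale the O(nm) cost is irrelevant — with
one shortcut: a pair whose length ratio is below the coverage threshold
cannot pass bidirectional coverage and is skipped unaligned. Because ties
among co-optimal alignments are broken on a canonical ordering of the pair,
identity is an exactly symmetric function of the two sequences, and the
clustering is invariant to input order.

**Context subgrouping.** Clusters with *more than 50* members (a strict
bound: 50 is skipped, 51 profiled) are fingerprinted by neighborhood content:
for each Pfam accession, the fraction of members whose window contains at
least one gene carrying it. Presence is counted once per member — the 5%
retention floor reads as prevalence, not multiplicity — and Pfams below 5%
are dropped (exactly 5% is kept). The focal gene and PF03472 itself are
excluded as uninformative constants. The profiling window reuses the
detection window (±4 genes); the original survey does not state its profiling
extent, and a shared window keeps one definition of "neighborhood"
throughout. Profiles are embedded in 3 dimensions and density-clustered with
DBSCAN (eps = 0.5, min_samples = 10), noise labeled −1.

The default embedding is a deterministic principal-component projection
(centered, unscaled, each component's sign fixed by its largest loading).
The corpus-scale survey used UMAP with `n_components = 3`; that method is
available behind the same interface (`embed_profiles(method = "umap")`,
mandatory seed, delegated to the host Python's umap-learn), but PCA is the
default because the survey's embedding is not recoverable anyway — eps = 0.5
is calibrated to an embedding-dependent scale — and a deterministic default
makes every downstream number reproducible. The synthetic subgrouping suite
therefore fixes its own geometry (below) rather than chasing the original
coordinates.

**DBSCAN determinism.** The textbook algorithm leaves two choices open,
which we pin down: clusters are the eps-connected components of core points,
labels are numbered by each cluster's smallest member id, and a border point
joins the cluster of its *nearest* core point within eps (ties by id). This
refines "first-encountered" orderings into something permutation-invariant;
tests assert equivalence against an independent eps-graph/connected-components
oracle.

**Residue classifier.** Nine residues are highly conserved across
AHL-binding LuxRs — six lining the ligand cavity (W57, Y61, D70, P71, W85,
G113 in TraR numbering) and three in the helix-turn-helix domain (E178,
L182, G188). Queries are globally aligned to a packaged TraR-like anchor
that carries these consensus residues at their literal positions; the
residues *between* key positions are a fixed synthetic stand-in (the anchor
is labeled synthetic in the packaged YAML), and a real TraR sequence can be
substituted via `reference_map(sequence = )`. The classifier reports the
anchored residue at each key position, the conserved count (0–9), the PAB
hallmark (M at 57 *and* W at 61), and a whole-sequence scan for the
diagnostic hexamers WYDPWG (canonical, checked first), TYDQCS (PluR-like)
and TYDQYI (PauR-like); the canonical "6-motif" is historically the set of
six cavity residues rather than a literal hexamer, so scanning is one of two
defensible readings and the anchored positions remain available in the
report. Class hints compose this evidence with neighborhood rules —
a proline-iminopeptidase (pip) neighbor marks the plant-associated context,
the ABC-transporter + response-regulator pattern the SdiA-like enteric
context — with precedence pyrone/DAR > PAB > AHL, and ≥ 8 of 9 conserved
residues (with no competing motif) reading as a canonical AHL sensor. Pfam
accessions stand in for gene names because the pipeline sees domains, not
annotations: pip defaults to PF00561 (the alpha/beta-hydrolase fold family of
proline iminopeptidases; the survey does not print its accession) and is
configurable. The hint is sequence/context evidence only — ligand-independent
solos retain all nine residues — and is never reported as a functional claim.

**Phylogeny.** Cluster representatives are summarized as a classical
neighbor-joining tree on 1 − identity distances. The original survey built
an approximate-ML tree from a progressive multiple alignment; here the tree
is a deterministic summary artifact, not an inference target, so the exact
distance algorithm with a lexical tie-break is preferable (and exact on
additive matrices, which the tests exploit). Negative branch lengths are
clamped to zero with the difference moved to the sister branch, preserving
the path length through the joined pair. Annotated Newick decorates leaf
labels with subgroup, class hint and environment, mirrored in a sidecar
table for readers that dislike decorated labels.

## What the generator emulates — and what it does not

`generate_corpus()` is first-class, tested code, and its defaults are the
study conditions:

* **Solo-count mixture** `(14351, 12235, 4448) / 31034` — the surveyed
  proportions of genomes with zero, one, or multiple solos. The printed
  percentages (~46.2 / ~39.4 / ~14.3) sum to 99.9 only because of rounding,
  so the exact genome counts are used.
* **Five archetypes** covering the survey's recognizable signatures:
  generic AHL sensor; PAB (W57M/Y61W + pip PF00561 neighbor, plant
  environment); an mfs1-like transporter-adjacent subgroup (PF07690,
  aquatic); SdiA-like enteric context (PF00005 + PF00072, human); and a
  PluR-like pyrone sensor (TYDQCS). Archetype ancestors derive from the
  packaged anchor with 50% of mutable positions substituted — far below the
  80% clustering threshold between families.
* **Members** are drawn from their ancestor by i.i.d. substitutions at 4%
  per mutable site (no indels by default), so two family members sit near
  92% identity — comfortably inside the threshold — and identity thresholds
  translate directly into mutation-rate settings. Key residues and the
  planted motif window are immutable so the planted class stays decidable.
* **Pairs** are planted in drawn topologies with drawn linkage distances
  (15% unlinked); complex pairs get one intervening gene and a capped gap so
  the linkage label survives the insertion. Planted elements keep ≥ 12 gene
  ranks of separation so neighborhoods never interact.
* **Decoys**: random-sequence genes with Pfams disjoint from every
  signature accession; ~5% of decoys are non-coding and merely occupy
  window slots. Genomes have 25–45 genes per chromosome and a plasmid in a
  quarter of genomes (the last solo moves there, exercising replicon
  independence).

The generator does **not** emulate genome evolution, taxonomic sampling,
indel processes, annotation noise, or the scale of the real corpus — so a
perfect score on planted truth shows the *machinery* is correct under clean
conditions, not that the survey's corpus-scale numbers (26,577 hits, 4,276
clusters, 341 profiled, 274 + 67 subgrouped) would be reproduced; those
require the 31,034-genome collection itself and are out of scope.

The subgrouping suite uses `generate_profile_blobs()` directly: 3 archetypes
x 15 profiles with disjoint 5-Pfam signatures (frequency ≈ 0.92 vs 0.02
background, ±0.04 member noise) plus 5 uniform noise profiles. Under the PCA
embedding the within-archetype spread is ≈ 0.2 and between-archetype
separation > 2, so eps = 0.5 / min_samples = 10 recovers the planted count
with noise at −1; the suite asserts this over 20 seeds at a ≥ 95% rate.

## Numerical and interface choices

* Coordinates are GFF3-style 1-based inclusive throughout; intergenic
  distance is `start₂ − end₁ − 1`, zero for overlapping genes; "less than
  3,000 bp" is strict.
* Percentages round half-up to one decimal (`46.25 → 46.3`), matching the
  survey's reporting style; R's banker's rounding is deliberately avoided.
* Domain input is precomputed (HMMER3 domtblout in either orientation, or a
  5-column TSV); the package never runs a profile-HMM search, because domain
  calls in the emulated survey come from the source database's annotations.
* The per-domain tabular parser accepts both hmmsearch (protein-as-target)
  and hmmscan (model-as-target) column orders and strips Pfam versions.
* Ties: clustering visits equal-length sequences in lexical id order;
  neighbor-joining breaks Q-ties by the lexically smallest id pair (within
  1e-12); DBSCAN labels are ordered by smallest member id. Every stage is a
  pure function of (inputs, seed), which the byte-identical rerun tests pin
  down.
* Problem sizes in the shipped suites — 100-genome corpora for recovery,
  ≤ 200-point DBSCAN instances, ≤ 12-taxon additive trees, 500 genomes for
  the mixture-convergence check — were chosen as the smallest sizes at which
  the properties are meaningfully exercised.
* `luxr_length_ok` (230–270 aa) is advisory metadata, never a filter: the
  length range is descriptive of the family, not part of the detection rule.
* One call is made per PF03472 protein, even if the domain appears twice in
  it; whether the original survey deduplicated multi-domain proteins is
  unstated.

## Known limitations

* The anchor's inter-key residues are synthetic; anchored numbering of a
  *real* query is only as good as its global alignment to that scaffold. For
  production use on biological sequences, substitute a real TraR anchor.
* Classes that are not decidable from sequence plus context (endogenous vs
  exogenous AHL response; ligand independence) are deliberately out of
  scope; the classifier emits `unclassified` rather than guessing.
* `method = "umap"` requires a Python interpreter with umap-learn on the
  PATH and is the one stage whose output depends on an external library's
  version; all shipped defaults avoid it.
* Complex pair arrangements are reported as `complex` without naming the
  intervening regulator (rsaL/rsaM-style genes are not modeled).

## A minimal session

```{r, eval = FALSE}
res <- run_pipeline(out_dir = "survey_out", seed = 7,
                    synthetic = corpus_config(n_genomes = 50))
res$summary_distribution
head(res$pairs)
head(res$ligand_classes)
```

Outputs land in `survey_out/` as `solos.tsv`, `clusters.tsv`,
`context_profiles.tsv`, `subgroups.tsv`, `ligand_classes.tsv`, `tree.nwk`
(+ `tree_annotations.tsv`) and `summary.json`, with the generated corpus
under `survey_out/corpus/` (including `truth.tsv`).
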