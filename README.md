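# soloscan

Mining and classifying **LuxR solo** (orphan) quorum-sensing regulators in
annotated bacterial genomes.

Most proteobacterial quorum-sensing circuits pair a LuxR-family receptor
with a LuxI-family acyl-homoserine-lactone (AHL) synthase on the same
stretch of DNA. A *LuxR solo* is a receptor without a nearby synthase —
the genomic signature of bacteria that eavesdrop on other species' AHLs,
respond to plant compounds (the PAB subfamily, hallmark W57M/Y61W
substitutions plus an adjacent proline-iminopeptidase gene), or sense
non-AHL molecules such as photopyrones (PluR-like TYDQCS motif) and
dialkylresorcinols (PauR-like TYDQYI). `soloscan` implements the complete
in silico survey for these regulators as a tested, reusable R pipeline,
exercisable end-to-end on synthetic annotated genomes with planted ground
truth — no external downloads.

## What it computes

Given per-genome gene models (GFF3), protein sequences (FASTA) and
precomputed Pfam domain hits (HMMER3 domtblout or simple TSV):

1. **Solo detection** — a protein with the autoinducer-binding domain
   PF03472 is a solo iff no gene within ±4 gene ranks on its replicon
   encodes the AHL-synthase domain PF00765.
2. **Pair topology** — non-solo LuxRs are paired with their blocking
   synthase and classified *tandem* / *convergent* / *divergent* /
   *complex*, with genetic linkage at < 3,000 bp intergenic.
3. **Sequence clustering** — greedy incremental clustering (CD-HIT style)
   at ≥ 80% identity and ≥ 80% bidirectional coverage over global
   Needleman–Wunsch alignments (match +1 / mismatch 0 / gap −1; identity
   over the shorter sequence).
4. **Context subgrouping** — clusters with > 50 members are fingerprinted
   by the frequency of each Pfam among their members' neighborhoods
   (5% floor), embedded in 3 dimensions (deterministic PCA by default,
   seeded UMAP optional) and density-clustered with DBSCAN
   (eps = 0.5, min_samples = 10; noise = −1).
5. **Ligand-class hints** — queries are anchored to TraR numbering and
   scored on the nine conserved residues (W57, Y61, D70, P71, W85, G113;
   E178, L182, G188), the PAB hallmark, diagnostic motifs, and
   neighborhood rules (pip-adjacent PAB, SdiA-like enteric context).
6. **Phylogeny & report** — neighbor-joining tree of cluster
   representatives on 1 − identity distances, annotated Newick output,
   and the per-genome solo-count distribution (% genomes with zero / one /
   multiple solos, rounded half-up to one decimal).

A seeded generator (`generate_corpus()`) produces synthetic multi-replicon
genomes with planted pairs, solos of designed neighborhood archetypes,
decoys and a machine-readable truth table; `generate_profile_blobs()`
produces labeled context profiles for the subgrouping stage.

## Worked example

```r
library(soloscan)
res <- run_pipeline(out_dir = "survey_out", seed = 7,
                    synthetic = corpus_config(n_genomes = 50))
```

```
[simulate] generating synthetic corpus (seed 7)
[detect] 50 genomes, 74 LuxR proteins, 44 solos
[detect] 30 luxI/luxR pairs classified
[cluster] 44 solo proteins -> 5 clusters
[profile] 0 clusters profiled
[subgroup] skipped: fewer than 2 profiled clusters
[classify] 44 solos scored: AHL_type=28, PAB_type=9, pyrone_DAR_type=7
[tree] neighbor-joining tree over 5 representatives
[report] wrote 8 files to survey_out
```

Of 50 genomes, 74 proteins carry the LuxR domain; 44 are solos (the other
30 sit next to a planted synthase and are classified as pairs instead).
The 44 solos collapse into 5 sequence clusters — one per planted archetype
family. No cluster exceeds 50 members at this corpus size, so context
subgrouping correctly reports nothing rather than inventing subgroups.

```r
res$summary_distribution
#> 50 genomes, 44 solo hits: 36.0% none, 46.0% one, 18.0% multiple

head(res$pairs, 3)
#>   genome_id   luxr_protein   luxi_protein arrangement intergenic_bp linked
#> 1     g0002 g0002_chr_p004 g0002_chr_p005      tandem           585   TRUE
#> 2     g0003 g0003_chr_p003 g0003_chr_p004      tandem          4076  FALSE
#> 3     g0005 g0005_chr_p005 g0005_chr_p006  convergent           102   TRUE

head(res$ligand_classes, 2)
#>       protein_id n_conserved key_residues pab_signature motif_match
#> 1 g0001_pla_p005           9    WYDPWGELG         FALSE        none
#> 2 g0005_chr_p020           7    MWDPWGELG          TRUE        none
#>   neighborhood_class predicted_class_hint
#> 1          sdiA_like             AHL_type
#> 2   pip_adjacent_PAB             PAB_type
```

The first solo keeps all nine conserved residues (`WYDPWGELG`) and sits in
an SdiA-like enteric context — a canonical AHL eavesdropper. The second
shows the plant-associated hallmark (`M…W` at anchored positions 57/61,
`pab_signature = TRUE`) next to a proline-iminopeptidase gene, so it is
hinted `PAB_type`. Hints are sequence/context evidence, never functional
claims.

Outputs (`solos.tsv`, `clusters.tsv`, `context_profiles.tsv`,
`subgroups.tsv`, `ligand_classes.tsv`, `tree.nwk`, `tree_annotations.tsv`,
`summary.json`) are byte-identical across reruns with the same seed. A
thin command-line front-end lives at `inst/scripts/solo-mine.R`
(`solo-mine.R simulate|run --out DIR --seed N`).

See the vignette (`vignettes/luxr-solo-mining.Rmd`) for the model, every
tunable parameter, and the design rationale.

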