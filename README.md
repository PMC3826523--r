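# paralogon

Reconstructing the evolution of paralogous chromosome regions after
whole-genome duplication.

## The scientific problem

Early vertebrate evolution included two rounds of whole-genome duplication
(2R) on the vertebrate stem and a third, teleost-specific round (3R). Each
round multiplied whole chromosomes, so related genes from a single ancestral
region now sit in *quartets* of related chromosome regions — a **paralogon**.
Recognising a paralogon, dating its duplications relative to the WGD
time-windows, and subtracting later rearrangements is how gene families such
as the visual opsins (LWS, SWS1, SWS2, RH1, RH2), the transducin subunits
(GNAT/GNAI), the oxytocin/vasopressin receptors (OT/VP-R) and the L-type
calcium channels (CACNA1-L) are traced back to a small ancestral gene set.

This package implements that analysis as a tested, reusable pipeline for
anyone studying gene-family evolution against WGD events:

1. **Synteny blocks** — windows of ±5 Mb around anchor genes
   (`define_blocks()`), family membership profiles across blocks
   (`profile_families()`), and selection of neighboring families present on
   ≥ *k* blocks (`select_families()`, `pool_selections()`).
2. **Duplication dating** — gene-tree/species-tree LCA reconciliation
   (`lca_map()`, `annotate_duplications()`) and classification of each
   duplication into a time-window (`classify_window()`,
   `date_duplications()`): `2R`, `3R`, `between-2R-3R`, `pre-window`,
   `post-3R-local`, `lineage-local` or `unresolved`. A duplication node *g*
   maps to the species node `M(g) = MRCA{species below g}`; it is a
   duplication iff two children map to comparable species nodes, and its
   window is the WGD content of the branch ending at `M(g)`.
3. **Paralogon assembly** — a block graph weighted by families contributing
   2R-dated paralog pairs (`build_paralogy_graph()`), connected components
   above a support threshold (`assemble_paralogons()`), fission detection
   against an outgroup (`detect_fission()`), and translocation detection and
   timing against a pre-3R outgroup (`detect_translocations()`).
4. **Ancestral repertoires** — cutting dated trees into subtype lineages
   (`build_lineages()`) and Dollo parsimony reconstruction of per-ancestor
   gene content and loss placements (`dollo_reconstruct()`,
   `scenario_summary()`).
5. **Simulation** — a genome-evolution simulator (`replay()`,
   `simulate_genomes()`, `script_figure5()`) producing locus tables,
   congruent gene trees and ground-truth event logs, so every stage is
   validated against known histories.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_locus_map()` graphics.

## Worked example

Count a published opsin repertoire and find tandem duplicates:

```r
library(paralogon)
tab <- read_locus_table(system.file("extdata", "table1_visual_opsins.tsv",
                                    package = "paralogon"))
count_repertoire(tab, species = "gar", family = "opsin")
#> # A tibble: 5 x 4
#>   species family subtype     n
#> 1 gar     OPSIN  LWS         1
#> 2 gar     OPSIN  RH1         2
#> 3 gar     OPSIN  RH2         1
#> 4 gar     OPSIN  SWS1        2
#> 5 gar     OPSIN  SWS2        1
```

The spotted gar carries 7 visual opsin genes; its two RH1 genes lie ~16.7 Mb
apart (a retrogene, not a tandem pair), while `find_local_duplicates(tab)`
shows the zebrafish RH2 cluster of 4 genes within 20 kb on chromosome 6.

Run the whole pipeline on the scripted WGD scenario:

```r
run <- run_all(run_config())
run$repertoire
#> # A tibble: 6 x 3
#>   family  `pre:2R-1` Vertebrata
#> 1 CACNA1L          1          4
#> 2 DECOY            1          1
#> 3 GNAI             1          3
#> 4 GNAT             1          3
#> 5 OPSIN            2          5
#> 6 OTVPR            2          6
```

The reconstruction recovers the pre-2R chromosome content (2 opsins, 1 GNAT,
1 GNAI, 2 OT/VP-R, 1 CACNA1-L) and the post-2R gnathostome repertoire
(5/3/3/6/4). `tidy(run$groups)` shows the five reference-genome blocks in
one paralogon; `run$units` merges the two fission products through their
outgroup orthologs, leaving the four ancestral units; and
`run$translocations` reports the two teleost rearrangements, both timed
post-3R against the pre-3R gar-like outgroup. The unlinked DECOY family is
never selected by the synteny screen.

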