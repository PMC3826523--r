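---
title: "Methods: paralogon detection, WGD dating and ancestral repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralogon detection, WGD dating and ancestral repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

This vignette explains the models behind the package, the parameters that
matter, the conservatism rules built into the dating step, what the
simulator does and does not emulate, and the known limits of the approach.

## The model

Two rounds of whole-genome duplication (2R) on the vertebrate stem and a
third round (3R) on the teleost stem multiplied entire chromosomes. A single
ancestral chromosome region therefore survives as up to four related regions
in a post-2R genome (a *paralogon*), up to eight in a teleost. The package
reconstructs that history from two kinds of evidence:

* **Positions**: gene coordinate tables (0-based, half-open bp; positions
  published at Mb resolution are stored as point anchors with
  `end = start + 1`). Co-residence of families across chromosome blocks is
  the synteny signal.
* **Topology**: rooted per-family gene trees reconciled against a rooted
  species tree carrying WGD placements on its branches.

### LCA reconciliation and time-windows

Every gene-tree node maps to the most recent species-tree node containing
all species below it. A node is a duplication when two of its children map
to species nodes on one root-to-tip path; for binary nodes this is the
classic "maps to the same node as a child" criterion and it extends
unchanged to polytomies. A duplication's window is the WGD content of the
species-tree branch it maps to: the vertebrate stem (carrying 2R-1 and 2R-2)
gives `2R`, the teleost stem gives `3R`, the branch between them
`between-2R-3R`, branches above the first WGD `pre-window`, terminal
branches of post-3R taxa `post-3R-local`, all others `lineage-local`. The
two 2R events are reported as a single window: topology cannot order them,
and nothing downstream needs the order.

A duplication that maps to the species root is only called `pre-window` when
the species tree contains taxa diverging before the first WGD; without that
outgroup context it is `unresolved`. Likewise a family whose trees hold a
`2R` call but no pre-2R species is flagged `undated` in its verdict — the
relative dating lacks its anchor.

### Conservatism rules in `date_duplications()`

Pure branch rules are provably wrong in two situations, and the dating step
corrects both:

**Window capacity.** k WGD rounds turn one gene into at most 2^k copies. If
a duplication on the WGD branch heads a subtree that leaves more than 2^k
lineages at the end of that branch, the topmost duplication cannot belong to
the window. On the first WGD branch it is relabelled `pre-window`: this is
the classic inference that a fifth family member where a quadruplication
allows four implies a tandem duplication preceding the window (the opsin
SWS/LWS split and the OT/VP-R V1/V2 split are exactly such cases, and the
rule is what makes the reconstructed pre-2R chromosome carry 2 opsins and
2 OT/VP-R genes). On later WGD branches the before/after order is
undecidable and the node becomes `unresolved`. The lineage-count criterion
(rather than chain depth) is deliberately chosen so that collapsing
weakly-supported nodes can never *create* 2R support — collapse leaves the
count unchanged or raises it, so `2R` labels can only disappear.

**Synteny guard.** Gene losses displace LCA mappings downward: a 2R
duplication whose copies survive only in, say, sarcopterygians maps to the
sarcopterygian ancestor and branch rules would mislabel it
`lineage-local`. When a locus table is supplied, a duplication mapped to a
branch without a WGD keeps its local/lineage label only if it looks like a
local event — some species carries copies from both sides on one chromosome
within `local_gap` (default 1 Mb), or the two sides contrast in intron
presence (the retrotransposition signature, which is how the intron-less
rhodopsin duplication on the actinopterygian stem keeps its
`between-2R-3R` date). Anything else becomes `unresolved` rather than
risking a wrong window.

Two irreducible blind spots remain, and the scoring utilities name them
explicitly. A WGD duplication whose two copies survive on disjoint sides of
the relevant species split is topologically identical to a speciation
(hidden paralogy through reciprocal loss); no topology-based method can
flag it, and `score_window_recovery()` counts such nodes as *absorbed by
loss* outside the detectable denominator. And a local duplication occurring
on the same branch as a WGD (the teleost OTR and V2A tandem pairs in the
scripted scenario) is indistinguishable from the WGD duplication by
topology alone and is dated to that window.

### Paralogon assembly and rearrangements

Blocks of one reference species become nodes of a graph; the edge between
two blocks counts the families contributing a paralog pair spanning them
whose join node is dated `2R` (or `3R` for within-teleost graphs). Connected
components after discarding edges below `min_support` are the paralogons.
`min_support = 2` by default: one shared family is weak evidence, while
genuine 2R blocks share many families.

Orthologs are read straight off the reconciled trees (join node is a
speciation). Two same-species blocks merge into one *ancestral unit* when at
least `min_support` of their genes' orthologs co-locate on a single outgroup
chromosome — recognising a lineage-specific fission, which is why the
scripted reference genome shows five raw blocks but four ancestral units.
Translocations are runs of at least `min_run = 2` consecutive loci whose
orthologs co-locate on an outgroup chromosome different from their host
chromosome's strict-majority "home"; a tie in the majority leaves the
chromosome unresolved rather than guessing. When the outgroup diverged
before the last WGD and the derived species after it, the move is timed
`post-3R`. Single-gene transpositions are not called unless `min_run` is
lowered, by design.

### Dollo reconstruction

Cutting each dated tree at its resolved duplications partitions the extant
loci into subtype lineages; each lineage originates at its duplication and,
under the single-origin (Dollo) assumption, can only be lost. Ancestral
content at a node counts the gene-tree edges crossing that node — this
handles lineages that later continue under new names (e.g. the RH1 gene
that later spawned the retrogene) without double counting, and the same
edge-crossing logic evaluated just before a WGD yields the pre-window
repertoire (`repertoire_before_wgd()`, `scenario_summary()` node keys
`pre:<label>`). Losses sit atop each maximal extinct subtree, which is the
unique minimal placement; species flagged assembly-unreliable never force a
loss, and when their exclusion opens several equally parsimonious
placements the topmost edge is reported with the tie count in
`n_alternatives` (verified against exhaustive branch-cover search in the
tests). Content at a node requires at least one surviving descendant below
it: a lineage extinguished before leaving any extant descendant is
unobservable, a stated limit of any parsimony reconstruction.

## The simulator

`replay()` executes an event log over the species tree: WGDs double every
locus onto a suffixed chromosome preserving order and adjacency; losses,
tandem duplications (small positional offsets), retrotranspositions
(intron flag off), translocations of contiguous runs and fissions edit the
genome along branches; speciations copy it into daughter lineages. True
gene trees record every branching, with node heights following species-tree
depth and within-branch event order; per-node truth labels state each
duplication's generating event and expected window. Replay is a pure
function of (log, tree), and the stochastic generator is a pure function of
its config including the seed.

The scripted scenario (`script_figure5()`) encodes the proposed history of
the visual-opsin regions: pre-2R tandem duplications (SWS/LWS, V1/V2), the
2R quadruplication and stem losses leaving 5 opsins / 3 GNAT / 3 GNAI /
6 OT/VP-R / 4 CACNA1-L, V1B loss and RH1 retrotransposition on the
actinopterygian stem, 3R with a retained-duplicate set (GNAI1, GNAI2, V1A,
CACNA1D, CACNA1C, CACNA1F, the RH1 retrogene), teleost tandem duplications
of OTR and V2A, two post-3R translocations intermingling the 3R blocks,
four tandem RH2 genes in the zebrafish lineage, and a fission of one 2R
chromosome in the human lineage. Whether the two intron-less rhodopsin
genes (rho/rhol) are 3R duplicates is genuinely open in the data; the
default scripts the 3R origin and `rho_3r = FALSE` scripts the post-3R
tandem alternative. A single-copy decoy family on an unlinked chromosome
serves as the negative control for the synteny screen.

The stochastic generator's defaults are the package's study conditions,
chosen once: the six-species tree (an invertebrate chordate outgroup,
coelacanth and human, gar, and two teleosts — the relevant divergences of
the real taxon sampling at desk scale); an ancestral chromosome carrying
the seven main-family genes plus ten single-copy neighbor families spread
over ~5 Mb (real screens pool dozens of neighboring families; ten keeps
runs fast while giving translocated runs enough ortholog anchors); loss
probability 0.2 per locus per branch; up to two post-3R translocations of
three-gene runs; optional NNI noise on the gene trees (default 0). On a
WGD-carrying branch the WGDs precede the drawn losses — a loss drawn before
the WGD would simply be indistinguishable from two losses after it.

What the simulator does *not* emulate: sequence evolution and inference
error (NNI moves are a topological stand-in), assembly fragmentation,
gene conversion, unequal crossing-over within tandem arrays, and
continuous-time rates (events are per-branch draws). Passing tests
therefore demonstrate correctness of the inference machinery on histories
of the modelled kind, not robustness to every artifact of real genome
assemblies.

## Parameters at a glance

| parameter | default | where | rationale |
|---|---|---|---|
| `window` | 5e6 bp | `define_blocks()` | the ±5 Mb screen used for these regions; exact arithmetic, no rounding |
| `min_blocks` | 2 | `select_families()` | membership on ≥2 blocks; the stricter 3-block variant used for teleost screens is a flag |
| `max_members` | 200 | `select_families()` | families too large for reliable phylogenetics are dropped; the cutoff is this package's choice |
| `max_gap` / `local_gap` | 1e6 bp | local duplicates, synteny guard | tandem duplicates sit within tens of kb; dispersed copies tens of Mb apart |
| `min_support` | 2 | `assemble_paralogons()`, `detect_fission()` | one shared family is weak evidence |
| `min_run` | 2 | `detect_translocations()` | avoids calling single-gene transpositions |
| `collapse_below` | off | `date_duplications()` | when set (e.g. 50), weak nodes become polytomies before dating |
| `loss_prob` | 0.2 | `sim_config()` | study condition for recovery experiments |
| `n_translocations`, `translocation_run` | 2, 3 | `sim_config()` | study condition |

## Numerical conventions

Coordinates are 0-based half-open; a locus exactly at a block end is
outside it. Blocks clip at 0 always and at chromosome length when a lengths
table is supplied (unknown chromosomes stay unclipped, with a warning).
Greedy adjacency pairing takes the nearest pair first, ties broken by
smaller start. Paralogon groups and ancestral units are numbered by their
smallest block id; all writers sort rows on stated keys so outputs diff
cleanly. Gene trees must arrive rooted; no automatic midpoint rooting is
applied. Within the simulator, WGD copies are suffixed `_<label>` on both
chromosome and lineage names, and families starting from several ancestral
loci are joined under an ancient duplication node so each family tree has a
single root.

## Validation sizes

The test suite validates reconciliation, duplication flagging, orthology
and Dollo loss placement against exhaustive brute-force oracles on 100
seeded random instances each (8-tip gene trees on a 5-species tree; up to
12-species trees for loss covers), checks the scripted scenario end to end
(137 extant loci, 6 families, exact integer repertoires), and measures
recovery on 20 seeded stochastic replicates at the study conditions,
scoring window labels over detectable (non-absorbed) WGD nodes and
translocations over detectable groups (≥2 surviving ortholog anchors on a
chromosome with an unambiguous home, moves between 3R-sister chromosomes
being invisible to a pre-3R outgroup by construction). The acceptance
script reruns all of this from scratch under a caller-supplied seed.

## Known limitations

* Hidden paralogy (reciprocal loss) and same-branch local duplications are
  undatable by topology, as described above.
* The pre-window capacity rule attributes super-capacity chains to tandem
  duplications *before* the window; a tandem duplication between 2R-1 and
  2R-2 would be indistinguishable and is not modelled separately.
* Dollo content cannot see lineages with no extant descendants.
* Translocation timing is binary (post-WGD vs unresolved) and relies on an
  intact pre-WGD outgroup; nested rearrangement histories are out of scope,
  as are inversion/breakpoint distances and rearrangement phylogenies.
* Orthology is tree-based only; no sequence-similarity fallback exists for
  families without trees (they are skipped with a warning).
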