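---
title: "Methods: calling highly conserved defense systems from pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling highly conserved defense systems from pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`coredefensome` operationalises a simple population-genomic question: which
complete anti-MGE defense systems are retained across (essentially) all
genomes of a bacterial species? The unit of analysis is the *conservation
block*: an equivalence class of orthologous complete system instances
within one species, counted once regardless of genomic position, so a
block may contain syntenic and non-syntenic instances alike.

The pipeline assumes its inputs are trustworthy annotations: per-genome
gene coordinates, complete defense/counter-defense system calls (family,
component genes), MGE intervals with class labels, and protein sequences.
It deliberately does **not** re-run annotation tools; only complete
systems are analysed, because partial hits carry too high a false-positive
burden and, for multi-gene systems, cannot function.

Orthology is gene-level reciprocal best hits (RBH), lifted to the system
level: two instances are linked iff they share a family and every
component of each has an RBH partner among the components of the other.
The RBH pair is computed over all hits first and then filtered on both
directed hits (identity $\ge$ 95 %, coverage $\ge$ 80 %, e-value
$\le 10^{-4}$). That ordering matters: filtering before picking the best
hit can promote a second-best hit and create new pairs when thresholds are
*raised*, which would break the expected monotonicity of the ortholog set
in the thresholds; filtering the mutual pair afterwards is monotone and
matches the natural reading of "a reciprocal best hit existed among them,
and both hits" pass the thresholds.

Blocks are connected components of the link graph under single linkage.
No clustering rule beyond pairwise orthology is implied by the method
itself; single linkage is the minimal closure that makes "block"
well defined, and at 95 % within-species identity spurious chaining is
unlikely. `defensome_config(linkage = "complete")` provides a stricter
clique-based variant for sensitivity analysis.

With $p$ = (genomes carrying at least one member) / (all QC-passing
genomes of the species):

* **core**: $p = 1$;
* **quasi-core**: $0.90 \le p < 1$ (boundary inclusive — "at least 90 %");
* **accessory**: $p < 0.90$.

HCADS = core $\cup$ quasi-core. The denominator includes genomes with zero
defense systems: conservation is a claim about the species, not about the
subset of genomes that happen to carry defenses.

## Tunable parameters

All thresholds live in `defensome_config()`; defaults are the published
analysis values.

| parameter | default | unit | role |
|---|---|---|---|
| `min_identity_pct` | 95 | % | RBH identity floor |
| `min_coverage_frac` | 0.80 | fraction | RBH coverage floor (both sequences) |
| `max_evalue` | 1e-4 | — | RBH e-value ceiling |
| `quasi_core_min_frac` | 0.90 | fraction | quasi-core presence floor |
| `island_max_gap_genes` | 10 | genes | max intervening non-defense genes |
| `island_min_genes` | 5 | genes | min defense genes per island |
| `island_min_families` | 3 | families | min distinct families per island |
| `min_genomes_per_species` | 10 | genomes | species (and vOTU) floor |
| `qc_min_completeness` | 90 | % | CheckM-style completeness floor |
| `qc_max_contamination` | 5 | % | contamination ceiling |
| `votu_min_ani` | 95 | % | vOTU ANI floor |
| `votu_min_tcov` | 0.85 | fraction | coverage floor on the member contig |

"$\ge$ 80 % coverage" is ambiguous (query, subject, or both); the default
applies it to the *minimum* of the two coverages, the strictest reading,
which prevents single-domain hits from seeding orthologs
(`coverage_mode = "query"` relaxes it). Likewise "separated by no more
than 10 genes" is read as $\le$ 10 *intervening* non-defense genes
(`gap_mode = "rank"` switches to the rank-distance reading).

## Defense islands

Defense genes (components of complete defense systems) are chained
greedily left-to-right along gene rank; a maximal chain is an island iff
it reaches the gene and family floors. Because maximal gap-bounded
clusters on a line are unique, the greedy chaining is exact, not a
heuristic — the test suite nevertheless verifies it against an
independent component-based enumeration on a thousand random replicons.
Circular replicons are chained with the wrap-around gap between the last
and first defense genes; the island set is therefore invariant under
rotation of the gene order. "At least 5 genes" counts defense genes, not
total genes in the span: only defense genes can "represent" defense
families. Gene rank is annotation order, recomputed from coordinates
(start, ties by end then gene id), because physical "genes apart" is what
a gap of ten genes means in practice.

## MGE colocalization

Overlapping MGE annotations (e.g. an integron called inside a plasmid)
are ambiguous evidence, so *both* members of every intersecting pair are
excluded before any context is assigned; the removal is symmetric because
the exclusion has no stated direction and a containment hierarchy would be
arbitrary (`mge_overlap_mode = "nested"` keeps the enclosing element). A
system gets an MGE context only when *all* its component genes fall inside
a single MGE interval; partial overlaps default to chromosome and are
flagged. This strict containment avoids double counting and makes the
context a partition: chromosome plus per-class counts always sum to the
number of complete instances (asserted at run time).

Density denominators: genome densities use the manifest genome size in
Mb; integron-class densities use the summed span of that class per genome
— a per-Mb-of-element normalisation, chosen because integron spans differ
by orders of magnitude from genome sizes. Zero counts are reported as
density 0 (null values are data); zero spans yield `NA`, not 0.

## Statistics

The Mann-Whitney-Wilcoxon test is two-sided. For $n_1 + n_2 \le 16$
without ties the exact permutation null is used; the number of rank
configurations at each value of $U$ is the coefficient of $q^U$ in the
Gaussian binomial $\binom{n_1+n_2}{n_1}_q$, computed by exact polynomial
recurrence, and the two-sided p-value is
$\min(1,\, 2\min(P(U \le u), P(U \ge u)))$. Larger or tied samples use the
normal approximation with tie correction and continuity correction; at
$n_1 = n_2 = 10$ the approximation is within 0.01 of enumeration.

Family enrichment in islands (or per MGE class) uses two-sided Fisher
exact tests on per-family 2×2 tables with Benjamini-Hochberg correction —
the source analysis names no method, and Fisher + BH is the standard
choice for sparse family counts. The density-size relation uses Spearman
rank correlation, robust to the heavy-tailed density distribution; the
correlation method is likewise an open choice documented here rather than
prescribed by the method.

## vOTU clustering

Greedy centroid clustering: contigs sorted by length (ties broken by id),
longest unassigned contig seeds a cluster, and a contig joins when an ANI
record links it to the centroid with ANI $\ge$ 95 % and the *member's*
covered fraction $\ge$ 85 %. The coverage orientation is the single
highest-risk compatibility point with the reference clustering script; the
implemented rule — the member, typically the shorter contig, must be
mostly covered by its alignment to the representative — reproduces that
script's effective behaviour (it filters edges on the coverage of the
edge's target, and keeps edges whose query is the centroid). The built-in
nucleotide ANI backend is a test-grade approximation (shared-k-mer
diagonal voting followed by ungapped column comparison), exact for
substitution-only divergence; production runs should supply a precomputed
ANI table.

## The synthetic world

`simulate_pangenome()` emulates exactly the statistical structure the
method assumes, nothing more:

* planted blocks appear in the first `round(p * n)` genomes (nested
  carrier sets), so the 0.90 boundary is exactly plantable (18/20);
* member proteins carry exactly `round(d * L)` substitutions from a block
  ancestor (`d` = 0.02 by default), so any two members differ at $\le 2dL$
  positions and always clear the 95 % identity threshold, while decoy
  paralogs descend from an 85 %-identity ancestor and can never reach it —
  both bounds are re-verified by assertion after generation;
* islands are planted as contiguous runs of 2–3 families with small
  internal gaps; isolated features are separated by 15 background genes,
  which cannot chain under a gap bound of 10;
* per genome the MGE layout includes a prophage carrying the decoy
  system, an empty plasmid, a sedentary integron, and an ICE/mobile-integron
  overlapping pair that must be excluded.

The mutation model is substitution-only (no indels) with uniform residue
replacement, and genomes differ only in which planted blocks they carry
plus independent background genes. This keeps every planted quantity
analytically controlled, which is the point of the generator; it does
**not** emulate gene gain/loss dynamics, rearrangement, real amino-acid
composition, HGT, or incomplete/fragmented systems. A green
planted-truth test therefore establishes that the pipeline's logic is
correct under its own stated assumptions — not that those assumptions
hold for any particular real dataset, nor that DefenseFinder-style inputs
are themselves accurate. Sample sizes of the default demo world (5
species × 20 genomes, 6 blocks at presences 1.0/0.95/0.9/0.5) were fixed
once, before any results were inspected, to cover every classification
boundary at desk scale.

`simulate_phage_contigs()` plants vOTUs the same way at the nucleotide
level (1 % within-vOTU divergence keeps intra-vOTU ANI $\ge$ 98 %;
inter-vOTU pairs are independent random sequences and are omitted from
the sparse ANI table, mimicking an aligner that reports no hit).

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF convention); any
  half-open arithmetic is private to an operation.
* Best-hit ties break deterministically: bitscore, then e-value, then
  identity, then lexicographic subject id.
* The built-in aligner is Smith-Waterman under BLOSUM62, gap open 11 /
  extend 1, with Karlin-Altschul e-values ($\lambda = 0.267$,
  $K = 0.041$, the gapped BLAST constants); pairs sharing no exact 6-mer
  are reported as zero-score rows without alignment — by pigeonhole, any
  pair that could pass 95 % identity over a meaningful span shares a
  6-mer, so no admissible hit is lost.
* Empty inputs flow through: an empty systems table yields zero blocks,
  an empty ANI table yields all-singleton vOTUs, a species with one
  genome yields an empty hit table.
* Unknown MGE classes and dangling gene references are fatal errors, not
  warnings: silent coercion would corrupt the colocalization statistics.

## Known limitations

* Intragenome (paralog) hits are ignored; families are never merged via
  paralogy.
* A single system instance whose own components straddle a gap larger
  than the island bound contributes its genes independently to chaining.
* Block counts treat multiple same-family blocks in one species as
  distinct blocks.
* The HCCDS arm inherits every assumption of the HCADS arm, with vOTU
  members in place of conspecific genomes; vOTUs below 10 members are
  skipped, not analysed with wider uncertainty.
* Full-scale published figures (tens of thousands of genomes, external
  aligners) are out of desk-scale reach; the package validates logic
  against planted truth and supports external hit/ANI tables for
  full-scale reproduction.
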