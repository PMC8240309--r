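---
title: "Finding genes scattered across assembly-graph edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding genes scattered across assembly-graph edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfgraph)
```

## The problem

Bacterial genomes — *Bacillus thuringiensis* with its insecticidal Cry/Cyt/Vip
genes is the motivating case — often carry several long, mutually similar
copies of a gene family. In a de Bruijn assembly graph those copies collapse
onto shared edges and diverge at bubbles, so a single gene is spelled by a
path through many edges, and the assembler's contigs each cover only a
fragment of it. Contig-based gene finders then miss the gene entirely.
`orfgraph` searches the graph itself: it takes partial protein or
profile-model alignments to the graph (*anchor paths*), extends each anchor
to every reachable in-frame start and stop codon, enumerates the candidate
coding paths connecting them, and reduces the resulting (often highly
redundant) set of open reading frames to a small list of representative
proteins.

## The procedure

1. **Anchors.** Alignments covering at least 80% of a query protein (or 90%
   of a profile model, at e-value ≤ 1e-9 for ingested model hits) become
   anchor paths. At desk scale the package aligns for itself: maximal
   simple-path spellings are translated in three frames (both strands are
   enumerated, covering six frames) and each query is locally aligned with
   BLOSUM62, keeping hits at ≥ 80% identity. Production-scale alignments
   from a sequence-to-graph or HMM-to-graph aligner are ingested from TSV
   instead. An anchor that is a subpath of another anchor in the same
   reading frame is redundant and removed.

2. **Codon search.** From the anchor's right boundary a breadth-first search
   walks the graph base by base, carrying the partial codon consumed so far
   (the *frameshift string*, 1–3 nt). A state whose frameshift string
   completes a stop codon is terminal: no ORF continues past an in-frame
   stop, so exploration halts there (but the site is reported). The start
   side runs the same machinery on the reverse-complement strand in the
   complementary frame; it is *not* pruned at upstream stops — a start lying
   beyond an in-frame stop is instead flagged `after_stop`, and a start
   preceded (5–15 nt upstream, ≥ 4/6 matches) by a Shine-Dalgarno-like
   AGGAGG motif is flagged `has_sd`. Both flags are annotations for the CDS
   report, never filters. Visited states are keyed by graph position,
   partial codon, and codon start, which bounds the search on cyclic graphs.

3. **CDS generation.** For every (start, stop) pair the package enumerates
   prefix paths (start → anchor) and suffix paths (anchor → stop) by bounded
   exhaustive search: a depth-first reachability pass first computes the set
   of edges that can lie on any sufficiently short connecting walk, and
   enumeration is confined to those edges, capped at 1000 paths per pair
   (with a truncation flag when the cap fires). Concatenates longer than
   3000 nt (`max_restorable_length`, inclusive), out of frame, containing an
   internal stop or an N, are discarded; survivors are translated (table 11,
   alternative initiators read as Met) and deduplicated on the amino-acid
   sequence.

4. **Ranking.** Each candidate carries the triplet *(start-distance
   likelihood, read coverage, path length)*, compared lexicographically. The
   likelihood of observing a model hit at distance *d* from the gene start
   is the fraction of training distances within *d* ± `binSize` (150 nt);
   coverage is the length-weighted mean of per-edge KC/DP tags; length is
   the spelled nucleotide length.

5. **Contig-contradiction filter.** An edge is *unique* when it is longer
   than `minLength` (300 nt) and its flanking junctions branch (start-node
   outdegree > 1, end-node indegree > 1). Two paths are *compatible* when
   one contains the other or a suffix of one equals a prefix of the other
   (orientation-aware). A candidate sharing a unique edge with a contig path
   while being incompatible with it cannot co-exist with that contig in one
   genome and is removed.

6. **Classification.** Candidates are compared against the protein database;
   best local-alignment identity below 80% removes the ORF from the retained
   set (this screens out thioredoxin-like look-alike families), identity of
   exactly 100% is `reliable-known`, within (90, 100) `reliable-novel`,
   otherwise `reliable`.

7. **Clustering and representatives.** Two ORFs are linked when one
   translation is a substring of the other or their identity exceeds `PI`
   (90%); clusters are single-linkage components. Edges longer than 1 kb
   appearing in a cluster are its *long cluster edges*; members are scanned
   in decreasing reliability and kept whenever they contain a long edge not
   yet covered, so the representatives jointly cover every long cluster
   edge. A cluster without long edges contributes its single most reliable
   member.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_protein_fraction` | 0.8 | fraction | anchor retention (protein hits) |
| `min_model_fraction` | 0.9 | fraction | anchor retention (model hits) |
| `max_evalue` | 1e-9 | — | ingested model hits only |
| `min_identity` | 80 | % | built-in aligner retention |
| `max_paths_per_pair` | 1000 | paths | enumeration cap |
| `max_restorable_length` | 3000 | nt | longest restorable CDS (inclusive) |
| `binSize` | 150 | nt | likelihood window half-width |
| `minLength` | 300 | nt | unique-edge length threshold |
| `retain_identity` / `reliable_identity` | 80 | % | retain filter / reliable band |
| `novel_low` | 90 | % | lower bound of the novel band |
| `PI` | 90 | % | clustering linkage threshold |
| `long_edge_min` | 1000 | nt | long cluster edges |

`minLength` is worth raising (e.g. to 500 nt) on high-N50 assemblies, where
300-nt edges are no longer reliably unique.

## Design choices at genuinely open points

- **Representative scan order.** Selecting representatives "in
  lexicographically non-decreasing order" of triplets would consider the
  *least* reliable member first, defeating the purpose of selecting reliable
  sequences; the package scans in decreasing order. The literal ascending
  scan is available via `cluster_params(literal_scan_order = TRUE)`; both
  orders provably cover all long cluster edges.
- **Unique-edge degree convention.** The predicate is implemented exactly as
  stated (start node outdegree > 1, end node indegree > 1), although the
  inverse (unitig-interior) convention is also defensible;
  `unique_edge_params(degree_convention = "unitig")` switches to it.
- **Repeated edges in enumeration.** Paths may revisit an edge as long as the
  total spelled length stays within `max_restorable_length`; tandem-repeat
  genes legitimately reuse edges, so the length bound, not simplicity, is
  the terminator.
- **Boundary semantics.** "Length below `max_restorable_length`" is
  implemented inclusively: a 3000-nt concatenate is kept, anything longer is
  not.
- **Thresholds count query residues.** The 80%/90% anchor-length fractions
  are computed over aligned query residues, and percent identity over
  aligned columns excluding terminal gaps.
- **Absent evidence.** A model with no training distances contributes
  likelihood 1 (no penalty); a graph without coverage tags scores coverage 0
  for every candidate, making the coverage component neutral.
- **Shine-Dalgarno definition.** AGGAGG with ≥ 4/6 matches, window 5–15 nt
  upstream; annotation only.
- **Gapped contig paths** are split at `;` gaps into gap-free sub-paths
  before the compatibility filter; a gap gives no adjacency evidence.
- **Initiator translation.** GTG/TTG initiators are translated as Met, so a
  recovered protein matches its database entry exactly.

## Numerical and degenerate-input behaviour

Coordinates are 0-based half-open throughout. Ties in the reliability order
are broken by `orf_id`, making every stage a deterministic function of its
input; re-running the pipeline byte-identically reproduces its outputs. Ends
of paths falling inside an edge overlap are normalised onto the previous
edge before spelling. Candidate ORFs whose spelled sequence contains N are
discarded (they cannot be translated faithfully). An empty anchor set, or a
similarity filter that removes everything, yields an empty result with a
warning rather than an error. Spelling assumes GFA overlap consistency
(adjacent edges agree on their shared bases); `read_gfa()` warns when a link
violates it.

## What the fixture generator emulates — and what it does not

`generate_fixture()` writes the graph directly rather than assembling reads:
edges are cut from a genome string so that adjacent edges share `k` (default
55) bases, exactly as a SPAdes-style graph would represent them. Each CDS is
flanked by 300 nt of random sequence with an in-frame stop planted
immediately upstream, so the embedded gene is the unique maximal ORF of its
region. Bubbles duplicate an internal in-gene edge with 3 third-codon
substitutions (strain-level divergence) at half the coverage of the original
path (20× vs 40×); a tangle shares one central repeat edge between two gene
copies diverged at 40% of codons (distinct family members), with additive
coverage on the shared edge. Unitig-style contigs are derived by cutting the
genome paths at every branching junction.

Real data differ in ways the fixtures deliberately ignore: sequencing error
and coverage gaps, chimeric links, overlaps that vary across the graph,
repeat families unrelated to the target genes, and assembler-specific
simplifications. Passing the test suite therefore demonstrates correctness
of the graph algorithms under clean topology, not robustness to noisy
assemblies; the anchor thresholds and the contig filter are the components
that carry that burden on real data, and they are exercised here only
structurally.

Problem sizes in the test suite are chosen for a desk-scale workflow:
embedded genes of 300–1000 codons, up to 10 bubbles (1024 path
combinations), graphs of a few dozen edges, and 100+ randomized
oracle-equivalence cases for the codon search against exhaustive path
enumeration.

## Known limitations

- The built-in aligner enumerates maximal simple paths and is intended for
  small graphs only; it aborts above a configurable path budget, at which
  point externally computed anchors (sequence-to-graph / profile-HMM-to-graph
  alignments) should be supplied.
- E-values for ingested model hits are taken at face value; the package does
  not recompute alignment statistics.
- The unique-edge heuristic is, by construction, error-prone on complex
  graphs; it trades recall for precision and its `minLength` should track
  assembly contiguity.
- Clustering computes all pairwise identities and is quadratic in the number
  of retained candidates.

## A worked example

```{r example, eval = FALSE}
fix <- generate_fixture(n_bubbles = 3, seed = 1)
db <- setNames(fix$truth$aa, fix$truth$gene_id)
res <- run_pipeline(pipeline_config(
  graph = fix$graph, proteins = db, contigs = fix$contigs,
  report_known = TRUE))
tidy(res)       # one row per representative, with verdict and triplet
glance(res)     # per-stage counts in one row
autoplot(res)   # stage-count bar chart
```
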