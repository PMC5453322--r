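---
title: "Methods: exon-level protein-feature annotation and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-level protein-feature annotation and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exont)
```

# The problem

A coding exon is a container for protein sequence: domains, modified
residues, localization signals, and structural states all map back to the
nucleotides that encode them. When a set of exons is co-regulated — say,
included in one cell state and skipped in another — the functional question
is which protein features that set adds or removes. `exont` answers it in
three steps: project protein-coordinate annotations onto genomic exons,
summarise each ontology term's footprint as a coverage score, and compare
that score against size-matched random exon sets from a control category.

# The ontology

Terms describing protein features are organised as a directed acyclic graph
of `is_a` links whose roots are eight classes: catalytic, binding,
receptor, transporter, localization, structure, PTM, other. The loader
accepts a minimal OBO subset (`[Term]`, `id:`, `name:`, `is_a:`) plus a
sidecar table mapping root terms to the eight classes, because merged
ontologies assembled from several sources (sequence-feature, protein
modification, and domain ontologies) do not share a single dialect. Merging
rules across sources are deliberately *not* re-invented here: the merged
ontology is an input, and the loader validates it (unique ids, no dangling
parents, no cycles) rather than constructs it.

Multiple parents are allowed — domain/GO-derived graphs are DAGs, and
"tree" is treated as informal. A term reachable from more than one root
class takes the class of its *nearest* root (breadth-first distance;
lexicographic tie-break) and is flagged, since the sources give no rule.
Terms from which no mapped root is reachable are reported and labelled
`unresolved` rather than dropped: they still carry annotation, they just
cannot be grouped by class.

# Gene models, exon categories, control pools

Models come from GFF3 (gene / mRNA / exon / CDS with `Parent` links). An
exon is *coding* if it overlaps a CDS segment of any transcript of its
gene; its coding sub-interval is the span of those intersections. Internal
coordinates are 1-based and closed — the GFF3 and IRanges convention, which
keeps every Bioconductor interval operation direct — and BED input/output
is converted at the boundary, so both dialects round-trip exactly.

Two labels drive control-pool choice, because different exon categories
carry systematically different features:

* **Position**: first / internal / last coding exon, per gene, on the union
  of its coding exons in transcription order (strand-aware). The single
  exon of a one-coding-exon gene is both first and last; it is recorded as
  `first_coding` and kept out of internal pools, and the case is reported.
* **Splice class**: an exon is *constitutive* when its exact genomic
  coordinates occur in every transcript of its gene, *alternative*
  otherwise. This exact-coordinate rule is a reproducible proxy — splicing
  databases flag alternative exons from transcript-evidence counts whose
  thresholds are not public — and it is applied uniformly to real and
  synthetic models.

A CDS length not divisible by three is a warning, not an error: real
annotations contain partial models, and amino-acid projection only requires
that a feature fit inside the CDS actually present.

# Projection of protein features

Amino acid *i* occupies coding nucleotides `3(i-1)+1 .. 3i`. These are
walked through the transcript's CDS segments in coding order (for a
minus-strand transcript, descending coordinates), split at segment
boundaries, and intersected with the coding part of every exon they
overlap; a feature partially overlapping an exon contributes only the
overlap. Before clipping, a feature of *k* amino acids always yields
exactly `3k` genomic nucleotides — an invariant the tests exercise
exhaustively. Single-residue features (modified sites) are 3-nucleotide
intervals; a codon split across a junction contributes its nucleotides to
both exons, which nucleotide-level bookkeeping makes unambiguous.

Hits of the same term on the same exon are unioned — "covered nucleotides"
means coverage, not summed hit lengths — so annotating a feature twice
changes nothing. With propagation on (the default for enrichment), every
hit is also recorded for all ancestor terms; parent coverage is then the
union over the subtree, and parent frequency dominates child frequency.
Propagation is off by default only for per-exon annotation *reports*, which
should show primary evidence rather than inherited copies; both behaviours
are exposed because upstream databases differ on whether ancestors are
materialised.

Localization motifs are scanned from protein sequence by configurable
regular expressions (leftmost non-overlapping matches, PCRE), shipped as an
editable table: a monopartite NLS `K[KR].[KR]`, a bipartite NLS
`[KR][KR].{10,12}[KR]{3}`, a CRM1-type NES `L.{2,3}[LIVFM].{2,3}L.[LI]`,
and the C-terminal PTS1 `[SAC][KRH][LM]$`. The patterns are data, not code:
published pattern sets vary, and users are expected to curate their own.

# Score, null distribution, Z, FDR

The score of term *h* on exon set *E* is `1000 * size(h) / size(E)` —
union-covered nucleotides per kilo-nucleotide of coding sequence, bounded
by [0, 1000] and equal to the coding-length-weighted mean of per-exon
scores. The nt-per-knt unit is used rather than a plain fraction; the two
differ by a constant, so Z-scores are unaffected.

The null is built by sampling exons uniformly without replacement from the
control pool, stopping at the first exon that reaches the test set's total
coding size (so realized sizes overshoot by less than one exon; they are
recorded). Each of `n_sets` (default 1000) random sets is scored for all
tested terms in one pass. Scores across random sets are approximately
log-normal, so inference happens on the log scale:
`z = (log s_obs - mu) / sigma`. Numerical choices:

* **Zeros.** A zero score has no log; it is replaced by the score of a
  single covered nucleotide over the set's total size. This keeps the
  transform finite and order-preserving. The floor matters only when a
  term can plausibly miss an entire random set — rare for the frequent
  terms that pass the 4% filter at realistic set sizes.
* **Degenerate nulls.** A term whose null scores have zero variance is
  flagged `untestable`, excluded from the FDR, and reported with `NA`
  statistics rather than an arbitrary z.
* **Frequency filter.** Only terms annotating at least `min_freq`
  (default 0.04) of the control pool's exons are tested, with propagation
  on; sparse terms have no usable null at desk scale.
* **p-values.** Default: two-sided normal tail of `z`. Alternative
  (`mode = "empirical"`): `2 * min(#above + 1, #below + 1) / (n_sets + 1)`,
  capped at 1 — provided because log-normality is an approximation, and the
  two modes should (and in tests do) rank terms nearly identically.
* **FDR.** Benjamini–Hochberg step-up across the tested terms, implemented
  directly (`q = min over larger ranks of p*m/rank`, capped at 1) and
  cross-checked against `stats::p.adjust` to 1e-12.
* **Determinism.** Every sampling function takes a seed and restores the
  caller's RNG state; a fixed seed reproduces the result table exactly.
  Results sort by `q`, then `|z|` descending, then term id.

Nulls are sampled on the fly rather than read from precomputed size-binned
distributions: at desk scale sampling is cheap and binning would only add
approximation. Test exons are *not* removed from the control pool by
default — the canonical designs compare disjoint categories (e.g.
alternative vs constitutive internal exons) — but `exclude_test = TRUE`
exists for overlapping designs.

# Interaction partners

The interactome overlay reads PSI-MITAB 2.5, consuming only the two
interactor id columns and the source column: the network is used as a
partner list, not a weighted graph. Edges are canonicalized
(lexicographic), deduplicated; self-edges are kept and flagged.
`partners_of()` returns each query gene's partners and the partners shared
by two or more query genes — the hook for asking whether co-regulated exons
sit in genes converging on common interactors.

# The synthetic generator

Because the full human annotation is built from external databases, every
module is instead testable against generated fixtures with known ground
truth. The generator emulates compact vertebrate-like coding loci:

* exon lengths log-normal, median ~130 nt, clipped to [30, 2000] nt —
  the human coding-exon length regime; intron lengths uniform 100–2000 nt;
  3–8 coding exons per gene, both strands;
* most genes (p = 0.7) carry a second transcript skipping one internal
  exon, creating alternative exons (the skipped exon is kept frame-intact
  so both CDS lengths stay divisible by three);
* term coverage is placed as randomly positioned intervals (geometric
  lengths, mean 30 nt) until a per-exon target density (default 0.25) is
  reached — overlapping hits exercise the union logic; modified-residue
  terms are planted as single residues;
* per-term exon frequencies are drawn from 0.15–0.40 and test lists hold
  25 internal exons (~4 knt). These sizes put the fixtures in the regime
  the method is designed for — terms frequent enough to pass the 4% filter
  and sets large enough that empty-set scores are rare — at 40 genes
  (~220 coding exons), which keeps the full test suite in minutes;
* proteins are emitted per transcript with localization motifs inserted at
  recorded positions. The background alphabet excludes K, R, L and H, so
  the shipped motif patterns cannot match, or extend a match, by chance:
  scanner recovery of exactly the recorded sites is guaranteed by
  construction, not by luck;
* spiking multiplies one term's density on chosen exons. Placement streams
  are seeded per (term, exon) independently of the main stream, so a spike
  changes only the targeted placements (as supersets of the originals) and
  an empty spike list reproduces byte-identical files;
* the truth record stores term frequencies recomputed by independent
  per-nucleotide marking over the emitted files, the planted spike, and
  the motif sites.

What the generator does **not** emulate: the heavy-tailed human term
frequency spectrum, UTR-containing exons with partial coding overlap
beyond simple clipping, non-canonical gene structures (trans-splicing,
seleno-recoding), or a realistic ontology of thousands of terms. Passing
tests therefore demonstrate correctness of the machinery and calibration
of the statistic under controlled conditions — not that any particular
biological annotation is right.

# Verification design

* Scores are compared *exactly* against a per-nucleotide mark-and-count
  oracle (independent code path: position enumeration and set union, no
  interval arithmetic) across random fixtures.
* Coordinate projection is verified by exhaustive round trips over random
  transcripts on both strands, and by the 3-nt-per-aa conservation law.
* Calibration: with test sets drawn from the control pool, the type-I rate
  at alpha = 0.05 over 200 trials (one focal term per trial, so trials are
  independent) must sit inside the binomial 99% interval, and the mean z
  across all terms and trials inside [-0.15, 0.15]. Problem sizes: 500
  null sets per trial, ~220-exon pools.
* Spike recovery: a term planted at 3x background must rank first by z
  (min-tie ranks) with q < 0.05 at 1000 null sets. The planted term is the
  sole child of its root class, so propagation cannot produce an ancestor
  with a strictly larger coverage union that would legitimately outrank
  the leaf.
* The BH step-up is compared to the stock implementation to 1e-12, and the
  4% filter is checked for exactness on frequencies straddling the
  threshold.

# Limitations

* Exact-coordinate constitutivity is a proxy; with sparse transcript
  annotations it over-calls constitutive exons.
* The parametric p assumes log-normal null scores; heavy flooring (sparse
  terms, tiny pools) distorts sigma. The empirical mode is the fallback,
  and `untestable` flags the fully degenerate cases.
* "Approximately the same size" is resolved as *first overshoot* sampling;
  other tolerance rules would shift realized sizes by fractions of one
  exon length.
* Protein ids must resolve to transcripts via the feature table or an id
  map; no remote lookups are performed anywhere.
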