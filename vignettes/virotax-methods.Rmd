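---
title: "Marker calibration and taxonomic voting for viral contigs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker calibration and taxonomic voting for viral contigs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virotax)
```

# Overview

`virotax` implements the analysis core of a marker-HMM viral annotation
workflow. Protein profile HMMs built from clusters of orthologous viral
proteins can act as taxonomic markers when their bit-score behaviour
separates one taxon from all others. The package covers the life cycle
of such markers: deciding which models are informative and at which
rank, calibrating their score cutoffs, summarising how densely each
taxon is covered by markers, triaging metagenomic contigs into
confidence classes, voting a taxonomic lineage per contig, and scoring
predictions against alignment-derived truth labels.

# The taxonomy model

The taxonomy is a rank-labelled parent-pointer tree over opaque taxon
ids, with exactly one root and ranks drawn from a vocabulary that
includes the four *working ranks* — genus, subfamily, family, order —
plus pass-through ranks (species, class, clades, `no-rank`). All
operations identify taxa by id; names are display-only, because names
collide and drift between taxonomy releases. Nodes with ranks outside
the vocabulary are retained as `no-rank` so NCBI-style trees load and
lineages simply skip them. Two input dialects are supported: the NCBI
`nodes.dmp`/`names.dmp` pair and a simplified 4-column lineage TSV; the
TSV is the canonical fixture format because it is diffable and requires
no downloads.

Real taxonomies evolve: markers calibrated against an older tree may
target ids that a later release has abolished. The package deliberately
does not guess a reconciliation; screening against a current valid-taxon
list is exposed as an ordinary subsetting of the markers table by a
user-supplied allow-list.

# Informative markers and threshold calibration

For one model's hit table (sequence, source taxid, full-sequence bit
score), the selection proceeds:

1. keep only each taxid's highest bit score;
2. group taxids by their ancestor at the current rank; each group's kept
   scores span a range `[low, high]`; taxids lacking an ancestor at the
   rank drop out of that rank's competition;
3. the model is informative at the rank iff a single taxon remains, or
   the best taxon's `low` strictly exceeds every other taxon's `high`.
   Ranks are tried genus → subfamily → family → order; failing all four
   leaves the model non-informative.

The *best* taxon is the one with the highest `high`; ties fall back to
the higher `low`, then the lexicographically smaller id. The tie-break
beyond "highest high" is a determinism choice of this package. Strict
inequality is used at exact equality of the best taxon's `low` and a
competitor's `high`: a shared boundary score is not separation.

`S1` is the best taxon's `low`, `S2` the maximum `high` over the other
taxa (absent when the model hit a single taxon). The six HMMER cutoffs
follow the displayed calibration formulas: per-sequence gathering and
trusted cutoffs equal `S1`; the per-domain cutoffs are `S1 - 3` unless
that trim would not stay strictly above `S2`, in which case they revert
to `S1`; the noise cutoff equals `S2` in both components and is omitted
when `S2` is absent. When `S2` is absent the 3-bit trim always applies
(there is no competitor to cross). We note that prose descriptions of
this construction can be read as trimming the per-sequence value
instead; we implement the formulas (trim the domain component only),
which keeps `GA_seq = TC_seq = S1` invariant everywhere.

Cutoffs are written into HMMER3 headers directly after the `CKSUM`
line in the native syntax (`GA    50.00 47.00;`), replacing any existing
cutoff lines, so the operation is idempotent and `hmmscan --cut_ga`
enforces the calibration without any post-processing.

# Taxon statistics and the TSR

Each annotated assembly contributes its CDS count to every working-rank
ancestor in its lineage; per taxon we keep the mean, the standard
deviation and the assembly count. Choices made where the procedure was
open:

* **Sample (n−1) standard deviation.** Per-taxon assembly counts are
  small; the sample form is the conventional estimator there. Taxa with
  a single assembly get `sd = 0` rather than `NA`, which keeps the
  CDS-count voting condition evaluable (it degenerates to
  `n_cds <= mean`).
* **Zero-CDS assemblies are excluded.** An assembly without annotated
  CDS is an annotation gap, not evidence of a zero-gene genome, and
  would deflate the means.

Marker counts are aggregated downward: a genus counts only its direct
markers, while subfamily/family/order taxa additionally count markers
linked to any descendant. The taxon-specific ratio is
`TSR = min(1, n_markers / mean_cds)`: the fraction of an average genome
of that taxon that our markers could possibly cover, capped at one.
Dense taxa therefore demand a high supporting-hit proportion, sparse
taxa a proportionally lower one.

# Contig triage

Evidence from three predictors is combined per contig after an
inclusive ≥ 1500 bp length filter (shorter contigs rarely carry enough
CDS for marker-based classification; virome surveys may raise the
cutoff, e.g. to 5 kb). Verdicts, with precedence HC > PP > LC:

* **HC** — VirSorter category 1 or 2 (whole-contig viral signal);
* **PP** — VirSorter prophage category 4 or 5, carrying the predicted
  region coordinates; category 6 is accepted only behind an explicit
  toggle;
* **LC** — VirFinder `p < 0.05` with `score >= 0.9`; or `score >= 0.7`
  corroborated by VirSorter category 3; or `score >= 0.7` corroborated
  by a PPR-Meta phage call. Score boundaries are inclusive and the
  p-value boundary exclusive, following the printed inequalities.
* **excluded** — no rule fires. Missing predictor output is
  non-reporting, never an error.

The precedence resolves multi-signal contigs to a single verdict (the
sets partition the input); the reported rule tag is the first satisfied
clause in the order above. Region coordinates are stored 0-based
half-open internally and converted from the 1-based inclusive predictor
convention at the parse boundary; excised prophages are named
`contig|prophage-start:end` so downstream CDS ids remain parseable.

# Gating and the voting classifier

Domain-table hits are gated per model: calibrated models require the
full-sequence score to reach `GA_seq` *and* the best domain score to
reach `GA_dom` (confidence `high`); known but uncalibrated models fall
back to a full-sequence E-value ≤ 1e-3 (confidence `low`); hits to
unknown models are dropped. Both confidence classes vote with equal
weight and are tallied separately in reports.

Each CDS keeps its single best hit (highest full-sequence score, then
highest domain score, then smallest model id). The denominator of the
voting proportion is the number of deduplicated informative hits on the
contig — per-CDS deduplication prevents multi-domain proteins from
voting repeatedly. The contig's total CDS count comes from the gene
caller output, not just the CDS with hits.

At each rank, finest first, every hit supports the ancestor of its
marker's taxon at that rank (a genus marker supports its family during
family voting); hits whose marker lineage lacks the rank support no
candidate but stay in the denominator. Candidates are tried in
decreasing proportion (ties: higher TSR, then smaller id) and the first
one passing both conditions wins:

1. `proportion >= factor * TSR(candidate)` with `factor = 0.6` by
   default;
2. `n_cds <= mean_cds + 2 * sd_cds` — a contig should not carry
   substantially more genes than the candidate taxon's average genome.

Candidates without statistics receive `TSR = 1` and a waived CDS
condition, with a warning: maximal stringency on the proportion rather
than silent exclusion. Exhausting all four ranks leaves the contig
unclassified. Because raising `factor` only shrinks the set of
acceptable candidates at every rank, the deciding rank is monotone:
a larger factor can only coarsen or lose a classification, never refine
it — this property is asserted in the acceptance suite.

# Benchmarking

Contigs are truth-labelled from `show-coords`-style alignment tables:
a contig is viral when the merged union of its alignments at identity
≥ 90% covers ≥ 70% of its length, both boundaries inclusive. The union
(rather than the single best alignment) is the default because contigs
spanning repeats align piecewise; a `mode = "best"` switch provides the
stricter reading. Alignment coordinates are normalized to 0-based
half-open forward intervals at parse time, which makes the union a
plain interval merge (delegated to `IRanges::reduce`). A
putative-prophage call counts its host contig as predicted viral, since
benchmark tallies are per whole contig. Precision, recall and F1 follow
the standard definitions, with undefined ratios reported as `NA` rather
than zero.

# The synthetic world

The generators produce every consumed format with planted ground truth,
under a single integer seed (the global RNG state is saved and
restored). Defaults state a desk-scale world:

* a balanced taxonomy of 2 orders / 4 families / 2 subfamilies /
  8 genera / 3 species per genus;
* 3 models per genus, with per-model score gaps drawn uniformly in
  `[1.5, 9.5]` bits between the target taxon's scores and the best
  off-target score — so both branches of the 3-bit trim guard occur;
* genus-characteristic genome sizes of 15–80 CDS with ~12% scatter,
  3 assemblies per species, ~1 CDS per kb on contigs;
* 60% of the planted marker-bearing CDS per viral entity, 20%
  cross-genus hit noise, and error-free predictor tables.

Viral entities draw their CDS count inside `mean ± 2·sd` of the source
genus's *realized* statistics, which makes the planted lineage
recoverable by construction in the noiseless case — that is the point
of a planted-truth fixture: a green end-to-end test certifies that the
implementation inverts the generator exactly, not that real data are
this clean. What the generator does **not** emulate: sequence
composition (contigs are uniform random nucleotides; nothing downstream
inspects composition), emission-realistic HMM scores, assembly
artefacts, chimeras, or taxonomically ambiguous homology. Green tests
therefore establish algorithmic correctness and calibrated behaviour
under stated noise, not field accuracy.

Prophage fixtures place the viral region inside a longer host contig
and attach CDS and hits to the excised region entity, mirroring how the
triage step hands excised regions to annotation.

# Numerical choices and degenerate inputs

* Score comparisons at gates are inclusive (`>=`); separation and the
  trim guard are strict (`>`), as printed.
* `TSR` is undefined for zero markers or non-positive mean CDS; such
  taxa are flagged at voting time rather than failing statistics
  generation.
* Empty inputs return empty, correctly-typed tables; an empty hit list
  makes a model non-informative; a contig without informative hits is
  unclassified.
* Ties everywhere break deterministically (documented above), so equal
  inputs give byte-equal outputs.

# Known limitations

* The classifier trusts the marker table's taxa; it does not detect
  markers calibrated against an outdated taxonomy (see the allow-list
  note above).
* Only VirSorter-style, VirFinder-style and PPR-Meta-style evidence
  tables are parsed; other predictors must be mapped to one of these
  conventions by the caller.
* The benchmark's prophage handling labels whole host contigs; it does
  not score region-boundary accuracy.
* `--cut_ga` gating is reproduced in post-processing; the package never
  executes hmmscan itself.
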