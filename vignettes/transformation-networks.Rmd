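---
title: "Transformation-product networks: model, naming rules, and filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformation-product networks: model, naming rules, and filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpnet)
```

## The graph model

Transformation data is inherently path-like: a parent compound degrades
or is metabolized into successors, which degrade further. `tpnet`
therefore models a compound table and a reaction table as a **directed
multigraph**: one node per compound (keyed by its integer CID, which
must be unique), one edge per reaction row, pointing from predecessor
to successor.

Three modelling commitments matter:

- **Parallel edges are data, not duplicates.** The same predecessor →
  successor pair reported by two datasets, in two biosystems, or with
  two enzymes, becomes two edges. Each keeps its full provenance
  payload and a stable `edge_id` assigned by input row order, so
  reports are reproducible and individual reactions addressable.
  Deduplication, where wanted, happens at query time (e.g. distinct
  partner counts), never at load time.
- **Nothing is dropped silently.** Reactions referencing CIDs absent
  from the compound table are quarantined into a dangling-edge list
  and surfaced by `validate_graph()`; self-loops are retained and
  flagged; compounds appearing in no reaction become isolated nodes
  and are flagged. The source data is never modified.
- **Validation is a report, not a gate.** `validate_graph()` checks
  node/edge counts against expected values, endpoint connectivity, the
  role-partition identity (the four role classes must partition the
  node set), and agreement between each reaction's recorded mass
  difference and the difference of its endpoint masses (0.01 Da
  tolerance — generous enough for rounding in source files, tight
  enough to catch swapped endpoints). Strict failure is an option of
  the ingest command, not of the library.

## Majority-vote display naming

Aggregated sources name the same compound many ways. For display, one
name per compound is selected from all candidates — the compound
table's IUPAC name and title plus every cleaned predecessor/successor
mention in the reaction rows — by sorting on:

1. **frequency of mention**, descending (the "majority vote");
2. **character length**, ascending (prefer "6:2 FTOH" over its
   13-locant systematic equivalent when frequencies tie);
3. **lexicographic order**, ascending (a pure determinism tie-break).

The ordering of the first two criteria is a genuine design choice:
"majority vote" names the method, so frequency leads; length breaks
ties in favour of short, recognizable names. The third criterion
guarantees that the selection is a deterministic, order-independent
function of the candidate multiset — permuting input rows can never
change a display name, which the test suite checks exhaustively over
permutations.

Names that would be unreadable in a network display — longer than 100
characters, or containing more than 20 *special characters* — are
replaced by `CID <n>`. "Special character" is defined here as any
character that is not an ASCII letter, digit or space. This class is
deliberately broad (hyphens, commas, colons and brackets all count):
heavily punctuated systematic names are exactly the ones the rule
should catch, and the definition is trivially testable. Both
thresholds are strict (`>`), so a 100-character name and a 20-special
name survive; the replacement string itself is short and
special-character-free, so the rule is stable under re-application.
All candidate names are retained for search regardless of what is
displayed.

Text cleaning (applied before tallying) trims outer whitespace,
collapses internal runs to single spaces, and normalizes Unicode to
the composed form (NFC) so visually identical strings from different
sources compare equal. Cleaning is idempotent and total.

## The display filter (60 / 300 Da)

Some biological reactions correctly report very small molecules
(carbon dioxide, 44 Da; formaldehyde, 30 Da; acetate, 59 Da) as
precursors of much larger products such as coenzymes. In a pathway
display these edges act as hubs that weld unrelated data islands
together and manufacture absurd "shortest pathways" through CO2. The
display filter hides an edge when

> predecessor mass **<** `small_mass_max` (default 60 Da) **and**
> successor mass **>** `large_mass_min` (default 300 Da).

Both inequalities are strict, so a compound of exactly 60 Da is never
a "small" precursor and a 300 Da product is never "large". The lower
default keeps environmentally relevant small molecules such as
triazole (69 Da) visible; the upper default is the smallest round
value that catches the problematic hub reactions in the compiled data.
Edges with either endpoint mass missing are never hidden — hiding on
absent evidence would be worse than showing a noisy edge. The filter
applies to pathway search and all compound views; `hidden_edges()`
always reports the hidden set (it probes with the thresholds even when
display filtering is disabled), and `edge_filter(enabled = FALSE)`
bypasses it entirely. The data itself is untouched.

## Pathway and neighborhood semantics

`shortest_pathways()` counts **reaction steps**, all steps weighted
equally. Parallel edges collapse to one step — they are alternative
evidence for the same hop, and each hop in a returned path carries all
of its parallel edge ids. Every distinct minimal *node sequence* is
returned (paths through different parallel edges are not counted as
distinct pathways); enumeration is delegated to igraph's all-shortest-
paths machinery on the filtered, collapsed graph, and the test suite
proves it equivalent to brute-force enumeration of all minimal simple
directed paths on hundreds of random graphs. Conventions for the
degenerate cases: `source == target` yields one zero-length path
(flagged by its length, harmless and explicit); an unreachable target
yields an empty path list with length `NA`.

The four compound views are traversals of the visible graph: `direct`
(distance-1 neighbors in either direction, plus only the focus's own
incident edges), `predecessor_path` / `successor_path` (directed
closures, depth-limited), and `all_connections` (the full weakly
connected component, ignoring the depth limit). The default depth
limit of 10 steps is configurable; published degradation cascades
rarely exceed a handful of steps, so 10 is effectively "everything"
while still bounding pathological traversals.

## Statistics definitions

- **Roles** partition nodes by in/out degree: `predecessor_only`
  (out ≥ 1, in = 0), `successor_only` (in ≥ 1, out = 0), `both`,
  `isolated`.
- **"Direct TPs" and "direct predecessors"** count *distinct* partner
  CIDs, not edges: a compound reported three times as forming the same
  product has one direct TP.
- **Per-dataset uniqueness**: a directed CID pair is unique to a
  dataset iff it occurs in no other dataset; `total_entries` counts
  raw rows (so within-dataset repeats inflate the denominator but not
  the numerator), and `unique_pct` is rounded to one decimal. This
  pairing of definitions reproduces the published per-dataset
  percentages exactly where they can be cross-checked.
- **Mass-difference bins** group `mass_diff` after rounding to 3
  decimals (configurable). Monoisotopic shifts of common reactions
  (+15.995 oxygen addition, +176.032 glucuronidation, −14.016
  demethylation) are separated cleanly at that precision while source
  rounding noise below a millidalton collapses into one bin.
- **Multistep statistics**: an *original predecessor* is a node with
  visible in-degree 0. For every other node the minimum directed
  distance from any original predecessor is computed (one multi-source
  BFS via a virtual super-source); nodes at distance ≥ 2 are the
  multistep compounds. For each, the *dataset span* is the number of
  distinct dataset references on the edges of its entire visible
  ancestor subgraph — not only on shortest paths — because every
  ancestor edge is part of some pathway into the compound; this is
  also the cheapest definition that is monotone in the data. Both
  statistics are computed on the filtered graph, consistent with what
  pathway displays show. These two choices (ancestor-subgraph span,
  filtered graph) are the documented ambiguity in the corresponding
  published figures.

## Substructure search

SMARTS matching runs over structures parsed from the SMILES column
(InChI is not used for matching) through Open Babel via ChemmineOB.
All patterns are validated before any matching begins, so a batch
never half-runs on a broken query set; within a batch file, invalid
lines are reported while valid lines still run, and each line's result
is provably identical to the corresponding single-pattern query.
Compounds whose SMILES fail to parse are skipped per compound with a
report — aggregated community data contains oddities, and one broken
structure should not kill a screen. No fingerprint prescreening is
used: at the scale of compiled TP collections (~10^4 compounds),
direct matching is already interactive.

## The synthetic-data generator

`generate_fixture()` realizes a `fixture_spec()` into schema-exact
tables built from a fixed pool of 20 hand-checked structures whose
monoisotopic masses were verified with Open Babel, spanning the three
mass regimes the display filter distinguishes (below 60 Da, 60–300 Da,
above 300 Da) and known substructure classes (aromatic rings,
CF3 groups). Generated tables contain, by construction: a probe chain
and a two-route diamond with recorded shortest-path lengths; optional
hub compounds with requested distinct degrees; cross-dataset duplicate
pairs at a configurable rate; name-spelling variants at a configurable
rate; and a configurable number of injected small → large edges — the
display filter's targets. Default conditions are 60 compounds, ~120
base reactions across 3 datasets, a 10% duplicate-pair rate, a 30%
name-variant rate and 2 injected filter-target edges: large enough
that every role class, parallel edges and multistep pathways all occur,
small enough that brute-force oracles stay instant.

Every ledger claim is recomputed by the corresponding module in the
test suite; crucially, the ledger is produced by plain tallies and a
hand-rolled BFS at construction time, independent of the igraph-backed
implementation it is used to check. Generation is a pure function of
the spec (fixed RNG kind, seed isolation from the caller's RNG state),
so the same seed yields byte-identical CSV files.

What the generator does **not** emulate: realistic reaction chemistry
(mass differences arise from whichever pool structures are joined, not
from plausible transformations), realistic name distributions, and the
heavy-tailed degree distribution of real compiled data. Passing tests
therefore demonstrate contract correctness — counting, traversal,
filtering, naming, serialization — not chemical plausibility of any
particular network.

## Numerical and interface choices

- CSV dialect: UTF-8, comma-separated, double-quote quoting, header
  row required. The literal source header spellings for the CID and
  name columns vary between deposits; the readers match headers
  case- and punctuation-insensitively against documented defaults, and
  a `column_map` argument overrides them when a deposit differs.
- XLSX export mirrors the generic CSV schema and is serialized through
  Python's openpyxl (the workbook format is out of scope for the R
  dependency set); all analytical outputs are plain CSV/JSON.
- Graph caching uses a node-link JSON document; a round-trip through
  `write_graph_json()` / `read_graph_json()` reproduces the graph
  exactly, including edge ids, and ingest output is byte-deterministic
  across reruns.
- Problem sizes in the test suite: property checks run on random
  graphs of up to 12 nodes (where exhaustive path enumeration is
  exact) over several hundred seeded trials, and on generated tables
  of 14–60 compounds; the acceptance script uses the generator's
  default conditions.

## Known limitations

- Name/SMILES → CID resolution is out of scope: contribution templates
  load with unresolved CIDs flagged, and linking them into the graph
  requires an external identifier-mapping step.
- The graph is in-memory; there is no server-backed storage or
  transactional update path. At the scale of current compiled TP
  collections this is comfortable; orders of magnitude beyond it would
  need a different backend behind the same contracts.
- Biosystem vocabulary is taken verbatim from the sources; no ontology
  mapping ("human" vs "Homo sapiens") is attempted.
- The headline counts of any given compiled release can only be
  verified when that release's CSVs are locally available; the test
  suite checks them when pointed at a copy (`TPNET_SOURCE_DIR`) and
  reports the property-based guarantees otherwise.
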