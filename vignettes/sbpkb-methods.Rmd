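---
title: "Building and querying a standard-parts knowledgebase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying a standard-parts knowledgebase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpkb)
```

## The data model

A parts registry export arrives as two relational tables: a **parts** table
(one row per catalogued DNA part: identity, free-text descriptions, curation
status, hierarchical category tags, and the nucleotide sequence) and a
**sequence features** table (one row per positioned region on a part's
sequence: label, type, 1-based inclusive start/end, strand). `sbpkb`
transforms these into a statement-based knowledge graph — subject, predicate,
object triples — because the questions a designer asks are joins across
record boundaries that a wiki-style catalog cannot answer mechanically.

Three modelling decisions shape the graph.

**Categories become classes.** The registry's category vocabulary is a set of
path-style tags organised as a hierarchy (e.g.
`//rnap/prokaryote/ecoli/sigma70` under `//rnap/prokaryote/ecoli`, …, under
`//rnap`). Each path is converted to an OWL class named by its segments in
reverse order joined by underscores — `sigma70_ecoli_prokaryote_rnap`,
`ecoli_prokaryote_chassis`, `forward_direction`, `positive_regulation` — and
declared a subclass of its parent path's class. The generated classes live in
a dedicated `partsregistry` namespace (`pr:`), separate from the core
`sbolcore:` model, to attribute them to their source. Category roots attach
to a neutral `sbolcore:RegistryCategory` anchor rather than to `Part`: a root
such as `chassis` is not a kind of part, and the anchor keeps the generated
forest connected to the core model without asserting false is-a semantics.
This vocabulary is deliberately *not* a formal ontology — it mirrors the
catalog's organisation, is useful for retrieval, and makes no description-
logic commitments (no restrictions, no disjointness).

Because segment underscores are preserved, two distinct paths can reverse to
the same class name (`//a_b` vs `//b/a`); `emit_class_axioms()` detects the
collision and raises rather than silently merging classes.

**Membership is materialized.** A part tagged only
`//promoter/constitutive` must still be found by a query for promoters.
Rather than requiring an RDFS-inference-capable query endpoint, the
transformer asserts each part's ancestor category classes as explicit
`rdf:type` statements (default `materialize = TRUE`). This reproduces
subclass-closure query semantics with a plain pattern-matching engine, at the
cost of extra type statements; `materialize = FALSE` is available when the
asserted-only view is wanted (for instance when displaying a record exactly
as catalogued). The statement set with materialization on is always a
superset of the set with it off.

**Identifiers are minted deterministically.** Individuals need opaque local
names. `mint_id()` digests `kind|registry_id|name` (SHA-1, truncated, base62)
and appends the registry id digits, so the same input record always yields
the same resource across rebuilds — serialized graphs diff cleanly — while
distinct records get distinct names (guarded against collision at build
time).

## Literal conventions

Positions, registry ids and owner ids are typed integers; everything else is
a plain string. Dates are stored verbatim as printed (`9/11/2007`): no
arithmetic is ever performed on them and locale-guessing would corrupt data.
Statuses are normalized case-insensitively onto {Available, Sent, Deleted,
Planning, Unavailable}; unrecognized tokens map to `Other` with the raw value
preserved, so dirty data is surfaced, never dropped. Empty-valued properties
are omitted entirely rather than asserted as empty strings — the cleaning
queries test for the *presence* of `dnaSequence`, and presence semantics is
kept uniform across all properties (a part's `name` is mandatory and always
present).

## The query layer

The engine implements the SPARQL fragment the workflow needs: `PREFIX`,
`SELECT [DISTINCT]`, basic graph patterns, and `FILTER` with `=`, `!=`,
`IN`, `NOT IN`, `!`, `&&`, `||`. There is no entailment at query time (see
materialization above) and no `OPTIONAL`/`UNION`/property paths — a
malformed or unsupported query fails loudly with a character position.
Evaluation is relational: each triple pattern is matched against the
statement table, bindings join on shared variables, filters apply to the
joined table, then projection and `DISTINCT`.

The named query bank encodes a refinement sequence:

1. `q_parts_by_class(g, "promoter")` — every part typed (directly or via a
   subcategory) as a promoter.
2. `q_describe_class()` — all statements about those parts; the exploration
   step in which one discovers, e.g., that `status` exists and that some
   records lack sequences.
3. `q_clean_parts()` — members with a `dnaSequence` property whose status is
   not `Deleted`.
4. `q_by_status()` — e.g. parts physically obtainable (`Available`, `Sent`).
5. `q_conjunctive_classes()` — parts in *all* of several classes: promoter ∧
   `sigma70_ecoli_prokaryote_rnap` for σ70-dependent promoters, or promoter ∧
   `positive_regulation` ∧ `negative_regulation` for the dual-regulated
   promoters a relaxation-oscillator design needs. The σ70 class is treated
   as an independent category axis conjoined with promoter, not as a
   promoter subclass — the vocabulary tags them independently.
6. `q_dual_regulated_with_features()` — the final narrowing: dual-regulated
   promoters that additionally possess an annotation→feature chain, i.e.
   known operator sites, returned as (part, name, description, author,
   feature label) rows.

Every query is `DISTINCT` over the part variable, so a part can never be
counted twice. Each refinement can only narrow or restructure the result:
clean ⊆ all, each conjunction ⊆ each conjunct, feature-restricted ⊆
dual-regulated.

The describe operation defaults to a symmetric bounded description (statements
in which the resource is subject or object); `mode = "forward"` gives the
outgoing-only view used when reproducing a record as catalogued.

## Serialization

Graphs serialize to Turtle and RDF/XML with the prefixes `sbolcore`, `pr`,
`rdf`, `rdfs`, `owl`, `xsd` declared in every file. The Turtle writer emits
one triple per line in canonical (sorted) order, so equal graphs produce
byte-identical files — convenient for diffing and a cheap determinism check.
Both formats parse back to exactly the original statement set; the test
suite additionally has an independent RDF stack (Python `rdflib`) parse both
serializations and confirm triple counts, cross-format isomorphism, and the
part count.

## Synthetic fixtures: what they emulate and what they do not

`generate_fixture()` emits registry-shaped tables with controlled structure:

- **Categories** are drawn independently per part from a weight table over
  realistic leaf paths (promoter and a promoter subcategory, both regulation
  polarities, the σ70 machinery path, an *E. coli* chassis path, direction,
  and several non-regulatory top-level categories). A part drawing nothing
  receives the highest-weight path, so every part is categorized. Only leaf
  paths are assigned; ancestors appear downstream through materialization.
- **Statuses** follow Available .30 / Sent .08 / Planning .40 /
  Unavailable .18 / Deleted .04, and 6% of parts lack a sequence — chosen to
  mirror the catalogued proportions the knowledgebase is meant for (roughly
  38% of parts obtainable as clones, roughly 90% clean), and fixed once.
- **Sequences** are uniform random over {a,c,g,t}, 40–400 nt; **features**
  (Poisson mean 0.6 per sequenced part) are placed within sequence bounds
  with labels drawn from a pool of operator-site names.

Alongside the tables the generator writes a **manifest** — the per-part
ground truth (categories, status, sequence presence, feature labels). The
test suite's oracles are brute-force filters over this manifest, written
without any RDF machinery, so a SPARQL answer and an R-level record filter
must agree for every named query at every seed tested; that agreement, not
any fixed count, is the fixture suite's acceptance surface.

The worked-example fixture (`inpaper_fixture()`) is deterministic: one fully
described promoter part (all ten literal properties, five category classes,
a 92-nt sequence) and six dual-regulated promoter parts whose names,
descriptions, authors and operator-site labels are fixed. Their registry ids
derive from the digits of their names; sequences and feature coordinates are
not part of the encoded record set, so they are synthesized from the seed
and kept in bounds. Optional distractor parts are promoters that lack at
least one regulation class (or carry no features) built from the same
vocabulary — they can inflate intermediate result sets but provably never
enter the final dual-regulated-with-features result, which the tests assert
for several distractor counts.

What the generator does **not** emulate: the true catalog's size (tens of
thousands of parts), its empirical category frequency distribution (unknown),
wiki free-text, multi-author edit histories, or cross-part composition links.
Passing tests therefore demonstrate correctness of the transformation and
query semantics under realistic structure, not performance or recall on any
particular registry snapshot; absolute result counts on such a snapshot are
out of reach without the snapshot itself.

## Numerical and procedural choices

- Table parsing is strict: a row with the wrong column count fails naming
  the line; duplicate registry ids fail at read time; sequences outside
  {a,c,g,t} (after lower-casing) fail rather than being silently cleaned.
  Validation (`validate_records()`) is the reporting counterpart: orphan
  features, missing sequences, duplicate ids, nonstandard statuses.
- A feature extending beyond its part's sequence draws a warning but is
  still transformed — registry-like data is imperfect, and exclusion is the
  job of explicit cleaning queries, not of the loader. Transformation is
  strict by default (`--lenient` at the CLI switches unknown categories and
  orphan features to warn-and-continue).
- Test and example problem sizes — 500-part fixtures, 20 seeds for the
  oracle-equivalence sweep, a 10,000-draw id-uniqueness sweep — were chosen
  to populate every stratum (dual-regulated promoters with features are a
  ~1–2% stratum) while keeping the full suite fast on a single CPU.
- The CLI is a thin dispatcher (`sbpkb_main()`, installed as `exec/sbpkb`)
  over exported functions; `fixgen → transform → query` with fixed seeds is
  byte-reproducible end to end.

## Known limitations

- The SPARQL fragment is exactly the workflow's: no OPTIONAL means the
  feature-restricted query *requires* name/description/author to be present
  (the fixtures always emit them; real exports that omit them would need the
  raw-SPARQL route with a relaxed pattern).
- No OWL reasoning: consistency checking or classification over the
  generated classes would need a DL reasoner and a formalized vocabulary.
- Sub-part composition (a composite part whose segments are themselves
  parts) is represented only through the annotation/feature mapping; segments
  are not typed as parts.
- Turtle parsing covers the canonical single-triple-per-line form this
  package writes (plus comments and blank lines), not the full Turtle
  grammar; RDF/XML parsing likewise targets the description-per-subject
  shape the writer produces.
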