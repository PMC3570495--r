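---
title: "Models and methods behind phenoassert"
author: "phenoassert authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenoassert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoassert)
```

# The inference model

`phenoassert` treats genome interpretation as three stacked layers of
evidence, each with its own degree of confidence.

**Terms.** A functional term is the unit a gene can be assigned to: a
protein product, a modified protein, or a protein complex. In a given
genome a term has one of three statuses: *present* (a gene carries it with
manual or propagated provenance), *candidate-only* (only weaker BBH-based
evidence exists), or *absent*. These map to the truth values true /
unknown / false.

**Reactions and pathways.** A reaction requires one of several
alternative term sets; within a set all terms (e.g. the subunits of a
complex) are needed. A pathway is an ordered list of steps, each a set of
alternative reactions. The pathway formula is therefore an AND (over
steps) of ORs (over reactions) of ANDs (over subunit terms) of ORs (over
requirement alternatives) — a monotone formula with no negation.
Evaluating it under the strong-Kleene connectives yields the assertion
status: true → *asserted*, unknown → *unknown*, false → *not asserted*.

**Phenotype rules.** Traits are boolean AND/OR/NOT expressions over
pathway identifiers, evaluated with the same connectives after mapping
statuses to truth values (asserted = true, not asserted = false, unknown
= unknown; the manual status *absent* maps to false). A rule that
evaluates true is *predicted*, false *not predicted*, unknown *unknown*.

## Why Kleene semantics, and what "unknown" commits to

For the monotone pathway formula, strong-Kleene evaluation coincides with
the completion semantics: the status is *asserted* iff every way of
resolving the candidate-only terms to present/absent satisfies the
formula, *not asserted* iff none does, and *unknown* otherwise. (This
equivalence holds because each term status feeds the formula positively;
the test suite checks it against a brute-force enumeration oracle.) A
consequence worth spelling out: for a pathway to be *unknown*, every term
that remains indispensable on all satisfying paths must have at least a
candidate gene. One could imagine a looser reading in which a single
candidate anywhere suffices; we deliberately do not offer that mode — two
silently different notions of "unknown" in one tool invite
misinterpretation.

For phenotype rules, which do contain negation, Kleene and completion
semantics still agree as long as no pathway identifier occurs twice in
one rule; all shipped rules have this form. Exposing the third verdict
(*unknown*) rather than collapsing it into "not predicted" is a design
choice: hiding it would discard exactly the information the three-valued
pathway status was built to preserve, and it is what makes the tool safe
on partial genomes (drafts, single-cell assemblies, bins).

## Rule grammar

Keywords `AND`, `OR`, `NOT` are case-insensitive; identifiers
(`[A-Za-z0-9_.]+`) are case-sensitive. Precedence is the conventional
`NOT > AND > OR`, binary operators left-associative. Published rule sets
in this domain are written fully parenthesised, so no precedence
convention is forced by the source material; we adopt the one every
boolean grammar uses. Serialising an AST and re-parsing it reproduces the
tree exactly (a tested property).

# Evidence thresholds

Term propagation (`propagationParams()`):

| parameter | default | meaning |
|---|---|---|
| `minHomologs` | 5 | qualifying homologs required before the vote |
| `minIdentityPct` | 50 | percent identity, exclusive |
| `minCoverageFrac` | 0.70 | aligned fraction of *both* proteins, exclusive |
| `minSupporting` | 2 | term-bearing homologs among the top `minHomologs` |

Candidate detection (`candidateParams()`): top `topK = 5` BBH partners,
`minSupporting = 2` bearers, coverage > 0.70 both sides, best bearer
identity > 25 %.

Three readings deserve justification:

* **All inequalities are strict.** The procedure is stated with ">"
  throughout, so boundary equality (exactly 50 % identity, exactly 0.70
  coverage) never satisfies a criterion. The acceptance sweeps verify the
  breakpoints sit exactly at 50 / 70 / 25.
* **Support is counted among the top `minHomologs` homologs**, ranked by
  identity, then score, then gene id — not among all qualifying homologs.
  This mirrors the "top 5 BBH" framing of the candidate rule and keeps
  the vote independent of how deep the hit table happens to be.
* **Ties break deterministically** (identity desc, score desc, id asc for
  homolog ranking; score desc, identity desc, id asc for "best hit" in
  BBH). Output is therefore invariant under permutation of input rows, a
  tested property.

When several terms reach the support threshold for one gene, all are
assigned (multi-term genes are legitimate) and a warning names the gene;
we do not guess a resolution order. Propagation is single-round by
default; `iterate = TRUE` repeats to a fixpoint (capped at 10 rounds) for
users who want newly propagated genes to vote in later rounds.
Candidates are computed per (gene, term): a gene may carry one term and
still be a candidate for another; a candidate is never emitted for a
(gene, term) pair that already has a manual or propagated assignment.

# Consistency reports

A gene's family *combination* is the triple of its full per-namespace id
sets (COG set, Pfam set, TIGRfam set), compared set-wise. Using sets —
rather than one row per domain — is the only reading under which a KO
spanning one COG and two Pfams can produce four distinct combinations,
which is the canonical worked structure for these reports. Combination
details are query-anchored: combinations are enumerated from the genes
carrying the query KO, and the four per-combination counts classify every
gene sharing that combination (query KO; some other KO, inclusive;
another KO but not the query; no KO). The suite checks the conservation
identity `first + third + fourth = carriers` and equality with a naive
quadruple-loop recount on random stores.

## MCL

No installed R package provides the Markov Cluster Algorithm, so it is
implemented here directly as the standard dense iteration: add
self-loops, column-normalise, then alternate expansion (matrix square)
and inflation (entry-wise power, default exponent 2, then column
renormalisation) until the largest entry change falls below `tol = 1e-6`
or 100 iterations. Numerical choices: self-loop weight equals the node's
maximum incident edge weight (a common heuristic that damps immediate
re-dispersal; isolated nodes get 1), entries below `1e-9` are pruned
between iterations, and clusters are read off as connected components of
the limit matrix's non-zero structure. Non-convergence raises a warning
but still interprets the current state. Paralog clusters keep only
clusters of size ≥ 2 — a singleton defines no paralog. Edge filters for
the paralog graph (identity > 30 %, coverage > 0.70) are exposed as
arguments because no published threshold exists for this step; the
defaults are ordinary working values for within-genome homology and are
deliberately looser on identity than term propagation, since clustering
claims less than annotation transfer.

# What the fixture generator emulates — and what it does not

`generateFixture()` produces eight designed genomes plus optional
unannotated padding. The design covers: all three computed statuses and
both manual overrides; a term delivered only by propagation (five
homologs at 55–95 % identity, three bearing the term); candidate-only
terms backed by two cross-genome BBH partners at 30–45 % identity (above
the 25 % candidate floor, below the 50 % propagation floor); all four
OR-branches of the cellulose-utilisation rule on four distinct genomes;
prototroph/auxotroph pairs for histidine, phenylalanine and lysine;
metadata rows that exercise agree, conflict, no-metadata and the synonym
map; a KO spanning four family combinations; planted within-genome
paralog pairs at ~80 % identity; and decoy hits at ≤ 25 % identity that
must trigger nothing. Similarities are sampled directly — no sequences
exist — because no stage consumes residues.

Passing the end-to-end tests on this fixture demonstrates that the
machinery implements its stated rules exactly; it does *not* demonstrate
performance on real data, where hit tables are noisy and enormous,
annotation families overlap messily, thresholds trade precision against
recall, and metadata vocabularies are far dirtier than a two-entry
synonym map. The fixture is a correctness instrument, not a benchmark.

Determinism is a contract: identical configuration and seed give
byte-identical files (all tables are written sorted; every random draw
flows from the single seed).

# Degenerate inputs and edge conventions

* Empty AND folds to true, empty OR to false (standard identities); the
  DSL forbids empty requirement sets and empty steps outright.
* Self-hits are dropped on hit-table construction; duplicate ordered
  pairs keep the highest score.
* A pathway step's evaluation is order-independent; step order is kept
  for display only.
* Profile gene counts count distinct genes, not (gene, term) pairs.
* Paralog pair identity uses the higher of the two directed hit records;
  a clustered pair with no hit record is skipped with a warning rather
  than silently zeroed.
* In lenient rule evaluation, unmapped pathway ids evaluate to unknown
  and are reported via the result's `missing` attribute; strict mode
  (the default) errors.

# Problem sizes

The shipped tests run the logic oracle on 1,000 random expressions of up
to 10 variables, the report oracle on 50 random stores of up to 200
genes, MCL order-invariance on 20 random graphs, and the full pipeline on
the 8-genome default fixture; together they complete in well under a
minute. These sizes were chosen as the smallest at which every code path
and every boundary is exercised with comfortable margin.

# Known limitations

* No sequence-level computation: alignments, HMM scans and similarity
  search are upstream inputs, taken as given.
* Reaction directionality, stoichiometry and compound identity are not
  modelled; a reaction is only a requirement structure over terms.
* The shipped rule catalog contains the classic worked rules (histidine,
  phenylalanine, lysine, cellulose via cellobiose, aerobe), not a
  comprehensive phenotype library.
* Metadata agreement checking is string matching with a small synonym
  table; ontology-backed normalisation is out of scope.
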