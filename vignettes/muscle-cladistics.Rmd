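---
title: "Parsimony analysis of muscle characters: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony analysis of muscle characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoclad)
```

## The problem

Comparative myology codes the gross morphology of striated muscles —
presence or absence of a muscle ("major" characters), and details of
attachments, bellies, tendons, and fusions ("minor" characters) — as
unordered discrete states across a set of terminal taxa, here hominoid
primates. Three questions drive the package:

1. **Coding**: how do specimen-level dissection records become one coded
   state per taxon?
2. **Inference**: which tree, and which placement of character changes on
   its branches, minimises the number of evolutionary changes (maximum
   parsimony), and how ambiguous is that placement?
3. **Tempo**: given calibrated node ages, how fast has each lineage changed,
   in characters per million years (Ma)?

The motivating data set — muscle characters across hominoids, with bonobos
(*Pan paniscus*) dissected specimen by specimen — is small by design: a
handful of terminals, one to two hundred characters. That makes *exact*
methods practical everywhere: exhaustive topology enumeration or
branch and bound for the tree, full enumeration of most-parsimonious
reconstructions (MPRs) for the ancestral states. The package never
approximates.

## Majority-rule coding

A state is coded for a taxon when it occurs in **at least half** of the
counted units (`code_majority()`). The threshold is inclusive: presence in
exactly 5 of 10 specimens codes as present. Two counting units are offered
because anatomical sample sizes are quoted both ways:

* `unit = "specimen"` (default): each dissected individual contributes
  weight 1. A bilaterally asymmetric specimen (muscle present on one side
  only) splits its weight 0.5/0.5 between the two conditions — a declared
  convention of this package; source reports rarely state how such
  specimens were weighted.
* `unit = "side"`: each side-specific record is one unit, matching sample
  sizes quoted as "cases" (two per specimen when both sides were examined).

Multistate characters code by the modal state; exact ties code as a
polymorphic state set rather than an arbitrary winner, because the
parsimony machinery handles polymorphic terminals natively. Own dissections
and literature records pool by specimen union (`merge_specimen_sources()`),
and conflicting records for the same specimen are an error, never silently
merged.

## Characters, cells, and missing data

A `char_matrix` stores, per cell, a non-empty set of integer states 0–9, or
`?` (missing), or `-` (inapplicable — e.g. an attachment character for a
taxon lacking the muscle). State 0 is by convention the ancestral
(plesiomorphic) condition, anchored by the outgroup. In all parsimony
computations missing and inapplicable cells are full-domain wildcards: they
can never force a step. They differ only in reporting. NEXUS files use the
standard `MISSING=?`/`GAP=-` declarations with `{}` polymorphism; the CSV
dialect uses `/`-separated polymorphism. Character kind (major/minor) and
body region (HN/FL/HL/trunk) ride along in the NEXUS character labels so
files round-trip completely.

## Parsimony: scoring, indices, search

All characters are **unordered** (Fitch) and equally weighted — the
published convention of the antecedent studies this data style comes from;
no ordering assumptions are imposed anywhere, and there are no step
matrices (out of scope).

Two exact scorers agree everywhere and are cross-checked in the tests:
a vectorised Fitch set engine on state bitmasks (binary trees, all
characters in one postorder pass), and a unit-cost Sankoff dynamic program
(per character) that is also exact on polytomies and is the basis for MPR
enumeration.

Per character, the homoplasy bookkeeping uses

* $m_i$: fewest changes on *any* tree. With polymorphic cells this is
  computed as (minimum hitting-set size over per-tip state choices) − 1,
  which collapses to "observed states − 1" when every cell is a singleton.
  The naive formula would violate $m_i \le s_i$ for a polymorphic tip that
  can collapse onto a common state.
* $s_i$: observed steps on the tree under evaluation.
* $g_i$: steps on a star tree = scorable tips − the largest count
  achievable by one state (polymorphic tips counted toward their most
  favourable state).

Ensemble indices: $CI = \sum m_i / \sum s_i$ and
$RI = (\sum g_i - \sum s_i) / (\sum g_i - \sum m_i)$, the latter over
parsimony-informative characters only (uninformative ones contribute equal
amounts to numerator and denominator). Whether uninformative characters
enter the CI sums is configurable (`include_uninformative`, default `TRUE`,
the PAUP* convention) because published CI values do not always state their
convention. Percentages print as integers rounded half away from zero; full
precision is retained. A zero-length tree makes CI formally undefined; it
is reported as 100 with an explicit `ci_defined = FALSE` flag.

`branch_and_bound_search()` adds taxa stepwise to every unrooted insertion
point. The lower bound for a partial tree is its own length plus one step
for every state that occurs only in fixed cells of unplaced taxa; the
incumbent is seeded by greedy stepwise addition, and subtrees are abandoned
only when the bound strictly exceeds the incumbent, so **all** co-optimal
topologies are returned (tie-breaking is unnecessary by construction).
Search refuses more than 16 taxa: heuristic rearrangement searches are
deliberately out of scope, and exhaustive correctness at small scale is the
point. `enumerate_topologies()` (guarded to 9 taxa; counts follow the
double-factorial closed forms, (2n−5)!! unrooted and (2n−3)!! rooted)
provides the independent oracle the search is tested against.

## Reconstructions, ambiguity, and direction

For each character, every MPR is enumerated by backtracking over the
Sankoff-optimal state sets; the reconstructions are exactly the assignments
attaining the Fitch length, including the resolution of polymorphic and
wildcard terminals. A change is **unambiguous** when the identical
branch/from/to transition occurs in every MPR; everything else is an
ambiguous candidate reported with all its alternative placements
(`summarize_synapomorphies()`).

For single-reconstruction reporting, the placement policy resolves ties in
a preorder pass over the optimal state sets:

* **DELTRAN** (default) keeps the parent state whenever optimal, delaying
  transformations tipward and favouring independent terminal acquisitions.
* **ACCTRAN** prefers a change on the current branch whenever optimal,
  accelerating transformations rootward (early gains, later reversals).

Remaining ties break to the smallest state, making both policies
deterministic. DELTRAN is the default because the motivating analysis
reports terminal-branch reassignments of previously deeper changes; both
policies are retained because the scientific argument rests on the full
equal-parsimony set, not on one convention.

A change is classified a **reversion** when it returns to the state held at
the root of that reconstruction (the outgroup-anchored ancestral condition)
from a different state, and an **acquisition** otherwise. In the union
table of ambiguous candidates, direction is reported relative to the
policy-selected reconstruction's root state; in the rare case of an
ambiguous root state the table can therefore mix conventions, which is why
per-reconstruction change tables carry their own `root_state`.

## Rates

A consistent between-taxon difference requires **disjoint** coded state
sets (`pairwise_differences()`): a polymorphic taxon overlapping the other
taxon's state is within-species variation, not a difference, and wildcards
never count. Rates are plain quotients, changes per Ma
(`divergence_rate()`), displayed with one decimal at ≥1/Ma and two below
(so 28 changes over 8 Ma prints "3.5" and 2 over 7.1 prints "0.28"); stored
values are full precision and rate × span always reproduces the count
exactly. Node ages live on nodes (Ma before present), terminals default to
age 0, and branch spans are age differences; two calibration presets cover
the split datings used in the rate arithmetic (chimpanzee–human 8 Ma with
chimpanzee–bonobo 2 Ma, default; and 7.5/3 Ma as the alternative published
scheme). The deeper preset ages (25/20/16/9 Ma) are conventional hominoid
values that only affect whole-lineage display rows, not the quoted rates.

## The worked-example fixtures

`build_paper_fixtures()` encodes the printed character vectors over the
seven-terminal working topology
`(Outgroup,(Hylobatids,(Pongo,(Gorilla,((P_troglodytes,P_paniscus),Homo)))))`:
32 characters reproducing the published difference bookkeeping — 7
chimp–bonobo differences (2 major), 16 head-neck/forelimb (HN-FL) plus 12
hindlimb chimp–human differences (20 major in total), the ambiguous
characters 112 and 66 with their equal-cost reconstructions, and the
Pan-stem (chars 120, 131) and *P. troglodytes* (chars 83, 140) reversions.

Where the source prints no state, choices were made once and documented in
the per-character provenance notes:

* hylobatid and outgroup cells default to the ancestral state 0;
* Pongo/Gorilla cells for characters 83, 120, 131 and 140 are set to the
  derived state, which is what makes the described stem gains and
  *P. troglodytes*/Pan-stem reversions the (unique) most-parsimonious
  placements;
* "contrahentes to digits 4 and 5" is encoded as two characters so the
  printed count of 13 major HN-FL differences is met — whether the original
  character list treats them as one or two cannot be resolved from the main
  text alone;
* the 16 HN-FL chimp–human differences are a printed tally, not a list;
  15 are reconstructable, and character 150 (labelled a synthetic
  placeholder) supplies the 16th so that the 28-difference, 3.5-per-Ma
  arithmetic is computable from the matrix.

One bookkeeping note: the source quotes 13 major bonobo–human differences,
netting the intermetacarpales character against scansorius across body
regions; under the same rules that give 20 major chimp–human differences,
the fixture yields 20 bonobo–human majors. The discrepancy is in the
source's own arithmetic and is deliberately not reproduced.

The full 166-character matrix of the original study lives in its
supplementary information and is not redistributed here; its headline
statistics (single most-parsimonious tree, L = 303, CI = 57, RI = 75)
are therefore *not evaluable* from the fixtures. `acceptance_suite()`
reports them as such rather than failed, and `run_analysis()` computes the
same statistics for any user-supplied matrix.

## The synthetic generator

`generate_matrix()` evolves characters on a known topology by sampling
change events per branch (Poisson), from root state 0, flipping binary
states or moving uniformly among multistate ones, with an optional bias of
events back toward the ancestral state. Defaults emulate the study scale:
10 terminals, 166 characters, 90% binary, and 1.8 expected changes per
character spread uniformly over the branches — the change density implied
by an ensemble CI in the high 50s at this matrix size. Per-branch Poisson
events, rather than a per-site continuous-time process, match the unit of
analysis: the discrete anatomical change event, with rates quoted as
changes per Ma. The generator emits the true net change per (character,
branch) alongside the matrix, so inference is scored by exact
(character, branch) matching (`recovery_report()`).

What the generator does **not** emulate: correlated characters,
region-specific rate covariance (mosaicism is measured, not simulated),
missing data, and polymorphic terminal coding. Passing recovery tests
therefore demonstrate correctness of the inference machinery under the
stated generating process, not robustness to those real-data features.

Two calibration points from the test suite, with the problem sizes chosen
for them:

* **Topology recovery.** At 8 taxa, 166 characters, and one expected change
  per character, the generating topology is among the returned
  most-parsimonious trees in 95 of generator seeds 1–100 (unique tree in
  93). The acceptance test asserts exactly this threshold at exactly these
  conditions.
* **Stasis branches.** A zero-rate branch ("the bonobo regime") never
  carries a true change, but the informal claim "no unambiguous change is
  ever inferred there" is only a theorem for characters whose realised
  change count equals their Fitch length — for those, the true history is
  itself an MPR, and an unambiguous change would have to appear in it.
  Characters whose realised history is homoplastic carry no such guarantee,
  and at 60 characters per matrix occasional counterexamples do occur. The
  tests assert the exact statement in a 0.5-changes-per-character regime,
  where over 80% of characters satisfy the condition.

## Numerical and degenerate-input conventions

* Rounding of printed percentages: half away from zero (57.5 → 58).
* Rate display: one decimal at ≥1/Ma, two decimals below.
* Zero-span branches are allowed only with zero changes; any dated tree is
  checked for parent-older-than-child consistency.
* Zero-character matrices are valid (taxa-only files round-trip); constant
  characters score zero steps and a single zero-change reconstruction.
* Canonical tree serialization orders children by the lexicographically
  smallest descendant tip label, giving deterministic output, stable
  topology identity keys, and duplicate-free enumeration.
* MPR enumeration is capped (default 200,000 reconstructions per character)
  and errors loudly rather than truncating silently.

## Known limitations

* Exact search only, to 16 taxa; no NNI/SPR/TBR heuristics.
* Unordered, equally weighted characters only; no step matrices, no
  implied weighting, no support values (bootstrap/jackknife) — these are
  explicit non-goals.
* Inapplicable cells are scored as wildcards, the standard morphology
  convention; no attempt is made at the newer "inapplicable-aware"
  algorithms.
* The ACCTRAN/DELTRAN preorder rules are deterministic conventions; with
  multistate ties other classical implementations may select a different
  member of the same MPR set. All placements of record come from the full
  MPR enumeration, which is implementation-independent.
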