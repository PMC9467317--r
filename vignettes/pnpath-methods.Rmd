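---
title: "Invariant-based pathway analysis: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant-based pathway analysis: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science implemented in `pnpath`: the discrete
Petri-net model class, the invariant analyses built on it, how complete
pathways and in-silico knockouts are derived, and the design decisions taken
where the methods leave genuine freedom. It also states precisely what the
bundled TNFR1-architecture model is and is not.

## The model class

A Place/Transition net is the quintuple `N = (P, T, F, W, m0)`: places carry
non-negative integer token counts; a transition is enabled when every
pre-place holds at least the arc weight, and firing removes and adds tokens
in one timeless step. Signalling models built this way are *open systems*:
input transitions (no pre-places) are protein syntheses, output transitions
(no post-places) are degradations, dissociations, and the cellular responses
themselves. The only closed sub-structures are conservation motifs such as a
gene shuttling between free and transcription-factor-bound form.

Two representation rules matter downstream:

* **Read arcs** (a place tested but not consumed, e.g. an assembled kinase
  platform that phosphorylates a substrate without being used up) are stored
  as a flagged pair of opposite arcs of equal weight. They participate in
  enabling and firing, where the two directions cancel, but are excluded
  from the incidence matrix `C`, which is only defined for the pure part of
  the net. All enabling logic therefore consults the arc list, never `C`,
  and "production" tests used by the pathway search use the pure production
  matrix — a transition that merely reads a place is not a supplier of it.
* **Logical place copies** (layout duplicates of one biochemical entity)
  are a serialization concern: the PNML reader merges same-named flagged
  copies into a single vertex, optionally erroring on conflicting
  annotations.

All matrix rows/columns and iteration orders are fixed lexicographically by
id (radix order, locale-independent), so every result is reproducible across
platforms.

## Invariants

A transition invariant (TI) is a minimal semi-positive integer vector `x`
with `C x = 0`; a place invariant (PI) a minimal `y` with `y C = 0`.
Minimality means no other solution's support is a strict subset, and the gcd
of the positive entries is one. TIs are steady-state flows (the analogue of
elementary modes in metabolic networks); PIs are conservation laws whose
weighted token sum is invariant under every firing — the package's property
tests verify both statements directly, by exact matrix products and by
replaying random firing walks.

The computation is classical Farkas/Fourier–Motzkin elimination on
`[C^T | I]`: constraints (places, for TIs) are eliminated one at a time,
keeping all non-negative pairwise combinations of rows with opposite signs,
deduplicating, gcd-reducing each row, and filtering non-minimal supports at
every step. Sparser constraints are eliminated first, which keeps
intermediate row sets small on biochemical nets. Two implementation choices:

* **Exact integers on doubles.** The algorithm is integer-only; entries are
  gcd-reduced after every combination, which keeps them tiny in practice
  (coefficients on biochemical nets rarely exceed single digits). A guard
  aborts — never silently rounds — if any intermediate exceeds 2^49, far
  below the 2^53 exact-integer limit of a double. This keeps the package
  dependency-free where an arbitrary-precision library would otherwise be
  needed; the guard has never tripped on the bundled model or the generated
  test nets.
* **Equal-support vectors.** Two minimal vectors with the same support but
  non-proportional coefficients are both kept; after gcd normalisation,
  proportional duplicates collapse to identical rows and are removed.

Correctness is checked against an independent oracle: on nets small enough,
all coefficient vectors up to 4 are enumerated exhaustively, reduced to
minimal supports, and compared entry-for-entry with the elimination result.

*Coverage.* A net is CTI when every transition lies in some TI support — the
standard consistency criterion, since a transition in no steady-state flow
can never fire at equilibrium and suggests a modelling error. Open systems
are deliberately far from the place-side analogue (CPI): only genuinely
conserved species sit in PIs.

## Realizability and Manatee invariants

A TI balances token flow but need not be *executable*: its firing sequence
may require tokens (an assembled complex, a nuclear transcription factor)
that only other flows produce. Such TIs are *dissected* pathways. A Manatee
invariant (MI) is a minimal non-negative integer combination of TIs whose
combined Parikh vector can actually fire, step by step, from the initial
marking; each MI carries the witness sequence, and replaying it returns
exactly the initial marking (`Δm = 0`), which the tests assert.

**Deciding realizability** (`realize_parikh`) is staged:

1. *Sound unrealizability proofs.* First the final marking
   `m0 + C·x` is checked for non-negativity — a vector that consumes more
   than it produces anywhere can never run, and the shortfall places are
   exactly the missing external requirements. Then a firability fixed point:
   a transition can only ever fire if each pre-place is supplied by the
   initial marking or by another transition of the vector that can itself
   fire. A required transition outside the fixed point proves
   unrealizability in any order, and the unsupplied pre-places of the
   excluded transitions are reported as the vector's blocking places.
2. *Greedy completion.* Output transitions only remove tokens, so any
   realizable sequence can be rearranged — by adjacent swaps that provably
   preserve enabledness — until all output firings form a suffix; given the
   non-negative final marking that suffix always fires. Outputs are
   therefore excluded from the search and appended. Inputs, symmetrically,
   are token-monotone and fired first. The remaining internal transitions
   are fired greedily under four deterministic orderings; for pathway-shaped
   nets one of them almost always completes.
3. *Bounded backtracking.* Only ordering-sensitive cases reach a memoized
   depth-first search with a node budget. Budget exhaustion yields an
   explicit `"inconclusive"` status — never a silent wrong answer.

**Constructing MIs** is a breadth-first search per seed TI, following the
idea that an incomplete pathway names what it is missing: while the
combination is unrealizable, the blocking places identify unproducible
pre-place requirements, and the search branches on every TI that produces
such a place, up to a multiplicity cap (default 3 — published examples of
combined pathways use small multiplicities, and unbounded search is
undecidable). Three refinements keep the frontier to genuine alternative
routes rather than a combinatorial explosion:

* Among the blocking places, the search branches on those whose trial token
  injection unlocks the largest part of the combination (re-running the
  cheap firability fixed point with one extra token). The root requirement
  of a deadlocked cycle — say, nuclear NF-κB for a gene-expression module —
  unlocks the whole cycle; its downstream members unlock nothing, and
  branching on their producers would only churn within the same stuck
  family.
* A provider addition must *progress*: enlarge the firable set within one
  step. A provider that itself awaits another token (a mitochondrial
  cascade still lacking its initiator caspase) is granted one pending step;
  two non-progress steps in a row end the branch.
* Each seed has a combination budget (default 400 examined combinations);
  exhaustion is reported in the `inconclusive` component, never hidden.

Minimality is per seed — no recorded combination for the same seed is
componentwise smaller — and the final set is deduplicated by Parikh vector.
This reading makes the singleton MIs exactly the TIs that are realizable
alone ("complete"), while a dissected TI appears only bundled with its
providers; both facts are asserted in the test suite. A TI is *trivial* when
it is complete and describes bare turnover: one synthesis, one degradation,
at most one place in between.

Pathway outcomes are assigned from a declarative YAML rule file: each
response output transition maps to an outcome (survival, apoptosis,
necroptosis); an MI reaching exactly one response gets its label, several
responses are resolved by ordered rules (the shipped rule labels an MI that
inhibits mitochondrial pore formation while still activating the executioner
caspase extrinsically as apoptosis) and otherwise "ambiguous"; no response
means "housekeeping". Rules are data, not code, so a different model ships a
different file.

## In-silico knockouts and clustering

A knockout deletes synthesis transitions. An MI survives iff its support
contains none of the knocked transitions; a place is *affected* iff it lies
in no surviving MI-induced subnetwork (among places covered by at least one
MI overall — never-covered places would be trivially red and are reported in
a diagnostics list instead). This MI-coverage semantics is equivalent, on
the synthetic test nets, to physically deleting the transitions and
recomputing the MIs from scratch, which the tests verify, and it is
monotone: knocking a union of sets affects at least the union of what each
affects.

The default knockout matrix knocks every synthesis (for the bundled model:
26 housekeeping syntheses plus the 5 translations of NF-κB-target genes,
which are the only supply of their proteins) against all places outside PI
supports — conserved places cannot be knocked out by removing a synthesis.
Protein impact is ranked by the fraction of MIs destroyed (primary, matching
the pathway-centric reading) and by the fraction of affected column places;
ties break lexicographically.

Knockout profiles are clustered by UPGMA on Pearson-correlation distance
`d = 1 − r` computed on the raw 0/1 vectors. Implementation is
`stats::hclust(method = "average")` behind the package surface, with labels
pre-sorted so equal-distance ties resolve on the lexicographically smallest
pair, and heights recorded on the `d/2` scale (ultrametric; branch lengths
in the Newick export are height differences). Choices worth stating:

* *Zero-variance profiles* (all-affected or all-unaffected rows) have no
  defined correlation; the documented fallback is distance 0 between two
  identical constant vectors and 1 otherwise, which keeps identical-row
  merges at height zero. It is configurable, never an exception.
* `(1 − r)/2` is offered as an alternative scale; it is a monotone
  rescaling, so the tree topology is unchanged — only heights halve.
* The implementation is cross-checked against a naive O(n³) linkage written
  independently in the test suite.

## The bundled TNFR1-architecture model

The fixture under `inst/extdata/tnfr1_synthetic/` is a **synthetic
reconstruction**, assembled from published structural descriptions of
TNFR1-mediated signalling (component inventories, complex compositions,
knockout dependency statements), not a transcription of any machine-readable
supplementary file. Its architecture: TNF/TNFR1/TRADD receptor-complex
assembly abstracted as a single association step; RIP1 recruitment; a
pre-formed TRAF2:cIAP1/2 unit; K63 ubiquitination; one composite step
recruiting LUBAC, TAK1/TAB1, and IKK/NEMO into full complex I; IKK-dependent
IκB phosphorylation (complex I tested via a read arc) driving NF-κB nuclear
translocation; five gene-expression conservation motifs (IκB, A20, XIAP,
cFLIP_L, BCL-2), each transcription → splicing → export → translation, with
one token per gene in the initial marking; A20 and CYLD feedback on complex
I; complex IIa (via dissociated TRADD, RIP1-independent) and IIb (via
TRADD:RIP1) with a pre-formed FADD:procaspase-8 unit and two-step caspase-8
maturation; extrinsic and intrinsic (BID → BAX → MOMP → apoptosome)
caspase-3 activation with XIAP/SMAC/BCL-2 control; and the
RIP1:RIP3 → MLKL → membrane-pore necroptosis branch. A shared proteasomal
substrate pool collects ubiquitinated remnants. Composite association steps
are deliberate: they encode the published observation that functionally
obligatory partners (TNF/TNFR1/TRADD; cIAP1/2–TRAF2; FADD–procaspase-8;
IKK–LUBAC–NEMO–TAK1) produce identical knockout rows.

What holds by construction and is verified at load time and in the tests:
118 places, 130 transitions, 299 edges, 26 input syntheses + 5 gene
translations, five PIs of support two (the gene pairs), CTI coverage, 108
non-conserved places, the 31 × 108 knockout matrix, the identical-row
groupings, non-empty knockout rows, receptor-proximal proteins at the top of
the ranking, and the sparing of nuclear NF-κB turnover under receptor
knockout.

What is *emergent* and differs from the published analysis of the original
model: this reconstruction yields 30 TIs and, under the bounded search
parameters above, 47 MIs (11 complete TIs, 19 dissected, 1 trivial —
synthesis and degradation of NF-κB), with outcome counts reported exactly as
computed. The original model's reaction granularity differs in ways the
prose descriptions do not pin down, and a finer net multiplies both TIs and
their combinations. These counts are reported as computed, never adjusted
toward external values; the acceptance suite states both numbers side by
side and leaves the comparison visible.

## Synthetic generators and what passing tests show

`generate_motif_net` composes motifs with closed-form planted truth:
synthesis–degradation chains (one TI), gene-expression cycles (one
support-2 PI, a dissected expression TI), linear cascades (one TI of length
+ 2), complex-formation joins, feedback loops whose TI is dissected unless
the catalyst place is marked, and provider/consumer pairs whose planted MI
algebra is `{provider}` and `{provider + consumer}`, never the consumer
alone. Motifs are instantiated under namespaced ids and composed
disjointly — coupling is exercised through the dedicated provider/consumer
motif rather than random shared places, so the planted truth stays exact.
`generate_random_net` produces connected bipartite nets with weights in
{1, 2} and optional read arcs under a single integer seed and no global
random state.

These generators emulate the structural vocabulary of curated signalling
models — open synthesis/degradation flows, conservation cycles, joins,
feedback — but not their scale, degree distribution, or biochemical
redundancy. A green property suite therefore demonstrates algorithmic
correctness on the motif vocabulary, not fidelity of any particular curated
model; that is what the bundled model's structural checks are for.

Problem sizes were chosen so the default suite stays comfortable on one
CPU: exhaustive invariant oracles run on nets of up to ~6 × 6 vertices
(coefficients ≤ 4), conservation is replayed over a thousand short walks on
a pooled set of ten nets, and the full bundled-model analysis (the dominant
cost, a few minutes) is computed once and shared across test files.

## Known limitations

* The MI search is heuristic where the underlying problem is undecidable:
  the multiplicity cap, the progress filter, and the per-seed budget bound
  it deterministically, and every truncation or undecided realizability is
  reported. Raising `max_coeff`, `budget`, or `combo_budget` widens the
  enumeration at a predictable cost.
* Colored, timed, stochastic, continuous, and hybrid Petri nets are out of
  scope, as are reachability graphs and model checking; the package never
  claims quantitative (kinetic) conclusions.
* Knockouts are binary deletions; partial knockdowns and dosage are not
  modelled. An optional downstream-only restriction of affected places is
  available for compatibility with path-restricted knockout tools.
* The bundled model is a reconstruction suitable for method development and
  structural reasoning about TNFR1 signalling; biological conclusions about
  specific reactions should be drawn from a curated model.
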