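---
title: "Qualitative Petri-net analysis of the VHL interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative Petri-net analysis of the VHL interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlpn)
```

## The modelling formalism

`vhlpn` works with qualitative standard place/transition Petri nets. Places
carry tokens and stand for molecular species, complexes, pools or states;
transitions stand for reactions, complex formation, transport or
post-translational modification; weighted arcs connect the two. No timing,
rates, colours or special arc types enter the formalism — the modelling
assumptions are:

* **Double (read) arcs** model the permanent presence of an object: an
  enzyme or cofactor that a reaction requires but does not consume. They
  are stored as a pre-arc plus post-arc of equal weight flagged as a pair,
  so enabling still requires the tokens while the net token change is
  exactly zero.
* **Boundary transitions** form the system interface: an input transition
  (no pre-places) models constitutive synthesis or intake; an output
  transition (no post-places) models degradation, secretion or export.
* **Macro (coarse) transitions** and **logical places** exist purely for
  presentation in hierarchical model files; `flatten()` removes the former
  and merges the copies of the latter before any analysis runs.

State is a marking `m` (tokens per place). The incidence matrix
`C = post − pre` (places × transitions) carries the whole algebra: firing
an enabled transition `t` moves the marking by column `C[, t]`.

Two structural objects summarise long-run behaviour. A **T-invariant** is a
non-negative integer vector `x` with `C x = 0`: a multiset of reaction
firings that reproduces the marking, i.e. a pathway operating at steady
state. A **P-invariant** is a non-negative integer `y` with `t(y) C = 0`: a
weighted token sum that no firing can change, i.e. a conserved moiety such
as ATP + ADP. A model is held structurally plausible when it is connected,
covered by T-invariants (every reaction takes part in some steady-state
cycle), and every invariant has a biological reading; `validate_structure()`
additionally checks homogeneity (all outgoing arcs of a place carry equal
weight) and that every place has a pre- and a post-transition.

## The reduced VHL core model

`build_core_model()` returns a hand-encoded net of 85 places and 96
transitions covering the main pVHL functional pathways: constitutive
HIF-1α/pVHL turnover; the oxygen- and PHD2-dependent hydroxylation of
HIF-1α followed by VCB/Cul2-mediated ubiquitination and proteasomal
degradation; the two alternative degradation routes (p53/Mdm2 and GSK3β
phosphorylation); nuclear HIF·ARNT transcription at the HRE with
p300/Creb/c-jun cofactors producing VEGF, EPO, endothelin, GLUT1, LDH-A,
PDK1, MMPs and Nur77; three VEGF and two EPO signalling branches that feed
back on oxygen supply; Sp1-driven, HIF-independent VEGF transcription with
HuR stabilisation; glucose uptake through GLUT1/2/4, glycolysis, the three
pyruvate fates, the Krebs cycle and the respiratory-chain ATPase; glycogen
synthesis and mobilisation under GSK3β control; Jade1/β-catenin/Wnt;
fibronectin-versus-MMP matrix regulation; and aPKCζII tight-junction
control.

Design choices worth knowing:

* **All arc weights are 1.** Token counts are qualitative (presence and
  flow, not stoichiometry), and unit weights make the net trivially
  homogeneous. One consequence is that glycolysis at token level is
  ATP-negative until respiration closes the loop, which is exactly what
  makes the respiratory-knockout behave the way it should.
* **Initial marking convention**: 1 token on every enzyme or
  side-condition place (Elongins, PHD2, Mdm2, the HRE, transporters,
  kinase pools, …), 3 on the ATP and NAD pools, 2 on oxygen, 0 elsewhere.
  The published marking of the full-scale model is not restated anywhere
  in text form, so a convention was fixed once and all qualitative
  assertions are made robust to it.
* **Reciprocal glycogen regulation**: glycogen mobilisation requires the
  inactive state of glycogen synthase as a side condition, reflecting the
  reciprocal phosphorylation control of synthesis and breakdown. This is
  what lets a GSK3β knockout lock the model into net glycogen production.
* **Ids** reuse the conventional `t_<n>` numbers where the corresponding
  reactions have well-known table positions in the literature on this
  network (e.g. `t_98` for the HIF/pVHL input, `t_97` for the ATPase,
  `t_113`–`t_119` for the degradation machinery); descriptive ids are used
  elsewhere. Analyses never depend on the numbering.
* The encoding was iterated until `validate_structure()` passes and the
  T-invariants cover every transition, mirroring how such models are
  curated in practice.

The model intentionally sits at roughly a quarter of the published
full-scale network (which has 323 places and 238 transitions); the
`load_full_model()` reader applies the identical analysis pipeline to that
file when a copy is available (place it at
`inst/extdata/vhl_full_model.spped`).

## Exact invariant computation

`minimal_t_invariants()` / `minimal_p_invariants()` implement classical
Farkas (Fourier–Motzkin column) elimination on `[t(C) | I]`: constraint
columns are eliminated in ascending non-zero-density order; positive and
negative rows are combined pairwise with the smallest cancelling integer
multipliers; every new row is gcd-reduced; and rows whose support strictly
contains another row's support are pruned at each step. The result is the
complete set of support-minimal, gcd-normalised semi-positive solutions,
in a deterministic order (support size, then lexicographic support).

Arithmetic is exact: entries are integer-valued doubles, kept small by the
gcd reduction at every step (observed maxima are single digits; doubles
are exact integers up to 2^53). Soundness (`C x = 0` entrywise, gcd = 1)
is asserted for every returned set.

**Trivial invariants.** A T-invariant with support ≤ 2 is flagged trivial —
these are the forward/backward reaction pairs (active/inactive protein
states, nuclear shuttling), with the degenerate support-1 case from an
all-zero column included and logged. A P-invariant with support 1 is
trivial — a single place attached only through double arcs. Trivial
invariants count toward coverage but are excluded from clustering and MCTS
analysis, where they would only add noise.

**The enumeration oracle.** The test suite cross-checks Farkas against
`brute_force_invariants()`, an independent exhaustive enumeration of all
vectors with entries ≤ 4. The box matters: a bounded solution can look
support-minimal merely because the invariant dominating it has an entry
above 4. The comparison is therefore made inside the box (and, in the
acceptance script, dominated enumeration vectors are discarded only under
an explicit witness certificate re-verified against the linear system).
Completeness beyond the box is covered separately by nets with planted,
provably complete invariant sets.

## Clustering and MCTS decomposition

Support similarity is the Tanimoto coefficient `|A∩B| / |A∪B|`, computed
exactly from integer intersection and union sizes. Two readings of
"cluster at a 65% similarity threshold" are implemented because the
phrase is genuinely ambiguous:

* `mode = "dendrogram"` (default): agglomerative clustering on the
  distance `1 − tanimoto`, cut at height `1 − threshold`. The default
  linkage is UPGMA (`average`) — the conventional choice for similarity
  matrices of this kind — with `single` and `complete` available.
* `mode = "pairwise"`: link every pair at similarity ≥ threshold and take
  connected components (equivalent to a single-linkage cut).

`clustering_mode_sweep()` tabulates all combinations across thresholds so
a reported cluster count can be reconciled empirically; on the core model
the mode and linkage change the count by a factor of about two, which is
why the choice is surfaced rather than buried. Determinism: invariant
order is canonical, ties in the merge sequence are resolved by `hclust`'s
deterministic ordering, and tiny floating-point height inversions produced
by tied merges are clamped monotone before cutting. Clusters are numbered
`C1, C2, …` by size (largest first), with smallest member id breaking
ties.

The **MCTS partition** groups transitions by their exact membership
pattern across the non-trivial T-invariants. Classes are maximal by
construction (two classes with equal patterns would have been one),
pairwise disjoint, and every class lies entirely inside or outside any
invariant's support. Classes of size ≥ 2 are numbered `M1, M2, …` by
smallest member id; size-1 classes are reported as singletons; transitions
in no invariant are listed as excluded. `coverage_table()` counts, for
each class, the invariants containing all of its members — the most
covered class is the block shared by the largest number of pathway
variants.

## Simulation and knockouts

`simulate_net()` plays the token game with sequential single-transition
semantics: at each step one transition is drawn uniformly among the
enabled ones. This matches the animation semantics under which such models
are visually inspected, and makes every qualitative claim a statement
about replicated random interleavings rather than about one scheduler.
Identical `(net, marking, steps, seed)` give identical traces, and the
caller's RNG state is saved and restored.

A knockout is a `knockout_spec()`: transitions erased outright (structural
loss of a reaction) and/or places clamped to a fixed count — clamping
detaches all arcs feeding the place; clamping to 0 erases the token and
starves every consumer permanently, which is the token-knockout used for
side-condition places such as Mdm2.

`run_experiment()` simulates once per seed (defaults: seeds 1–10, 5000
steps) and reports judgements that must hold in **every** replicate:

* **dead** — never enabled at any visited state;
* **accumulating** — the count sampled every 50 steps is non-decreasing,
  gains ≥ 3 tokens overall, *and* the place lies in no P-invariant of the
  knocked-out net. The last condition is structural: a place covered by a
  P-invariant is bounded by the conserved sum, so a small pool saturating
  (ADP drifting to its pool maximum after the ATPase is removed) is never
  mistaken for unbounded growth;
* **depleted** — held tokens at some point and the sampled count is zero
  throughout the final quarter of the run.

These are operational proxies for the visual judgements "grows without
bound" and "runs out"; the window (50), gain (3), seed set and step count
are package defaults chosen so that the designed monotone behaviours are
detected reliably at sub-minute runtimes, and all are arguments.

`named_experiments()` encodes the eight loss-of-function scenarios with
their expected qualitative outcomes (pVHL; HIF-1α alone; HIF-1α + Sp1;
HIF-1α + pVHL; PHD2; the Mdm2-token knockout silencing the p53 route; the
respiratory ATPase; GSK3β). Each expectation is asserted over all ten
replicate seeds by the regression suite. "Inactivated MCTS" is taken to
mean a class all of whose members are removed or dead; note that a class
containing a boundary input transition can never be fully inactivated by
a token knockout, since inputs stay enabled by definition.

## The synthetic generator

`generate_net()` builds nets from vertex-disjoint directed cycles (each a
planted all-ones T-invariant), optionally joined by reversible bridge
pairs (planted trivial T-invariants) and decorated with read-arc enzyme
places (planted singleton P-invariants). Ground truth is established **by
construction, not by solving**: when the bridge multigraph over the cycles
is a forest, no circuit beyond the planted ones exists, so the planted
sets are provably the complete minimal sets (`mode = "exact_planted"`);
otherwise the mode degrades to `superset_allowed`. Planted objects are
re-verified against the generated incidence matrix before the net is
returned. `generate_supports()` plants cluster structure in support sets
with calibrated within/between similarity bounds, verified exhaustively
before returning.

What the generator emulates of real pathway models: unit-dominant arc
weights, read-arc side conditions, boundary behaviour, cyclic steady-state
structure, and separable pathway variants. What it does not: hierarchical
macro nodes, logical place copies, heavy-tailed degree distributions, the
dense coupling through shared cofactor pools, or biologically meaningful
annotations. Passing the planted-recovery tests therefore certifies the
*algorithms* (completeness, minimality, clustering recovery), while the
hand-encoded core model — whose coupling through ATP/NAD/oxygen pools is
exactly the kind of structure the generator omits — carries the burden of
showing the pipeline behaves on realistic topology.

## Problem sizes and runtime

The validation suite runs at sizes chosen for desk-scale turnaround: 200
random nets of ≤ 8 places × 8 transitions against the enumeration oracle;
the planted grid over 1–5 cycles × lengths 2–6 × 5 seeds; 20 seeds of
planted support clusters; 1000-step conservation traces; and the eight
knockouts at 10 × 5000 steps. The full run takes about a minute; invariant
analysis of the core model itself takes about two seconds.

## Known limitations

* The analysis is purely qualitative; nothing here estimates rates,
  concentrations or time courses.
* Liveness is judged by simulation-based dead-transition detection, not by
  reachability-graph construction; a transition enabled only on an
  astronomically rare interleaving could in principle be misjudged dead
  (mitigated by replication across seeds).
* The enumeration oracle is complete only within its entry bound; the
  planted constructions cover the rest.
* The accumulation/depletion calls are operational proxies with
  configurable defaults, not formal boundedness proofs — except where the
  P-invariant filter applies, which *is* a proof of boundedness.
* The Snoopy-dialect reader is reverse-engineered and read-only; it falls
  back to a generic element-name scan and reports what it matched rather
  than failing silently.
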