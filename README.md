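# vhlpn — qualitative Petri-net analysis of the VHL tumor-suppressor network

Loss of the von Hippel–Lindau protein (pVHL) causes a hereditary cancer
syndrome. pVHL's best-characterised job is tagging the hypoxia-inducible
transcription factor HIF-1α for oxygen-dependent degradation, but it acts
as a molecular hub across matrix stability, tight junctions, Wnt
signalling and glucose metabolism — systems with many players and almost
no reliable kinetic constants. Qualitative place/transition Petri nets fit
this situation: species are places holding tokens, reactions are weighted
transitions, and structural analysis plus token-game simulation yield
falsifiable statements without any rate parameters.

`vhlpn` is an R package plus analysis workflow for exactly this kind of
study. It is written for systems biologists who want to validate a curated
pathway net and run in-silico knockouts, and for methodologists who want
exact invariant machinery with testable ground truth. It provides:

* a core data model for hierarchical standard Petri nets with read-arc
  side conditions (`petri_net()`, `flatten()`, `incidence()`, `fire()`);
* **exact minimal semi-positive invariants** by Farkas elimination:
  T-invariants (`C x = 0`, steady-state pathway cycles) and P-invariants
  (`t(y) C = 0`, conserved moieties such as ATP + ADP), with
  trivial-invariant classification, coverage checks and occurrence
  rankings;
* **decomposition**: Tanimoto-coefficient (`|A∩B|/|A∪B|`) clustering of
  invariant supports and the maximal-common-transition-set (MCTS)
  partition — transitions occurring in exactly the same invariants;
* **seeded token-game simulation and knockouts** with qualitative
  readouts: dead transitions, token accumulation, depletion;
* a hand-encoded **reduced VHL core model** (85 places, 96 transitions)
  and the eight named knockout experiments, kept green as a regression
  suite;
* **synthetic generators with planted ground truth** (provably complete
  invariant sets, calibrated cluster structure) and a brute-force
  enumeration oracle, so every stage is testable offline;
* readers/writers for PNML and a tabular net format, and a read-only
  reader for Snoopy-style `.spped` XML.

## Worked example

```r
library(vhlpn)

core <- build_core_model()
core$net
#> <petri_net> vhl_core
#>   places:      85
#>   transitions: 96
#>   arcs:        283 (68 in read pairs)

validate_structure(core$net)
#> <structure_report>
#>   connected:                    TRUE
#>   homogeneous:                  TRUE
#>   every place has pre & post:   TRUE
#>   boundary transitions:         27
```

The net is connected, every place's outgoing arcs carry equal weight, and
every species has both a producer and a consumer — the 27 boundary
transitions are the model's interface to the rest of the cell
(synthesis inputs, degradation/secretion outputs).

```r
ti <- classify_trivial(minimal_t_invariants(core$net))
ti
#> <invariant_set> kind T, 190 invariants (10 trivial) over 96 transitions [vhl_core]
coverage(core$net, ti)$covered
#> [1] TRUE
```

All 96 transitions sit inside at least one of the 190 minimal
T-invariants, so every reaction takes part in some steady-state cycle;
the 10 trivial invariants are the forward/backward state pairs (nuclear
shuttling of HIF-1α, kinase active/inactive toggles, and so on).

```r
head(occurrence_table(ti), 3)
#>   transition count percentage
#> 1       t_91   169     93.889
#> 2       t_92   169     93.889
#> 3       t_93   169     93.889
```

The occurrence ranking says which reactions the steady-state cycles lean
on most — here the Krebs-cycle core, present in 169 of the 180
non-trivial invariants (93.889%).

```r
cluster_invariants(ti, threshold = 0.65)
#> <invariant_clustering> 22 clusters of 180 invariants (threshold 0.65, dendrogram/average)
#>   sizes: 45 45 30 18 9 6 6 3 3 3 1 1 1 1 1 1 1 1 1 1 1 1
mcts(ti)
#> <mcts_partition> 22 non-trivial sets, 15 singletons, 17 excluded transitions
```

Clustering at 65% Tanimoto similarity groups the pathway variants; the
MCTS partition cuts the transition set into blocks that always operate
together (the pVHL degradation machinery, the transcription programme,
the Krebs cycle, each signalling branch).

```r
rep <- run_experiment(core$net, named_experiments()$t97$spec, seeds = 1:10)
rep
#> <knockout_report> [vhl_core] removed: t_97
#>   dead transitions:     1
#>   accumulating places:  acoa, glucose_in, oxygen
#>   depleted places:      atp
```

Removing the respiratory-chain ATPase (`t_97`) makes oxygen accumulate —
nothing consumes it any more — while ATP is drained and never
regenerated: the cell can no longer turn metabolism into energy. All
eight named experiments (`named_experiments()`) carry expected assertions
like these and are checked over ten replicate seeds.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write tables to
`results/`:

| script | what it does |
|---|---|
| `01_build_model.R` | build the core model, structural validation, export `.net`/`.pnml` |
| `02_invariants.R` | T-/P-invariants, trivial classification, coverage, occurrence ranking, degradation-route exclusivity |
| `03_decomposition.R` | Tanimoto clustering, MCTS partition, cluster×MCTS coverage table, clustering-mode sweep |
| `04_knockouts.R` | the eight knockout experiments with assertion tables and JSON reports |
| `05_synthetic_validation.R` | oracle agreement, planted recovery, conservation checks |

Run any of them from the repository root, e.g.
`Rscript analysis/02_invariants.R`.

If a copy of the full-scale published model file is available, place it at
`inst/extdata/vhl_full_model.spped`; `load_full_model()` and the test
suite will pick it up and run the identical pipeline at full scale.

## Tabular net format

`write_net(net, path, "tabular")` emits three tab-separated sections, each
with a header line:

```
[PLACES]
id	name	tokens	logical
[TRANSITIONS]
id	name	kind	parent
[ARCS]
source	target	weight	read_pair
```

`kind` is one of `internal`/`input`/`output`/`macro`; `parent` is `-` or
the enclosing macro transition; `read_pair` marks one half of a double
arc. `read_net()` auto-detects this format, PNML, and the Snoopy dialect.

## See also

The package vignette (`vignettes/qualitative-petri-net-analysis.Rmd`)
documents the model encoding, the invariant algorithm, the clustering
ambiguity and its resolution, the simulation semantics, and the
generator's scope and limits.
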