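## The core-model analyses feed several tests; compute them once.
core <- build_core_model()
core_ti <- classify_trivial(minimal_t_invariants(core$net))
core_pi <- classify_trivial(minimal_p_invariants(core$net))
core_supports <- invariant_supports(core_ti, non_trivial_only = TRUE)

test_that("the core model satisfies the structural validity criteria", {
  rep <- validate_structure(core$net)
  expect_true(rep$connected)
  expect_true(rep$homogeneous)
  expect_true(rep$every_place_has_pre_and_post)
  ## boundary interface transitions exist and are reported separately
  expect_true(all(c("t_98", "t_69", "t_216") %in% rep$boundary_transitions))
  ## covered by T-invariants, not covered by P-invariants
  expect_true(coverage(core$net, core_ti)$covered)
  expect_false(coverage(core$net, core_pi)$covered)
})

test_that("model size stays in the intended reduced range", {
  ## about a quarter of the full published model's place count and well
  ## under half of its transitions
  expect_gte(nrow(core$net$places), 55)
  expect_lte(nrow(core$net$places), 95)
  expect_gte(nrow(core$net$transitions), 50)
  expect_lte(nrow(core$net$transitions), 100)
  ## every transition annotated; pathway tags refer to real ids
  expect_true(all(core$net$transitions$id %in% names(core$annotations)))
  expect_true(all(unlist(core$pathway_tags) %in% core$net$transitions$id))
})

test_that("the state-cycle pairs come out as the trivial T-invariants", {
  triv <- invariant_supports(core_ti)[core_ti$trivial]
  expect_equal(length(triv), 10)
  expected_pairs <- list(c("t_0", "t_2"), c("t_99", "t_100"),
                         c("t_101", "t_102"), c("t_103", "t_132"),
                         c("t_167", "t_199"), c("t_177", "t_208"),
                         c("t_174", "t_222"), c("t_181", "t_207"))
  for (pair in expected_pairs) {
    expect_true(any(vapply(triv, setequal, logical(1), pair)),
                label = paste("pair", paste(pair, collapse = "+")))
  }
})

test_that("the three HIF degradation routes form distinct invariant supports", {
  tags <- core$pathway_tags
  has <- function(s, tag) any(tags[[tag]] %in% s)
  via_pvhl <- vapply(core_supports, has, logical(1), "hif_degradation_pvhl")
  via_p53 <- vapply(core_supports, has, logical(1), "hif_degradation_p53")
  via_gsk <- vapply(core_supports, has, logical(1), "hif_degradation_gsk3b")
  expect_gt(sum(via_pvhl & !via_p53 & !via_gsk), 0)
  expect_gt(sum(via_p53 & !via_pvhl & !via_gsk), 0)
  expect_gt(sum(via_gsk & !via_pvhl & !via_p53), 0)
})

test_that("degradation-route exclusivity holds over the full invariant set", {
  tags <- core$pathway_tags
  ## the p53 and GSK3beta routes never share a minimal invariant
  both_alt <- vapply(core_supports, function(s) {
    any(tags$hif_degradation_p53 %in% s) &&
      any(tags$hif_degradation_gsk3b %in% s)
  }, logical(1))
  expect_equal(sum(both_alt), 0)
  ## hence no support carries all three routes
  all_three <- vapply(core_supports, function(s) {
    any(tags$hif_degradation_pvhl %in% s) &&
      any(tags$hif_degradation_p53 %in% s) &&
      any(tags$hif_degradation_gsk3b %in% s)
  }, logical(1))
  expect_equal(sum(all_three), 0)
})

test_that("the three VEGF branches occur in equally many invariants", {
  n13 <- sum(vapply(core_supports, function(s) "t_13" %in% s, logical(1)))
  n14 <- sum(vapply(core_supports, function(s) "t_14" %in% s, logical(1)))
  n15 <- sum(vapply(core_supports, function(s) "t_15" %in% s, logical(1)))
  expect_gt(n13, 0)
  expect_equal(n13, n14)
  expect_equal(n14, n15)
})

test_that("P-invariants recover the conserved pools and enzyme singletons", {
  supp <- invariant_supports(core_pi)
  find_support <- function(ids) any(vapply(supp, setequal, logical(1), ids))
  expect_true(find_support(c("atp", "adp")))
  expect_true(find_support(c("nad", "nadh")))
  expect_true(find_support(c("fad", "fadh2")))
  expect_true(find_support(c("gsk3b", "gsk3b_i")))
  expect_true(find_support(c("gs_act", "gs_i")))
  expect_true(find_support(c("arnt", "hif_arnt")))
  ## read-only enzymes are trivial singleton P-invariants
  for (e in c("elob", "eloc", "mdm2", "phd2", "hre")) {
    expect_true(find_support(e), label = e)
  }
  ## the HuR pool (free / mRNA-bound / pVHL-sequestered) is conserved
  expect_true(find_support(c("hur", "vegf_hur", "hur_seq")))
})

test_that("named experiments are well-formed and reference real ids", {
  exps <- named_experiments()
  expect_setequal(names(exps),
                  c("pvhl", "hif1a", "hif1a_sp1", "hif1a_pvhl", "phd2",
                    "mcts1", "t97", "gsk3b"))
  all_ids <- c(core$net$transitions$id, core$net$places$id)
  for (e in exps) {
    expect_true(all(e$spec$removed_transitions %in% core$net$transitions$id))
    expect_true(all(names(e$spec$clamped_places) %in% core$net$places$id))
    expect_true(all(unlist(e$expected[c("dead", "alive")]) %in%
                      core$net$transitions$id))
    expect_true(all(unlist(e$expected[c("accumulating", "depleted")]) %in%
                      core$net$places$id))
  }
})

test_that("load_full_model reports raw counts and flattens for analysis", {
  ## exercised on a written copy of the core model (the published
  ## supplementary file is loaded the same way when available)
  path <- withr::local_tempfile(fileext = ".net")
  write_net(core$net, path, "tabular")
  mod <- load_full_model(path)
  expect_equal(unname(mod$raw_counts["places"]), nrow(core$net$places))
  expect_equal(unname(mod$raw_counts["transitions"]),
               nrow(core$net$transitions))
  expect_equal(unname(mod$raw_counts["arcs"]), nrow(core$net$arcs))
  expect_equal(unname(mod$raw_counts["firable_transitions"]),
               nrow(core$net$transitions))
  expect_true(coverage(mod$net, minimal_t_invariants(mod$net))$covered)
})
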