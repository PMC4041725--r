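test_that("incidence matrix reflects pre/post structure exactly", {
  net <- reversible_pair_net()
  inc <- incidence(net)
  expect_equal(unname(inc$C), matrix(c(-1, 1, 1, -1), 2, 2))
  expect_identical(inc$C, inc$post - inc$pre)

  ## side condition cancels in C but keeps its weights
  sc <- side_condition_net()
  inc2 <- incidence(sc)
  expect_true(all(inc2$C["E", ] == 0))
  expect_equal(inc2$pre["E", "t"], 1)
  expect_equal(inc2$post["E", "t"], 1)

  ## 3-cycle: each column one +1 and one -1
  inc3 <- incidence(three_cycle_net())
  expect_true(all(colSums(inc3$C == 1) == 1))
  expect_true(all(colSums(inc3$C == -1) == 1))

  ## input column >= 0, output column <= 0
  incb <- incidence(branched_net())
  expect_true(all(incb$C[, "t1"] >= 0))
  expect_true(all(incb$C[, "t3"] <= 0))
})

test_that("firing an enabled transition applies the incidence column", {
  net <- three_cycle_net()
  inc <- incidence(net)
  m <- initial_marking(net)
  for (t in c("t1", "t2", "t3")) {
    m2 <- fire(net, m, t, inc)
    expect_identical(unname(m2 - m), unname(inc$C[, t]))
    expect_true(all(m2 >= 0))
    m <- m2
  }
  expect_identical(m, initial_marking(net))  # a full cycle reproduces m0
})

test_that("read pairs require but preserve the enzyme token", {
  net <- side_condition_net()
  m <- initial_marking(net)
  m2 <- fire(net, m, "t")
  expect_equal(unname(m2["E"]), 1)
  expect_equal(unname(m2["p1"]), 0)
  expect_equal(unname(m2["p2"]), 1)
  ## without the enzyme token the transition is disabled
  m["E"] <- 0
  expect_error(fire(net, m, "t"), "E")
})

test_that("firing a disabled transition names the deficient place", {
  net <- reversible_pair_net()
  m <- initial_marking(net)
  expect_error(fire(net, m, "t_b"), "B")
  ## an input transition is enabled under the empty marking
  b <- branched_net()
  m0 <- initial_marking(b)  # all zero
  expect_true("t1" %in% enabled_transitions(b, m0))
  m1 <- fire(b, m0, "t1")
  expect_equal(unname(m1["p1"]), 1)
})

test_that("flatten merges logical copies and drops macro containers", {
  ## 7 logical ATP copies merge into one place carrying all arcs
  copies <- sprintf("atp_%d", 1:7)
  net <- petri_net(
    places = data.frame(id = c(copies, "x"),
                        name = c(rep("ATP", 7), "x"),
                        is_logical = c(rep(TRUE, 7), FALSE),
                        tokens = c(3, rep(0, 6), 0)),
    transitions = data.frame(id = sprintf("t%d", 1:7)),
    arcs = data.frame(source = c(copies, "t1"),
                      target = c(sprintf("t%d", 1:7), "x"))
  )
  flat <- flatten(net)
  expect_equal(nrow(flat$places), 2)
  expect_equal(sum(flat$places$name == "ATP"), 1)
  atp_id <- flat$places$id[flat$places$name == "ATP"]
  expect_equal(sum(flat$arcs$source == atp_id), 7)
  expect_equal(flat$places$tokens[flat$places$id == atp_id], 3)
  expect_false(any(flat$places$is_logical))

  ## macro containers disappear; children stay firable
  net2 <- petri_net(
    places = data.frame(id = c("a", "b"), tokens = c(1, 0)),
    transitions = data.frame(id = c("M", "c1", "c2", "c3"),
                             kind = c("macro", rep("internal", 3)),
                             parent = c(NA, "M", "M", "M")),
    arcs = data.frame(source = c("a", "c1", "a", "c2", "a", "c3"),
                      target = c("c1", "b", "c2", "b", "c3", "b"))
  )
  flat2 <- flatten(net2)
  expect_equal(nrow(flat2$transitions), 3)
  expect_false(any(flat2$transitions$kind == "macro"))
  expect_equal(hierarchy_depth(flat2), 0L)
})

test_that("flatten is idempotent and the identity on flat nets", {
  net <- branched_net()
  expect_identical(flatten(net)[c("places", "transitions", "arcs")],
                   net[c("places", "transitions", "arcs")])
  pn <- generate_net(2, 3, n_bridges = 1, read_arcs = 1, seed = 3)
  f1 <- flatten(pn$net)
  f2 <- flatten(f1)
  expect_identical(f1[c("places", "transitions", "arcs")],
                   f2[c("places", "transitions", "arcs")])
})

test_that("nesting deeper than the declared depth is rejected", {
  net <- petri_net(
    places = data.frame(id = "a", tokens = 1),
    transitions = data.frame(id = c("M1", "M2", "M3", "c"),
                             kind = c("macro", "macro", "macro", "internal"),
                             parent = c(NA, "M1", "M2", "M3")),
    arcs = data.frame(source = "a", target = "c")
  )
  expect_error(flatten(net), "depth")
  expect_silent(flatten(net, max_depth = 3))
})

test_that("structure report flags inhomogeneous places and missing pre/post", {
  ## homogeneous: two outgoing arcs of equal weight
  net <- petri_net(
    places = data.frame(id = "p", tokens = 1),
    transitions = data.frame(id = c("t1", "t2", "t3")),
    arcs = data.frame(source = c("p", "p", "t3"), target = c("t1", "t2", "p"),
                      weight = c(1, 1, 1))
  )
  expect_true(validate_structure(net)$homogeneous)
  ## weights 1 and 2 from the same place: flagged
  net$arcs$weight[2] <- 2L
  rep <- validate_structure(net)
  expect_false(rep$homogeneous)
  expect_identical(rep$inhomogeneous_places, "p")

  ## a place without a pre-transition is listed
  net2 <- petri_net(
    places = data.frame(id = c("a", "b"), tokens = c(1, 0)),
    transitions = data.frame(id = "t"),
    arcs = data.frame(source = c("a", "t"), target = c("t", "b"))
  )
  rep2 <- validate_structure(net2)
  expect_false(rep2$every_place_has_pre_and_post)
  expect_true("a" %in% rep2$places_missing_pre_or_post)

  expect_error(validate_structure(
    petri_net(data.frame(id = character(), tokens = integer()),
              data.frame(id = character()),
              data.frame(source = character(), target = character()))),
    "empty")
})

test_that("net construction rejects malformed input", {
  expect_error(petri_net(data.frame(id = c("a", "a")),
                         data.frame(id = "t"),
                         data.frame(source = "a", target = "t")),
               "duplicate")
  expect_error(petri_net(data.frame(id = "a"), data.frame(id = "t"),
                         data.frame(source = "a", target = "zzz")),
               "dangling")
  expect_error(petri_net(data.frame(id = c("a", "b")), data.frame(id = "t"),
                         data.frame(source = "a", target = "b")),
               "bipartite")
})
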