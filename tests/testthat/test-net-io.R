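test_that("tabular round trip reproduces the net exactly", {
  nets <- c(fixture_nets(), list(core = build_core_model()$net))
  for (net in nets) {
    path <- withr::local_tempfile(fileext = ".net")
    write_net(net, path, "tabular")
    doc <- read_net(path)
    expect_identical(doc$source_format, "tabular")
    expect_identical(doc$net$places[, c("id", "name", "is_logical", "tokens")],
                     net$places[, c("id", "name", "is_logical", "tokens")])
    expect_identical(doc$net$transitions, net$transitions)
    expect_identical(doc$net$arcs, net$arcs)
  }
})

test_that("tabular round trip keeps hierarchy and logical flags", {
  net <- petri_net(
    places = data.frame(id = c("atp_1", "atp_2", "x"),
                        name = c("ATP", "ATP", "x"),
                        is_logical = c(TRUE, TRUE, FALSE),
                        tokens = c(2, 0, 0)),
    transitions = data.frame(id = c("M", "c1"), kind = c("macro", "internal"),
                             parent = c(NA, "M")),
    arcs = data.frame(source = c("atp_1", "c1"), target = c("c1", "x"))
  )
  path <- withr::local_tempfile(fileext = ".net")
  write_net(net, path, "tabular")
  back <- read_net(path)$net
  expect_identical(back$places$is_logical, net$places$is_logical)
  expect_identical(back$transitions$parent, net$transitions$parent)
})

test_that("pnml round trip preserves structure, marking and read pairs", {
  for (net in list(side_condition_net(), build_core_model()$net)) {
    path <- withr::local_tempfile(fileext = ".pnml")
    write_net(net, path, "pnml")
    back <- read_net(path)$net
    expect_setequal(back$places$id, net$places$id)
    expect_setequal(back$transitions$id, net$transitions$id)
    expect_equal(nrow(back$arcs), nrow(net$arcs))  # never drops arcs
    expect_identical(initial_marking(back)[net$places$id],
                     initial_marking(net))
    expect_equal(sum(back$arcs$read), sum(net$arcs$read))
    ## boundary kinds are recovered from structure
    expect_identical(
      back$transitions$kind[match(net$transitions$id, back$transitions$id)],
      net$transitions$kind)
  }
})

test_that("a minimal pnml document parses to counts (1, 1, 1)", {
  path <- withr::local_tempfile(fileext = ".pnml")
  writeLines(paste0(
    '<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">',
    '<net id="n"><page id="pg">',
    '<place id="p1"/><transition id="t1"/>',
    '<arc id="a1" source="p1" target="t1"/>',
    '</page></net></pnml>'), path)
  net <- read_net(path)$net
  expect_equal(c(nrow(net$places), nrow(net$transitions), nrow(net$arcs)),
               c(1, 1, 1))
})

test_that("pnml of the reversible pair holds 2+2 nodes and 4 arcs", {
  path <- withr::local_tempfile(fileext = ".pnml")
  write_net(reversible_pair_net(), path, "pnml")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//place")), 2)
  expect_equal(length(xml2::xml_find_all(doc, ".//transition")), 2)
  expect_equal(length(xml2::xml_find_all(doc, ".//arc")), 4)
})

test_that("spped is read-only and unknown dialects are named", {
  expect_error(write_net(reversible_pair_net(), tempfile(), "spped"),
               "read-only")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<mysteryformat><a/></mysteryformat>", path)
  expect_error(read_net(path), "mysteryformat")
  expect_error(read_net(tempfile("nope")), "not found")
})

test_that("a synthetic Snoopy-style file parses with hierarchy and marking", {
  ## constructed example of the reverse-engineered dialect (synthetic, not
  ## the published supplementary file)
  path <- withr::local_tempfile(fileext = ".spped")
  writeLines(c(
    '<Snoopy version="2" revision="1.13">',
    '<netclass name="Petri Net"/>',
    '<nodeclasses>',
    '<nodeclass count="3" name="Place">',
    '<node id="n1"><attribute name="Name">oxygen</attribute>',
    '<attribute name="Marking">2</attribute></node>',
    '<node id="n2"><attribute name="Name">atp</attribute>',
    '<attribute name="Marking">3</attribute></node>',
    '<node id="n3"><attribute name="Name">adp</attribute></node>',
    '</nodeclass>',
    '<nodeclass count="2" name="Transition">',
    '<node id="n4"><attribute name="Name">t_97</attribute></node>',
    '<node id="n5"><attribute name="Name">t_224</attribute></node>',
    '</nodeclass>',
    '<nodeclass count="1" name="Coarse Transition">',
    '<node id="n6"><attribute name="Name">Glycolysis</attribute></node>',
    '</nodeclass>',
    '</nodeclasses>',
    '<edgeclasses><edgeclass count="3" name="Edge">',
    '<edge source="n1" target="n4"/>',
    '<edge source="n3" target="n4"/>',
    '<edge source="n4" target="n2"/>',
    '</edgeclass></edgeclasses>',
    '</Snoopy>'), path)
  doc <- read_net(path)
  expect_identical(doc$source_format, "spped")
  expect_equal(nrow(doc$net$places), 3)
  expect_equal(nrow(doc$net$transitions), 3)
  expect_equal(sum(doc$net$transitions$kind == "macro"), 1)
  expect_equal(nrow(doc$net$arcs), 3)
  m <- initial_marking(doc$net)
  expect_equal(unname(m[c("n1", "n2", "n3")]), c(2, 3, 0))
  ## the flat view drops the childless macro container
  expect_equal(nrow(flatten(doc$net)$transitions), 2)
})

test_that("dangling arcs in a model file are reported with the offending id", {
  path <- withr::local_tempfile(fileext = ".spped")
  writeLines(c(
    '<Snoopy><nodeclasses>',
    '<nodeclass name="Place"><node id="n1">',
    '<attribute name="Name">A</attribute></node></nodeclass>',
    '<nodeclass name="Transition"><node id="n2">',
    '<attribute name="Name">t</attribute></node></nodeclass>',
    '</nodeclasses>',
    '<edgeclasses><edgeclass name="Edge">',
    '<edge source="n1" target="n99"/>',
    '</edgeclass></edgeclasses></Snoopy>'), path)
  expect_error(read_net(path), "n99")
})
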