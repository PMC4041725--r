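## Small fixture nets, built in code.

## t_f: A -> B, t_b: B -> A
reversible_pair_net <- function() {
  petri_net(
    places = data.frame(id = c("A", "B"), tokens = c(1, 0)),
    transitions = data.frame(id = c("t_f", "t_b")),
    arcs = data.frame(source = c("A", "t_f", "B", "t_b"),
                      target = c("t_f", "B", "t_b", "A")),
    name = "reversible_pair"
  )
}

## t1: p1 -> p2, t2: p2 -> p3, t3: p3 -> p1
three_cycle_net <- function() {
  petri_net(
    places = data.frame(id = c("p1", "p2", "p3"), tokens = c(1, 0, 0)),
    transitions = data.frame(id = c("t1", "t2", "t3")),
    arcs = data.frame(source = c("p1", "t1", "p2", "t2", "p3", "t3"),
                      target = c("t1", "p2", "t2", "p3", "t3", "p1")),
    name = "three_cycle"
  )
}

## t1: 0 -> p1, t2: p1 -> p2, t3: p2 -> 0, t4: p2 -> p1
branched_net <- function() {
  petri_net(
    places = data.frame(id = c("p1", "p2")),
    transitions = data.frame(id = c("t1", "t2", "t3", "t4"),
                             kind = c("input", "internal", "output",
                                      "internal")),
    arcs = data.frame(source = c("t1", "p1", "t2", "p2", "p2", "t4"),
                      target = c("p1", "t2", "p2", "t3", "t4", "p1")),
    name = "branched"
  )
}

## enzyme E attached to t by a double arc; p1 -> t -> p2 and a return t2
side_condition_net <- function() {
  petri_net(
    places = data.frame(id = c("p1", "p2", "E"), tokens = c(1, 0, 1)),
    transitions = data.frame(id = c("t", "t2")),
    arcs = data.frame(
      source = c("p1", "t", "E", "t", "p2", "t2"),
      target = c("t", "p2", "t", "E", "t2", "p1"),
      read = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
    ),
    name = "side_condition"
  )
}

fixture_nets <- function() {
  list(reversible_pair = reversible_pair_net(),
       three_cycle = three_cycle_net(),
       branched = branched_net(),
       side_condition = side_condition_net())
}

expect_same_invariants <- function(a, b) {
  expect_identical(dim(a$vectors), dim(b$vectors))
  expect_identical(unname(a$vectors[, a$ids, drop = FALSE]),
                   unname(b$vectors[, a$ids, drop = FALSE]))
}

## canonical form of a partition: sorted list of sorted member sets
partition_signature <- function(groups) {
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1)))
  unname(sig)
}
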