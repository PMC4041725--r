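#' Generate a synthetic net with planted invariants
#'
#' Composes `n_cycles` vertex-disjoint directed cycles (each a planted
#' T-invariant with an all-ones vector), optionally joined by reversible
#' bridge pairs (each a planted trivial T-invariant) and decorated with
#' read-arc enzyme places (each a planted trivial, singleton P-invariant).
#' Ground truth is established by construction rather than by solving: when
#' the bridge multigraph over the cycles is a forest, no circuit other than
#' the planted ones exists, the planted T-invariant set is provably the
#' complete minimal set, and the planted P-invariants (one all-ones vector
#' per bridge-connected component of cycles, plus the enzyme singletons)
#' are complete as well; the net is flagged `mode = "exact_planted"`.
#' Otherwise extra circuits through multiple bridges may arise and the mode
#' degrades to `"superset_allowed"` (planted invariants are still invariants,
#' but the computed set may be larger).
#'
#' All planted claims are re-verified against the generated incidence matrix
#' before returning; a failure aborts.
#'
#' @param n_cycles number of disjoint cycles.
#' @param cycle_len transitions (= places) per cycle, at least 2.
#' @param n_bridges number of reversible bridge pairs between distinct
#'   cycles.
#' @param read_arcs number of enzyme side-condition places to add.
#' @param seed RNG seed.
#' @param grunwald_safe connect all cycles with a spanning path of bridges so
#'   the net is guaranteed connected (forces
#'   `n_bridges >= n_cycles - 1`).
#' @return a list of class `planted_net`: `net`, `planted_t_invariants`,
#'   `planted_p_invariants` (both as [invariant_set()]), `mode`, `seed`.
#' @export
generate_net <- function(n_cycles, cycle_len, n_bridges = 0L, read_arcs = 0L,
                         seed = 1L, grunwald_safe = FALSE) {
  stopifnot(n_cycles >= 1, cycle_len >= 2, n_bridges >= 0, read_arcs >= 0)
  if (grunwald_safe) n_bridges <- max(n_bridges, n_cycles - 1L)
  if (n_bridges > 0 && n_cycles < 2) {
    stop("bridges need at least two cycles")
  }
  with_seed(seed, {
    places <- data.frame(id = character(), tokens = integer())
    transitions <- data.frame(id = character(), kind = character())
    arcs <- data.frame(source = character(), target = character(),
                       weight = integer(), read = logical())
    t_universe <- character()
    planted_t <- list()
    for (i in seq_len(n_cycles)) {
      p_ids <- sprintf("p_%d_%d", i, seq_len(cycle_len))
      t_ids <- sprintf("t_%d_%d", i, seq_len(cycle_len))
      places <- rbind(places, data.frame(id = p_ids,
                                         tokens = c(1L, rep(0L, cycle_len - 1))))
      transitions <- rbind(transitions, data.frame(id = t_ids,
                                                   kind = "internal"))
      nxt <- c(p_ids[-1], p_ids[1])
      arcs <- rbind(arcs,
                    data.frame(source = p_ids, target = t_ids,
                               weight = 1L, read = FALSE),
                    data.frame(source = t_ids, target = nxt,
                               weight = 1L, read = FALSE))
      t_universe <- c(t_universe, t_ids)
      planted_t[[length(planted_t) + 1]] <- t_ids
    }
    ## reversible bridges between distinct cycles; a spanning-path layout is
    ## used first (keeps the bridge multigraph a forest while possible)
    comp <- seq_len(n_cycles)   # union-find over cycles, for the P-invariants
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    bridge_pairs <- list()
    forest <- TRUE
    for (b in seq_len(n_bridges)) {
      if (b < n_cycles) {
        ci <- b; cj <- b + 1L
      } else {
        ci_cj <- sample.int(n_cycles, 2)
        ci <- ci_cj[1]; cj <- ci_cj[2]
      }
      if (find(ci) == find(cj)) forest <- FALSE else comp[find(ci)] <- find(cj)
      a_p <- sprintf("p_%d_%d", ci, sample.int(cycle_len, 1))
      b_p <- sprintf("p_%d_%d", cj, sample.int(cycle_len, 1))
      tf <- sprintf("t_br%d_f", b); tb <- sprintf("t_br%d_b", b)
      transitions <- rbind(transitions,
                           data.frame(id = c(tf, tb), kind = "internal"))
      arcs <- rbind(arcs,
                    data.frame(source = c(a_p, tf, b_p, tb),
                               target = c(tf, b_p, tb, a_p),
                               weight = 1L, read = FALSE))
      t_universe <- c(t_universe, tf, tb)
      planted_t[[length(planted_t) + 1]] <- c(tf, tb)
      bridge_pairs[[b]] <- c(ci, cj)
    }
    ## enzyme side conditions: a token that is required and returned
    enzyme_ids <- character()
    for (e in seq_len(read_arcs)) {
      ez <- sprintf("enz_%d", e)
      tgt <- t_universe[sample.int(length(t_universe), 1)]
      places <- rbind(places, data.frame(id = ez, tokens = 1L))
      arcs <- rbind(arcs,
                    data.frame(source = c(ez, tgt), target = c(tgt, ez),
                               weight = 1L, read = TRUE))
      enzyme_ids <- c(enzyme_ids, ez)
    }
    net <- petri_net(places, transitions, arcs,
                     name = sprintf("synthetic(c%d,l%d,b%d,r%d,s%d)",
                                    n_cycles, cycle_len, n_bridges, read_arcs,
                                    seed))
    mode <- if (forest) "exact_planted" else "superset_allowed"

    t_vec <- do.call(rbind, lapply(planted_t, function(s)
      as.integer(net$transitions$id %in% s)))
    planted_t_set <- invariant_set(t_vec, net$transitions$id, "T", net$name)

    ## P-invariants: all-ones over each bridge-connected component of cycle
    ## places, plus the enzyme singletons
    roots <- vapply(seq_len(n_cycles), find, integer(1))
    p_list <- lapply(unique(roots), function(r) {
      cyc <- which(roots == r)
      unlist(lapply(cyc, function(i) sprintf("p_%d_%d", i, seq_len(cycle_len))))
    })
    p_list <- c(p_list, as.list(enzyme_ids))
    p_vec <- do.call(rbind, lapply(p_list, function(s)
      as.integer(net$places$id %in% s)))
    planted_p_set <- invariant_set(p_vec, net$places$id, "P", net$name)

    ## generator honesty: planted objects must verify on the generated net
    inc <- incidence(net)
    assert_invariants_sound(planted_t_set, inc)
    assert_invariants_sound(planted_p_set, inc)

    structure(list(net = net, planted_t_invariants = planted_t_set,
                   planted_p_invariants = planted_p_set,
                   mode = mode, seed = seed),
              class = "planted_net")
  })
}

#' @export
print.planted_net <- function(x, ...) {
  cat("<planted_net> mode ", x$mode, ", seed ", x$seed, "\n", sep = "")
  print(x$net)
  invisible(x)
}

#' Generate support sets with planted cluster structure
#'
#' Builds `n_clusters * per_cluster` transition-id sets from disjoint cluster
#' cores plus per-item private noise elements, calibrated so that every
#' within-cluster Tanimoto similarity is at least `within_sim` and every
#' between-cluster similarity at most `between_sim`; the realised bounds are
#' verified exhaustively before returning. An optional `common_core` adds a
#' block of ids shared by every support (useful for MCTS pattern tests).
#'
#' @param n_clusters number of planted clusters.
#' @param per_cluster supports per cluster.
#' @param universe total number of available transition ids.
#' @param within_sim,between_sim target similarity bounds
#'   (`within_sim > between_sim`).
#' @param seed RNG seed.
#' @param common_core number of ids shared by all supports (default 0).
#' @return a list of class `planted_supports`: `supports` (named list),
#'   `true_labels`, `within_sim`/`between_sim` (realised min/max), and an
#'   [invariant_set()] view `invariants` for the decomposition functions.
#' @export
generate_supports <- function(n_clusters, per_cluster, universe = 40L,
                              within_sim = 0.8, between_sim = 0.2,
                              seed = 1L, common_core = 0L) {
  stopifnot(n_clusters >= 1, per_cluster >= 1)
  if (within_sim <= between_sim) stop("need within_sim > between_sim")
  ## core of size c with s private ids per item: within sim = c / (c + 2 s)
  s_noise <- 1L
  core_sz <- ceiling(within_sim * 2 * s_noise / (1 - within_sim))
  need <- common_core + n_clusters * (core_sz + per_cluster * s_noise)
  if (need > universe) {
    stop("infeasible: need ", need, " ids but universe has ", universe)
  }
  with_seed(seed, {
    ids <- sprintf("t_%d", sample.int(universe))  # shuffled universe
    shared <- if (common_core > 0) ids[seq_len(common_core)] else character()
    pool <- ids[(common_core + 1):length(ids)]
    supports <- list()
    labels <- integer()
    k <- 0
    for (cl in seq_len(n_clusters)) {
      core <- pool[seq_len(core_sz)]; pool <- pool[-seq_len(core_sz)]
      for (it in seq_len(per_cluster)) {
        noise <- pool[seq_len(s_noise)]; pool <- pool[-seq_len(s_noise)]
        k <- k + 1
        supports[[k]] <- c(shared, core, noise)
        labels[k] <- cl
      }
    }
    names(supports) <- sprintf("S%d", seq_along(supports))
    sim <- tanimoto_matrix(supports)
    same <- outer(labels, labels, "==")
    diag(sim) <- NA
    w_min <- if (n_clusters * per_cluster > 1 && any(same & !is.na(sim)))
      min(sim[same], na.rm = TRUE) else 1
    b_max <- if (any(!same)) max(sim[!same]) else 0
    if (w_min < within_sim - 1e-12 || b_max > between_sim + 1e-12) {
      stop("similarity calibration failed: realised within ", w_min,
           ", between ", b_max)
    }
    universe_ids <- sprintf("t_%d", seq_len(universe))
    vec <- do.call(rbind, lapply(supports, function(s)
      as.integer(universe_ids %in% s)))
    invs <- invariant_set(vec, universe_ids, "T", "planted_supports")
    ## map labels onto the canonical invariant order
    key <- vapply(supports, function(s)
      paste(sort(s), collapse = " "), character(1))
    inv_key <- apply(invs$vectors > 0, 1, function(m)
      paste(sort(colnames(invs$vectors)[m]), collapse = " "))
    labels_canon <- labels[match(inv_key, key)]
    structure(list(supports = supports, true_labels = labels,
                   invariants = invs, labels_in_invariant_order = labels_canon,
                   within_sim = w_min, between_sim = b_max, seed = seed),
              class = "planted_supports")
  })
}

#' Random small nets for oracle cross-checks
#'
#' Draws a connected-ish random place/transition net with bounded size and
#' arc weights, used to compare the Farkas computation against brute-force
#' enumeration. Optionally decorates transitions with read-arc side
#' conditions.
#'
#' @param n_places,n_transitions maximum dimensions (at least 1 each).
#' @param max_weight maximum arc weight.
#' @param p_arc probability of each place/transition arc.
#' @param read_arcs number of read pairs to add.
#' @param seed RNG seed.
#' @return a [petri_net()].
#' @export
random_net <- function(n_places = 8L, n_transitions = 8L, max_weight = 2L,
                       p_arc = 0.25, read_arcs = 0L, seed = 1L) {
  with_seed(seed, {
    np <- sample.int(n_places, 1)
    nt <- sample.int(n_transitions, 1)
    p_ids <- sprintf("p_%d", seq_len(np))
    t_ids <- sprintf("t_%d", seq_len(nt))
    src <- list(); tgt <- list(); wt <- list()
    for (p in p_ids) for (t in t_ids) {
      if (stats::runif(1) < p_arc) {
        src[[length(src) + 1]] <- p; tgt[[length(tgt) + 1]] <- t
        wt[[length(wt) + 1]] <- sample.int(max_weight, 1)
      }
      if (stats::runif(1) < p_arc) {
        src[[length(src) + 1]] <- t; tgt[[length(tgt) + 1]] <- p
        wt[[length(wt) + 1]] <- sample.int(max_weight, 1)
      }
    }
    if (length(src) > 0) {
      arcs <- data.frame(source = unlist(src), target = unlist(tgt),
                         weight = unlist(wt), read = FALSE)
    } else {
      arcs <- data.frame(source = p_ids[1], target = t_ids[1],
                         weight = 1L, read = FALSE)
    }
    ## every node takes part in at least one arc (an isolated reaction or
    ## species carries no structure worth testing)
    for (t in setdiff(t_ids, c(arcs$source, arcs$target))) {
      p <- p_ids[sample.int(np, 1)]
      arcs <- rbind(arcs, data.frame(source = p, target = t,
                                     weight = sample.int(max_weight, 1),
                                     read = FALSE))
    }
    for (p in setdiff(p_ids, c(arcs$source, arcs$target))) {
      t <- t_ids[sample.int(nt, 1)]
      arcs <- rbind(arcs, data.frame(source = t, target = p,
                                     weight = sample.int(max_weight, 1),
                                     read = FALSE))
    }
    if (read_arcs > 0) {
      for (e in seq_len(read_arcs)) {
        p <- p_ids[sample.int(np, 1)]
        t <- t_ids[sample.int(nt, 1)]
        key <- paste(arcs$source, arcs$target)
        if (!(paste(p, t) %in% key) && !(paste(t, p) %in% key)) {
          arcs <- rbind(arcs, data.frame(source = c(p, t), target = c(t, p),
                                         weight = 1L, read = TRUE))
        }
      }
    }
    petri_net(data.frame(id = p_ids, tokens = sample(0:2, np, replace = TRUE)),
              data.frame(id = t_ids),
              arcs, name = sprintf("random(s%d)", seed))
  })
}

#' Brute-force minimal invariant enumeration (oracle)
#'
#' Independent reference for the Farkas computation on small systems: every
#' non-negative integer vector with entries up to `max_entry` is tested
#' against the defining linear system directly; solutions are gcd-normalised,
#' deduplicated, and reduced to minimal supports. Exponential in the number
#' of unknowns — intended for nets with at most ~8 transitions and places.
#'
#' @param C incidence matrix (or [incidence()] result, or a flat
#'   [petri_net()]).
#' @param kind `"T"` or `"P"`.
#' @param max_entry largest entry enumerated.
#' @return an [invariant_set()].
#' @export
brute_force_invariants <- function(C, kind = c("T", "P"), max_entry = 4L) {
  kind <- match.arg(kind)
  net_ref <- "matrix"
  if (inherits(C, "petri_net")) {
    net_ref <- C$name
    C <- incidence(C)$C
  } else if (inherits(C, "incidence_matrix")) C <- C$C
  A <- if (kind == "T") C else t(C)      # A %*% x = 0, x over columns of A
  n <- ncol(A)
  ids <- colnames(A)
  if (is.null(ids)) ids <- paste0(if (kind == "T") "t" else "p", seq_len(n))
  grid <- as.matrix(expand.grid(rep(list(0:max_entry), n)))[-1, , drop = FALSE]
  resid <- grid %*% t(A)
  sols <- grid[rowSums(resid != 0) == 0, , drop = FALSE]
  if (nrow(sols) == 0) return(invariant_set(matrix(0, 0, n), ids, kind, net_ref))
  g <- apply(sols, 1, gcd_vec)
  sols <- sols / g
  sols <- sols[!duplicated(apply(sols, 1, paste, collapse = " ")), ,
               drop = FALSE]
  sols <- sols[minimal_support_mask(sols > 0), , drop = FALSE]
  invariant_set(sols, ids, kind, net_ref)
}
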