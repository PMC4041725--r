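#' Incidence matrices of a flattened net
#'
#' Builds the pre- and post-weight matrices and the incidence matrix
#' `C = post - pre` (places in rows, transitions in columns, stored order).
#' A pure side condition (read pair, pre = post) contributes zero to `C` but
#' keeps its weights in `pre`/`post`, so enabling semantics are preserved.
#' `C` houses the linear systems behind invariant analysis: a T-invariant is
#' a non-negative integer `x` with `C x = 0`, a P-invariant a non-negative
#' integer `y` with `t(y) C = 0`.
#'
#' @param net a flattened [petri_net()].
#' @return a list of class `incidence_matrix` with integer matrices `pre`,
#'   `post`, `C`, all dimnamed by place/transition ids.
#' @export
incidence <- function(net) {
  stop_if_not_flat(net, "incidence()")
  p_ids <- net$places$id
  t_ids <- net$transitions$id
  np <- length(p_ids); nt <- length(t_ids)
  pre <- matrix(0L, np, nt, dimnames = list(p_ids, t_ids))
  post <- pre
  a <- net$arcs
  if (nrow(a) > 0) {
    from_p <- a$source %in% p_ids
    if (any(from_p)) {
      idx <- cbind(match(a$source[from_p], p_ids), match(a$target[from_p], t_ids))
      for (k in seq_len(nrow(idx))) {
        pre[idx[k, 1], idx[k, 2]] <- pre[idx[k, 1], idx[k, 2]] + a$weight[from_p][k]
      }
    }
    to_p <- !from_p
    if (any(to_p)) {
      idx <- cbind(match(a$target[to_p], p_ids), match(a$source[to_p], t_ids))
      for (k in seq_len(nrow(idx))) {
        post[idx[k, 1], idx[k, 2]] <- post[idx[k, 1], idx[k, 2]] + a$weight[to_p][k]
      }
    }
  }
  structure(list(pre = pre, post = post, C = post - pre),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", nrow(x$C), " places x ", ncol(x$C),
      " transitions\n", sep = "")
  invisible(x)
}

#' Flatten a hierarchical net
#'
#' Removes macro (coarse) transitions, which are presentation containers and
#' never fire, and merges all logical copies of a place into a single place
#' carrying the union of the copies' arcs. Duplicate arcs arising from the
#' merge have their weights summed (with a warning). The result has hierarchy
#' depth 0 and no logical flags; flattening a flat net is the identity.
#'
#' @param net a [petri_net()] with hierarchy depth at most 2.
#' @param max_depth maximum tolerated macro nesting depth.
#' @return a flattened [petri_net()].
#' @export
flatten <- function(net, max_depth = 2L) {
  d <- hierarchy_depth(net)
  if (d > max_depth) {
    stop("macro nesting depth ", d, " exceeds declared maximum ", max_depth)
  }
  t <- net$transitions
  keep <- t$kind != "macro"
  t <- t[keep, , drop = FALSE]
  t$parent <- NA_character_

  p <- net$places
  a <- net$arcs
  if (any(p$is_logical)) {
    ## logical copies share a name; the representative keeps the first id
    for (nm in unique(p$name[p$is_logical])) {
      copies <- p$id[p$name == nm]
      if (length(copies) < 2 && sum(p$is_logical & p$name == nm) > 0 &&
          length(copies) == 1) {
        ## a single flagged copy: just clear the flag below
        next
      }
      rep_id <- copies[1]
      a$source[a$source %in% copies] <- rep_id
      a$target[a$target %in% copies] <- rep_id
      tok <- sum(p$tokens[p$id %in% copies])
      p <- p[!(p$id %in% copies[-1]), , drop = FALSE]
      p$tokens[p$id == rep_id] <- tok
    }
    p$is_logical <- FALSE
  }
  ## drop arcs that touched macro containers (children carry the semantics)
  macro_ids <- net$transitions$id[net$transitions$kind == "macro"]
  if (length(macro_ids) > 0) {
    a <- a[!(a$source %in% macro_ids) & !(a$target %in% macro_ids), ,
           drop = FALSE]
  }
  ## merge duplicate arcs created by logical-node merging
  if (nrow(a) > 0) {
    key <- paste(a$source, a$target, a$read, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate arcs after flattening; weights summed")
      w <- tapply(a$weight, key, sum)
      a <- a[!duplicated(key), , drop = FALSE]
      a$weight <- as.integer(w[paste(a$source, a$target, a$read, sep = "\r")])
    }
  }
  petri_net(p, t, a, name = net$name)
}

#' Fire a transition (token game)
#'
#' Standard token-game semantics: `t` is enabled under `m` when every
#' pre-place holds at least the pre-arc weight (read pairs included); firing
#' consumes pre-weights and produces post-weights. Side-condition tokens are
#' returned unchanged.
#'
#' @param net a flattened [petri_net()].
#' @param m a named marking vector (see [initial_marking()]).
#' @param t a transition id.
#' @param inc optional precomputed [incidence()] of `net`.
#' @return the successor marking.
#' @export
fire <- function(net, m, t, inc = incidence(net)) {
  j <- match(t, colnames(inc$pre))
  if (is.na(j)) stop("unknown transition: ", t)
  m <- m[rownames(inc$pre)]
  need <- inc$pre[, j]
  lack <- which(m < need)
  if (length(lack) > 0) {
    stop("transition ", t, " is not enabled; deficient place(s): ",
         paste(rownames(inc$pre)[lack], " (", m[lack], " < ", need[lack], ")",
               sep = "", collapse = ", "))
  }
  m2 <- m - need + inc$post[, j]
  stopifnot(all(m2 >= 0))
  m2
}

#' Transitions enabled under a marking
#'
#' @inheritParams fire
#' @return a character vector of enabled transition ids.
#' @export
enabled_transitions <- function(net, m, inc = incidence(net)) {
  m <- m[rownames(inc$pre)]
  colnames(inc$pre)[colSums(inc$pre > m) == 0]
}

#' Structural validity report
#'
#' Checks the structural criteria used to judge a biological net plausible:
#' the (undirected) bipartite graph is connected; every place is homogeneous
#' (all of its outgoing arcs carry the same weight); and every place has both
#' a pre-transition and a post-transition. Boundary (input/output) transitions
#' model the system interface and are listed separately for reference.
#'
#' @param net a flattened, non-empty [petri_net()].
#' @return a list of class `structure_report` with booleans `connected`,
#'   `homogeneous`, `every_place_has_pre_and_post`, violation lists, and the
#'   ids of boundary interface transitions.
#' @export
validate_structure <- function(net) {
  stop_if_not_flat(net, "validate_structure()")
  if (nrow(net$places) == 0 || nrow(net$transitions) == 0) {
    stop("empty net")
  }
  a <- net$arcs
  g <- igraph::graph_from_data_frame(
    a[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = c(net$places$id, net$transitions$id))
  )
  connected <- igraph::is_connected(g)

  out_by_place <- split(a$weight[a$source %in% net$places$id],
                        a$source[a$source %in% net$places$id])
  inhomog <- names(out_by_place)[vapply(out_by_place,
                                        function(w) length(unique(w)) > 1,
                                        logical(1))]

  has_post <- net$places$id %in% a$source  # place -> transition
  has_pre <- net$places$id %in% a$target   # transition -> place
  missing_pre_post <- net$places$id[!(has_post & has_pre)]

  inc <- incidence(net)
  boundary <- colnames(inc$pre)[colSums(inc$pre) == 0 | colSums(inc$post) == 0]

  structure(list(
    connected = connected,
    homogeneous = length(inhomog) == 0,
    every_place_has_pre_and_post = length(missing_pre_post) == 0,
    inhomogeneous_places = inhomog,
    places_missing_pre_or_post = missing_pre_post,
    boundary_transitions = boundary,
    n_components = igraph::count_components(g)
  ), class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  cat("  connected:                   ", x$connected, "\n")
  cat("  homogeneous:                 ", x$homogeneous, "\n")
  cat("  every place has pre & post:  ", x$every_place_has_pre_and_post, "\n")
  cat("  boundary transitions:        ", length(x$boundary_transitions), "\n")
  invisible(x)
}
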