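#' Construct a place/transition Petri net
#'
#' A standard qualitative Petri net: a bipartite directed multigraph of places
#' (molecular species, complexes, pools) and transitions (reactions, complex
#' formation, transport), connected by weighted arcs. Read-arc side conditions
#' (an enzyme or cofactor that is required but not consumed) are stored as an
#' ordinary pre-arc plus post-arc of equal weight, both flagged `read`, so
#' that enabling still requires the tokens while the incidence contribution
#' cancels exactly. Hierarchical models may contain macro (coarse) transitions
#' that group a sub-network for presentation and never fire themselves, and
#' logical places (copies of a shared node such as ATP, drawn several times);
#' both are removed by [flatten()] before analysis.
#'
#' @param places data frame with columns `id`, and optionally `name`
#'   (free text, defaults to `id`), `is_logical` (logical, default `FALSE`),
#'   `tokens` (non-negative integer initial marking, default 0).
#' @param transitions data frame with columns `id`, and optionally `name`,
#'   `kind` (one of `"internal"`, `"input"`, `"output"`, `"macro"`; default
#'   `"internal"`), `parent` (id of the enclosing macro transition, `NA` for
#'   top level).
#' @param arcs data frame with columns `source`, `target`, and optionally
#'   `weight` (positive integer, default 1) and `read` (logical, default
#'   `FALSE`, marking one half of a double arc).
#' @param name model name used in reports.
#' @return an object of class `petri_net`.
#' @examples
#' net <- petri_net(
#'   places = data.frame(id = c("A", "B"), tokens = c(1, 0)),
#'   transitions = data.frame(id = c("t_f", "t_b")),
#'   arcs = data.frame(source = c("A", "t_f", "B", "t_b"),
#'                     target = c("t_f", "B", "t_b", "A"))
#' )
#' net
#' @export
petri_net <- function(places, transitions, arcs, name = "net") {
  places <- as.data.frame(places, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)

  np <- nrow(places); nt <- nrow(transitions)
  if (is.null(places$name)) places$name <- places$id
  if (is.null(places$is_logical)) places$is_logical <- rep(FALSE, np)
  if (is.null(places$tokens)) places$tokens <- rep(0L, np)
  places$tokens <- as.integer(places$tokens)
  if (is.null(transitions$name)) transitions$name <- transitions$id
  if (is.null(transitions$kind)) transitions$kind <- rep("internal", nt)
  if (is.null(transitions$parent)) {
    transitions$parent <- rep(NA_character_, nt)
  }
  if (nrow(arcs) > 0) {
    if (is.null(arcs$weight)) arcs$weight <- 1L
    arcs$weight[is.na(arcs$weight)] <- 1L  # files may omit weights
    arcs$weight <- as.integer(arcs$weight)
    if (is.null(arcs$read)) arcs$read <- FALSE
  } else {
    arcs <- data.frame(source = character(), target = character(),
                       weight = integer(), read = logical())
  }

  places <- places[, c("id", "name", "is_logical", "tokens")]
  transitions <- transitions[, c("id", "name", "kind", "parent")]
  arcs <- arcs[, c("source", "target", "weight", "read")]

  net <- structure(
    list(places = places, transitions = transitions, arcs = arcs, name = name),
    class = "petri_net"
  )
  validate_petri_net(net)
  net
}

validate_petri_net <- function(net) {
  p <- net$places; t <- net$transitions; a <- net$arcs
  dup_p <- duplicated(p$id[!p$is_logical])
  if (any(dup_p)) {
    stop("duplicate non-logical place ids: ",
         paste(unique(p$id[!p$is_logical][dup_p]), collapse = ", "))
  }
  if (anyDuplicated(t$id)) {
    stop("duplicate transition ids: ",
         paste(unique(t$id[duplicated(t$id)]), collapse = ", "))
  }
  shared <- intersect(p$id, t$id)
  if (length(shared) > 0) {
    stop("place and transition id namespaces overlap: ",
         paste(shared, collapse = ", "))
  }
  if (any(p$tokens < 0)) stop("negative initial tokens")
  if (nrow(a) > 0) {
    if (any(a$weight < 1)) stop("arc weights must be >= 1")
    src_is_p <- a$source %in% p$id
    src_is_t <- a$source %in% t$id
    tgt_is_p <- a$target %in% p$id
    tgt_is_t <- a$target %in% t$id
    dangling <- !((src_is_p | src_is_t) & (tgt_is_p | tgt_is_t))
    if (any(dangling)) {
      bad <- unique(c(a$source[!src_is_p & !src_is_t],
                      a$target[!tgt_is_p & !tgt_is_t]))
      stop("dangling arc endpoint(s): ", paste(bad, collapse = ", "))
    }
    bad_pair <- (src_is_p & tgt_is_p) | (src_is_t & tgt_is_t)
    if (any(bad_pair)) {
      stop("arcs must connect a place and a transition (bipartite); offending: ",
           paste(paste(a$source[bad_pair], a$target[bad_pair], sep = "->"),
                 collapse = ", "))
    }
  }
  bad_parent <- !is.na(t$parent) & !(t$parent %in% t$id[t$kind == "macro"])
  if (any(bad_parent)) {
    stop("transition parent is not a macro transition: ",
         paste(t$id[bad_parent], collapse = ", "))
  }
  invisible(net)
}

#' @export
print.petri_net <- function(x, ...) {
  n_macro <- sum(x$transitions$kind == "macro")
  n_log <- sum(x$places$is_logical)
  cat("<petri_net> ", x$name, "\n", sep = "")
  cat("  places:      ", nrow(x$places),
      if (n_log > 0) paste0(" (", n_log, " logical copies)"), "\n", sep = "")
  cat("  transitions: ", nrow(x$transitions),
      if (n_macro > 0) paste0(" (", n_macro, " macro)"), "\n", sep = "")
  cat("  arcs:        ", nrow(x$arcs),
      " (", sum(x$arcs$read), " in read pairs)\n", sep = "")
  invisible(x)
}

#' Hierarchy depth of a net
#'
#' Number of macro-nesting levels (0 for a flat net).
#'
#' @param net a [petri_net()].
#' @return a non-negative integer.
#' @export
hierarchy_depth <- function(net) {
  t <- net$transitions
  depth_of <- function(id, seen = character()) {
    if (id %in% seen) stop("macro nesting cycle at ", id)
    par <- t$parent[match(id, t$id)]
    if (is.na(par)) 0L else 1L + depth_of(par, c(seen, id))
  }
  if (nrow(t) == 0) return(0L)
  max(vapply(t$id, depth_of, integer(1)))
}

#' Initial marking of a net
#'
#' @param net a [petri_net()].
#' @return a named integer vector of token counts, one entry per place.
#' @export
initial_marking <- function(net) {
  stats::setNames(as.integer(net$places$tokens), net$places$id)
}

## TRUE for the flattened form expected by the analysis layer.
is_flat <- function(net) {
  !any(net$transitions$kind == "macro") && !any(net$places$is_logical)
}

stop_if_not_flat <- function(net, what) {
  macros <- net$transitions$id[net$transitions$kind == "macro"]
  logicals <- unique(net$places$id[net$places$is_logical])
  if (length(macros) > 0 || length(logicals) > 0) {
    stop(what, " requires a flattened net; offending macro transition(s): ",
         paste(macros, collapse = ", "), "; logical place(s): ",
         paste(logicals, collapse = ", "), call. = FALSE)
  }
  invisible(net)
}
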