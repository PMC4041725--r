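#' Minimal semi-positive invariants by Farkas elimination
#'
#' Computes the complete set of support-minimal, gcd-normalised, non-negative
#' integer solutions of `C x = 0` (T-invariants) or `t(y) C = 0`
#' (P-invariants) with exact integer arithmetic. The classical Farkas
#' (Fourier-Motzkin column) elimination is used: starting from `[t(C) | I]`,
#' constraint columns are eliminated one at a time in ascending density
#' order, combining positive and negative rows pairwise, gcd-reducing each
#' new row and pruning rows whose support strictly contains another row's
#' support at every step. The output order is deterministic (lexicographic by
#' sorted support).
#'
#' @param C an incidence matrix (the `C` component of [incidence()]), or an
#'   `incidence_matrix` object, or a [petri_net()] which is then flattened
#'   implicitly only if already flat.
#' @param kind `"T"` or `"P"`.
#' @return an [invariant_set()].
#' @seealso [minimal_t_invariants()], [minimal_p_invariants()]
#' @export
minimal_invariants <- function(C, kind = c("T", "P")) {
  kind <- match.arg(kind)
  net_ref <- "matrix"
  if (inherits(C, "petri_net")) {
    net_ref <- C$name
    C <- incidence(C)$C
  } else if (inherits(C, "incidence_matrix")) {
    C <- C$C
  }
  A <- if (kind == "T") t(C) else C  # rows = unknowns, columns = constraints
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0(if (kind == "T") "t" else "p", seq_len(nrow(A)))
  vecs <- farkas(A)
  invariant_set(vecs, ids, kind = kind, net_ref = net_ref)
}

#' @rdname minimal_invariants
#' @param net a flattened [petri_net()] or an incidence matrix.
#' @export
minimal_t_invariants <- function(net) minimal_invariants(net, "T")

#' @rdname minimal_invariants
#' @export
minimal_p_invariants <- function(net) minimal_invariants(net, "P")

## Farkas elimination on A (n unknowns x m constraints): returns the matrix
## of minimal semi-positive solutions x (rows) of t(A) x = 0 ... precisely,
## of x^T A = 0 with x >= 0.
farkas <- function(A) {
  n <- nrow(A)
  m <- ncol(A)
  Tm <- cbind(A, diag(n))  # working tableau: [constraints | solution part]
  ## eliminate constraint columns in ascending non-zero-density order
  dens <- colSums(A != 0)
  for (j in order(dens)) {
    col <- Tm[, j]
    pos <- which(col > 0)
    neg <- which(col < 0)
    zer <- which(col == 0)
    keep <- Tm[zer, , drop = FALSE]
    if (length(pos) > 0 && length(neg) > 0) {
      pp <- rep(pos, each = length(neg))
      nn <- rep(neg, times = length(pos))
      a <- col[pp]
      b <- -col[nn]
      g <- mapply(gcd2, a, b)
      ## row i of the new block: (b/g)_i * row(pos_i) + (a/g)_i * row(neg_i)
      new_rows <- Tm[pp, , drop = FALSE] * (b / g) +
        Tm[nn, , drop = FALSE] * (a / g)
      keep <- rbind(keep, new_rows)
    }
    if (nrow(keep) == 0) {
      Tm <- keep
      break
    }
    ## gcd-normalise every row
    sol <- keep[, (m + 1):(m + n), drop = FALSE]
    g <- apply(cbind(abs(keep), 0), 1, gcd_vec)
    g[g == 0] <- 1
    keep <- keep / g
    ## prune: drop duplicates and rows whose support strictly contains
    ## another row's support (they cannot lead to minimal invariants)
    sol <- keep[, (m + 1):(m + n), drop = FALSE]
    supp <- sol > 0
    ord <- order(rowSums(supp))
    keep <- keep[ord, , drop = FALSE]
    supp <- supp[ord, , drop = FALSE]
    dup <- duplicated(apply(keep, 1, paste, collapse = " "))
    keep <- keep[!dup, , drop = FALSE]
    supp <- supp[!dup, , drop = FALSE]
    keep <- keep[minimal_support_mask(supp), , drop = FALSE]
    Tm <- keep
  }
  if (nrow(Tm) == 0) {
    return(matrix(0, 0, n))
  }
  sol <- Tm[, (m + 1):(m + n), drop = FALSE]
  zeroed <- rowSums(abs(Tm[, seq_len(m), drop = FALSE])) == 0
  sol <- sol[zeroed & rowSums(sol) > 0, , drop = FALSE]
  if (nrow(sol) == 0) return(matrix(0, 0, n))
  ## final minimality + normalisation (idempotent after the stepwise pruning)
  g <- apply(sol, 1, gcd_vec)
  sol <- sol / g
  supp <- sol > 0
  keep <- minimal_support_mask(supp)
  sol <- sol[keep, , drop = FALSE]
  sol[!duplicated(apply(sol, 1, paste, collapse = " ")), , drop = FALSE]
}

## TRUE for rows whose support does not strictly contain any other row's
## support. `supp` is a logical matrix (rows = candidates). Greedy pass in
## ascending support-size order: a candidate survives unless a strictly
## smaller surviving support is contained in it, so the kept set stays small
## even when the candidate list is huge.
minimal_support_mask <- function(supp) {
  k <- nrow(supp)
  if (k <= 1) return(rep(TRUE, k))
  sz <- rowSums(supp)
  ord <- order(sz)
  n <- ncol(supp)
  kept <- matrix(0, 0, n)
  kept_sz <- numeric(0)
  res <- logical(k)
  for (i in ord) {
    s <- supp[i, ]
    ok <- TRUE
    if (nrow(kept) > 0) {
      outside <- kept %*% (1 - s)      # |kept_j \ s|
      if (any(outside == 0 & kept_sz < sz[i])) ok <- FALSE
    }
    res[i] <- ok
    if (ok) {
      kept <- rbind(kept, s * 1)
      kept_sz <- c(kept_sz, sz[i])
    }
  }
  res
}

#' Invariant sets
#'
#' Container for a set of minimal semi-positive invariants over a fixed,
#' ordered id universe (transitions for kind T, places for kind P). Vectors
#' are stored as the rows of an integer matrix; the support of an invariant
#' is the set of ids with a positive entry.
#'
#' @param vectors numeric matrix, one invariant per row, columns in `ids`
#'   order.
#' @param ids character vector naming the columns.
#' @param kind `"T"` or `"P"`.
#' @param net_ref identifier of the analysed net.
#' @return an object of class `invariant_set` with elements `kind`, `ids`,
#'   `vectors` (named, deterministically ordered), `trivial` (logical flag
#'   per invariant, all `FALSE` until [classify_trivial()] is applied) and
#'   `net_ref`.
#' @export
invariant_set <- function(vectors, ids, kind = c("T", "P"), net_ref = "net") {
  kind <- match.arg(kind)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) > 0) {
    colnames(vectors) <- ids
    ## deterministic order: lexicographic by sorted support pattern
    key <- apply(vectors > 0, 1, function(s) paste(ids[s], collapse = " "))
    ord <- order(rowSums(vectors > 0), key)
    vectors <- vectors[ord, , drop = FALSE]
    rownames(vectors) <- sprintf("%sInv_%d", kind, seq_len(nrow(vectors)))
  } else {
    vectors <- matrix(0, 0, length(ids), dimnames = list(NULL, ids))
  }
  structure(list(kind = kind, ids = ids, vectors = vectors,
                 trivial = rep(FALSE, nrow(vectors)), net_ref = net_ref),
            class = "invariant_set")
}

#' @export
print.invariant_set <- function(x, ...) {
  cat("<invariant_set> kind ", x$kind, ", ", nrow(x$vectors), " invariants (",
      sum(x$trivial), " trivial) over ", length(x$ids), " ",
      if (x$kind == "T") "transitions" else "places",
      " [", x$net_ref, "]\n", sep = "")
  invisible(x)
}

#' @export
length.invariant_set <- function(x) nrow(x$vectors)

#' Supports of an invariant set
#'
#' @param invs an [invariant_set()].
#' @param non_trivial_only drop invariants flagged trivial.
#' @return a named list of character vectors (ids with positive entry).
#' @export
invariant_supports <- function(invs, non_trivial_only = FALSE) {
  v <- invs$vectors
  keep <- if (non_trivial_only) !invs$trivial else rep(TRUE, nrow(v))
  v <- v[keep, , drop = FALSE]
  lapply(stats::setNames(seq_len(nrow(v)), rownames(v)),
         function(i) colnames(v)[v[i, ] > 0])
}

#' Flag trivial invariants
#'
#' A trivial T-invariant is a forward/backward reaction pair (support size at
#' most 2, covering the degenerate single-transition case of an all-zero
#' incidence column); a trivial P-invariant is a single place attached only
#' through double arcs (support size 1). Trivial invariants are excluded from
#' clustering and MCTS analysis downstream.
#'
#' @param invs an [invariant_set()].
#' @return the set with the `trivial` flags populated.
#' @export
classify_trivial <- function(invs) {
  sz <- rowSums(invs$vectors > 0)
  invs$trivial <- if (invs$kind == "T") sz <= 2 else sz <= 1
  if (invs$kind == "T" && any(sz == 1)) {
    message("degenerate single-transition T-invariant(s) flagged trivial")
  }
  invs
}

#' Invariant coverage of a net
#'
#' A biologically plausible model should be covered by T-invariants: every
#' transition lies in the support of at least one invariant (trivial ones
#' count). The same check applies to places and P-invariants.
#'
#' @param net the flattened [petri_net()] the invariants were computed on.
#' @param invs an [invariant_set()] for that net.
#' @return a list with `covered` (boolean) and `uncovered` (ids).
#' @export
coverage <- function(net, invs) {
  universe <- if (invs$kind == "T") net$transitions$id else net$places$id
  if (!setequal(universe, invs$ids)) {
    stop("invariant set does not match the net's ",
         if (invs$kind == "T") "transitions" else "places")
  }
  hit <- colnames(invs$vectors)[colSums(invs$vectors > 0) > 0]
  uncovered <- setdiff(universe, hit)
  list(covered = length(uncovered) == 0, uncovered = sort_ids(uncovered))
}

#' Transition occurrence in non-trivial T-invariants
#'
#' For each transition occurring in at least one non-trivial T-invariant, the
#' count of non-trivial invariants containing it and the percentage of the
#' non-trivial total (rounded half-up to 3 decimals), sorted descending by
#' percentage with ties broken by id.
#'
#' @param invs a T-kind [invariant_set()] with trivial flags set (see
#'   [classify_trivial()]).
#' @return a data frame with columns `transition`, `count`, `percentage`.
#' @export
occurrence_table <- function(invs) {
  stopifnot(invs$kind == "T")
  v <- invs$vectors[!invs$trivial, , drop = FALSE]
  total <- nrow(v)
  if (total == 0) {
    return(data.frame(transition = character(), count = integer(),
                      percentage = numeric()))
  }
  count <- colSums(v > 0)
  tab <- data.frame(transition = names(count), count = as.integer(count),
                    percentage = round_half_up(100 * count / total, 3),
                    row.names = NULL)
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab <- tab[order(-tab$percentage, rank_ids(tab$transition)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## numeric rank of ids under the t_<n> ordering, for tie-breaks
rank_ids <- function(ids) {
  r <- integer(length(ids))
  r[order_ids(ids)] <- seq_along(ids)
  r
}

#' Verify that every invariant satisfies its linear system
#'
#' Soundness assertion used throughout the tests: for kind T, `C x = 0`
#' exactly; for kind P, `t(y) C = 0` exactly.
#'
#' @param invs an [invariant_set()].
#' @param C the incidence matrix of the net.
#' @return `TRUE` (invisibly), or an error.
#' @export
assert_invariants_sound <- function(invs, C) {
  if (inherits(C, "incidence_matrix")) C <- C$C
  if (nrow(invs$vectors) == 0) return(invisible(TRUE))
  resid <- if (invs$kind == "T") {
    C[, invs$ids, drop = FALSE] %*% t(invs$vectors)
  } else {
    invs$vectors %*% C[invs$ids, , drop = FALSE]
  }
  if (any(resid != 0)) stop("invariant set violates its defining system")
  g <- apply(invs$vectors, 1, gcd_vec)
  if (any(g != 1)) stop("invariant vector not gcd-normalised")
  invisible(TRUE)
}
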