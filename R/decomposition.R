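#' Tanimoto coefficient of two support sets
#'
#' `|a intersect b| / |a union b|`, the similarity measure used to group
#' T-invariants whose supports overlap.
#'
#' @param a,b non-empty character vectors (supports).
#' @return a number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty support set")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

## Pairwise Tanimoto similarity matrix of a list of supports, via the
## binary membership matrix (exact: integer intersections / unions).
tanimoto_matrix <- function(supports) {
  ids <- sort(unique(unlist(supports)))
  M <- vapply(supports, function(s) ids %in% s, logical(length(ids))) * 1
  inter <- crossprod(M)              # |a & b|
  sz <- colSums(M)
  uni <- outer(sz, sz, "+") - inter  # |a | b|
  sim <- inter / uni
  dimnames(sim) <- list(names(supports), names(supports))
  sim
}

#' Cluster non-trivial T-invariants by support similarity
#'
#' Groups non-trivial T-invariants whose supports are similar, so that each
#' cluster collects variants of the same biological pathway. Two modes are
#' provided, because a "65% similarity threshold" can be read two ways:
#' `"dendrogram"` (default) performs agglomerative clustering on the distance
#' `1 - tanimoto` and cuts the tree at distance `1 - threshold`;
#' `"pairwise"` links every pair with similarity `>= threshold` directly and
#' takes connected components. Both are deterministic for a fixed input
#' order (invariant sets order their invariants canonically).
#'
#' @param invs a T-kind [invariant_set()]; trivial invariants are flagged via
#'   [classify_trivial()] and excluded.
#' @param threshold similarity cut in `(0, 1]`.
#' @param linkage agglomeration method for the dendrogram mode
#'   (`"average"`, `"single"` or `"complete"`).
#' @param mode `"dendrogram"` or `"pairwise"`.
#' @return a list of class `invariant_clustering`: `clusters` (named list of
#'   invariant-id vectors, sorted by size descending then smallest member),
#'   `threshold`, `linkage`, `mode`, `similarity` (the pairwise matrix).
#' @export
cluster_invariants <- function(invs, threshold = 0.65,
                               linkage = c("average", "single", "complete"),
                               mode = c("dendrogram", "pairwise")) {
  linkage <- match.arg(linkage)
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  invs <- if (any(invs$trivial)) invs else classify_trivial(invs)
  supports <- invariant_supports(invs, non_trivial_only = TRUE)
  if (length(supports) == 0) stop("no non-trivial invariants to cluster")

  if (length(supports) == 1) {
    membership <- stats::setNames(1L, names(supports))
    sim <- matrix(1, 1, 1, dimnames = list(names(supports), names(supports)))
  } else {
    sim <- tanimoto_matrix(supports)
    if (mode == "pairwise") {
      g <- igraph::graph_from_adjacency_matrix(sim >= threshold,
                                               mode = "undirected",
                                               diag = FALSE)
      membership <- igraph::components(g)$membership
      names(membership) <- names(supports)
    } else {
      hc <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
      ## average/single/complete linkage is monotone; clamp the tiny
      ## floating-point height inversions that tied merges can produce
      hc$height <- cummax(hc$height)
      membership <- stats::cutree(hc, h = 1 - threshold)
    }
  }
  groups <- split(names(membership), membership)
  sizes <- lengths(groups)
  first <- vapply(groups, function(g) min(rank_ids(g)), numeric(1))
  groups <- groups[order(-sizes, first)]
  names(groups) <- paste0("C", seq_along(groups))
  structure(list(clusters = groups, threshold = threshold, linkage = linkage,
                 mode = mode, similarity = sim, net_ref = invs$net_ref),
            class = "invariant_clustering")
}

#' @export
print.invariant_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("<invariant_clustering> ", length(x$clusters), " clusters of ",
      sum(sizes), " invariants (threshold ", x$threshold, ", ", x$mode,
      if (x$mode == "dendrogram") paste0("/", x$linkage), ")\n", sep = "")
  cat("  sizes: ", paste(sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Maximal common transition sets (MCTS)
#'
#' Partitions transitions into maximal classes whose members occur in exactly
#' the same non-trivial T-invariants — the disjoint building blocks of the
#' network: reactions that always operate together at steady state, whether
#' or not they are adjacent. Classes of size two or more are numbered
#' M1, M2, ... in order of their smallest member id; single-transition
#' classes are reported as singletons; transitions occurring in no
#' non-trivial invariant are listed separately as excluded.
#'
#' @param invs a T-kind [invariant_set()] (trivial invariants are excluded,
#'   flags are computed if absent).
#' @return a list of class `mcts_partition` with `sets` (named list, the
#'   non-trivial classes), `singletons`, `excluded` and `pattern` (the
#'   invariant-membership matrix used).
#' @export
mcts <- function(invs) {
  stopifnot(invs$kind == "T")
  invs <- if (any(invs$trivial)) invs else classify_trivial(invs)
  v <- invs$vectors[!invs$trivial, , drop = FALSE]
  member <- v > 0                     # invariants x transitions
  in_any <- colSums(member) > 0
  excluded <- colnames(member)[!in_any]
  member <- member[, in_any, drop = FALSE]
  pattern <- apply(member, 2, paste, collapse = "")
  classes <- split(colnames(member), pattern)
  classes <- lapply(classes, sort_ids)
  sizes <- lengths(classes)
  nontriv <- classes[sizes >= 2]
  ## number M1, M2, ... by smallest member id
  first <- vapply(nontriv, function(g) min(match(g, sort_ids(colnames(member)))),
                  numeric(1))
  nontriv <- nontriv[order(first)]
  names(nontriv) <- paste0("M", seq_along(nontriv))
  singletons <- sort_ids(unlist(classes[sizes == 1], use.names = FALSE))
  structure(list(sets = nontriv, singletons = singletons,
                 excluded = sort_ids(excluded),
                 membership = member, net_ref = invs$net_ref),
            class = "mcts_partition")
}

#' @export
print.mcts_partition <- function(x, ...) {
  cat("<mcts_partition> ", length(x$sets), " non-trivial sets, ",
      length(x$singletons), " singletons, ", length(x$excluded),
      " excluded transitions\n", sep = "")
  invisible(x)
}

#' Cluster x MCTS coverage table
#'
#' For every MCTS (and every singleton transition) the number of non-trivial
#' T-invariants whose support contains all of its members, overall and per
#' cluster. A highly covered set is shared by many pathway variants and is
#' therefore central to the network's behaviour.
#'
#' @param invs the T-kind [invariant_set()] behind both decompositions.
#' @param part an [mcts()] partition of the same set.
#' @param clust an optional [cluster_invariants()] clustering of the same
#'   set; when supplied a per-cluster breakdown is included.
#' @return a data frame with columns `set`, `size`, `count` and (with a
#'   clustering) one column per cluster.
#' @export
coverage_table <- function(invs, part, clust = NULL) {
  stopifnot(invs$kind == "T")
  invs <- if (any(invs$trivial)) invs else classify_trivial(invs)
  v <- invs$vectors[!invs$trivial, , drop = FALSE]
  if (!identical(sort(colnames(part$membership)),
                 sort(intersect(invs$ids, colnames(part$membership))))) {
    stop("MCTS partition does not stem from this invariant set")
  }
  units <- c(part$sets, stats::setNames(as.list(part$singletons),
                                        part$singletons))
  contains_all <- vapply(units, function(g) {
    rowSums(v[, g, drop = FALSE] > 0) == length(g)
  }, logical(nrow(v)))
  if (nrow(v) == 1) contains_all <- matrix(contains_all, nrow = 1,
                                           dimnames = list(rownames(v), names(units)))
  tab <- data.frame(set = names(units), size = lengths(units),
                    count = colSums(contains_all), row.names = NULL)
  if (!is.null(clust)) {
    if (!all(unlist(clust$clusters) %in% rownames(v))) {
      stop("clustering does not stem from this invariant set")
    }
    for (cn in names(clust$clusters)) {
      rows <- rownames(v) %in% clust$clusters[[cn]]
      tab[[cn]] <- colSums(contains_all[rows, , drop = FALSE])
    }
  }
  tab[order(-tab$count, rank_ids(tab$set)), , drop = FALSE]
}

#' Sweep clustering modes, linkages and thresholds
#'
#' Since a similarity threshold can either cut an agglomerative dendrogram or
#' link pairs directly, and the linkage itself is a free choice, this helper
#' tabulates the resulting number of clusters across all combinations so a
#' model's reported cluster count can be reconciled empirically.
#'
#' @param invs a T-kind [invariant_set()].
#' @param thresholds similarity thresholds to sweep.
#' @return a data frame: `mode`, `linkage`, `threshold`, `n_clusters`,
#'   `n_multi` (clusters with more than one member), `largest`.
#' @export
clustering_mode_sweep <- function(invs, thresholds = c(0.5, 0.65, 0.8)) {
  rows <- list()
  for (th in thresholds) {
    for (mode in c("dendrogram", "pairwise")) {
      linkages <- if (mode == "dendrogram")
        c("average", "single", "complete") else "components"
      for (lk in linkages) {
        cl <- if (mode == "dendrogram") {
          cluster_invariants(invs, th, linkage = lk, mode = mode)
        } else cluster_invariants(invs, th, mode = mode)
        sizes <- lengths(cl$clusters)
        rows[[length(rows) + 1]] <- data.frame(
          mode = mode, linkage = lk, threshold = th,
          n_clusters = length(sizes), n_multi = sum(sizes > 1),
          largest = max(sizes))
      }
    }
  }
  do.call(rbind, rows)
}
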