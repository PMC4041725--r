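#' Seeded token-game simulation
#'
#' Sequential single-transition semantics, matching the animation semantics
#' used for visual inspection of signalling models: at every step one
#' transition is drawn uniformly at random among the enabled ones and fired;
#' the run stops at `max_steps` or in a dead state. Identical
#' `(net, m0, max_steps, seed)` give identical traces; the caller's RNG state
#' is left untouched.
#'
#' @param net a flattened [petri_net()].
#' @param m0 initial marking (default [initial_marking()] of the net).
#' @param max_steps maximum number of firings.
#' @param seed integer RNG seed.
#' @param record `"full"` stores the fired transition and marking at every
#'   step; `"sampled"` stores markings every `sample_every` steps only;
#'   `"none"` keeps only the summary statistics.
#' @param sample_every sampling stride for `record = "sampled"`.
#' @return an object of class `simulation_trace`: `seed`, `n_steps`,
#'   `stop_reason` (`"max_steps"` or `"dead state"`), `fired_counts`,
#'   `ever_enabled` (logical per transition), `final_marking`, and the
#'   recorded `steps` / `markings` depending on `record`.
#' @export
simulate_net <- function(net, m0 = initial_marking(net), max_steps = 5000L,
                         seed = 1L, record = c("full", "sampled", "none"),
                         sample_every = 50L) {
  record <- match.arg(record)
  stop_if_not_flat(net, "simulate_net()")
  stopifnot(max_steps >= 1)
  inc <- incidence(net)
  m <- m0[rownames(inc$pre)]
  if (anyNA(m)) stop("marking does not cover every place")
  if (any(m < 0)) stop("negative token count in initial marking")
  t_ids <- colnames(inc$pre)
  nt <- length(t_ids)
  fired_counts <- stats::setNames(integer(nt), t_ids)
  ever_enabled <- stats::setNames(logical(nt), t_ids)
  fired_seq <- if (record == "full") character(max_steps) else NULL
  markings <- if (record == "full") {
    matrix(NA_integer_, nrow = max_steps, ncol = length(m),
           dimnames = list(NULL, names(m)))
  } else if (record == "sampled") {
    matrix(NA_integer_, nrow = floor(max_steps / sample_every) + 1,
           ncol = length(m), dimnames = list(NULL, names(m)))
  } else NULL
  if (record == "sampled") markings[1, ] <- m

  pre <- inc$pre; delta <- inc$C
  steps_done <- 0L
  stop_reason <- "max_steps"
  with_seed(seed, {
    for (step in seq_len(max_steps)) {
      enabled <- which(colSums(pre > m) == 0)
      if (length(enabled) > 0) ever_enabled[enabled] <- TRUE
      if (length(enabled) == 0) {
        stop_reason <- "dead state"
        break
      }
      j <- enabled[sample.int(length(enabled), 1L)]
      m <- m + delta[, j]
      if (any(m < 0)) stop("negative token count after firing ", t_ids[j])
      fired_counts[j] <- fired_counts[j] + 1L
      steps_done <- step
      if (record == "full") {
        fired_seq[step] <- t_ids[j]
        markings[step, ] <- m
      } else if (record == "sampled" && step %% sample_every == 0) {
        markings[step / sample_every + 1, ] <- m
      }
    }
  })
  if (record == "full") {
    fired_seq <- fired_seq[seq_len(steps_done)]
    markings <- markings[seq_len(steps_done), , drop = FALSE]
  } else if (record == "sampled") {
    markings <- markings[!is.na(markings[, 1]), , drop = FALSE]
  }
  structure(list(seed = seed, n_steps = steps_done, stop_reason = stop_reason,
                 fired_counts = fired_counts, ever_enabled = ever_enabled,
                 final_marking = m, fired = fired_seq, markings = markings,
                 sample_every = if (record == "sampled") sample_every else NA),
            class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace> seed ", x$seed, ": ", x$n_steps, " steps (",
      x$stop_reason, "), ", sum(x$fired_counts > 0), " distinct transitions fired\n",
      sep = "")
  invisible(x)
}

#' Knockout specification
#'
#' An in-silico loss-of-function perturbation: transitions erased outright
#' (disease-causing loss of a reaction) and/or places clamped to a fixed
#' token count. Clamping detaches all arcs feeding the place and resets its
#' initial tokens; clamping to 0 erases the token and, because consumers can
#' then never be enabled, permanently disables every transition that needs it.
#'
#' @param removed_transitions character vector of transition ids to delete.
#' @param clamped_places named integer vector: place id -> fixed token count.
#' @return an object of class `knockout_spec`.
#' @export
knockout_spec <- function(removed_transitions = character(),
                          clamped_places = integer()) {
  stopifnot(is.character(removed_transitions))
  if (length(clamped_places) > 0) {
    stopifnot(!is.null(names(clamped_places)), all(clamped_places >= 0))
  }
  structure(list(removed_transitions = removed_transitions,
                 clamped_places = clamped_places),
            class = "knockout_spec")
}

#' Apply a knockout to a net
#'
#' Returns a modified copy (the original is untouched): removed transitions
#' are deleted together with their arcs; clamped places lose every incoming
#' arc (including the return half of read pairs) and have their initial
#' marking set to the clamp level.
#'
#' @param net a [petri_net()].
#' @param spec a [knockout_spec()].
#' @return the knocked-out [petri_net()].
#' @export
apply_knockout <- function(net, spec) {
  unknown_t <- setdiff(spec$removed_transitions, net$transitions$id)
  unknown_p <- setdiff(names(spec$clamped_places), net$places$id)
  if (length(unknown_t) + length(unknown_p) > 0) {
    stop("unknown id(s) in knockout spec: ",
         paste(c(unknown_t, unknown_p), collapse = ", "))
  }
  p <- net$places; t <- net$transitions; a <- net$arcs
  if (length(spec$removed_transitions) > 0) {
    t <- t[!(t$id %in% spec$removed_transitions), , drop = FALSE]
    a <- a[!(a$source %in% spec$removed_transitions) &
             !(a$target %in% spec$removed_transitions), , drop = FALSE]
  }
  if (length(spec$clamped_places) > 0) {
    clamped <- names(spec$clamped_places)
    a <- a[!(a$target %in% clamped), , drop = FALSE]  # detach producers
    p$tokens[match(clamped, p$id)] <- as.integer(spec$clamped_places)
  }
  petri_net(p, t, a, name = paste0(net$name, "+ko"))
}

#' Run a knockout experiment
#'
#' Simulates the knocked-out net once per seed and derives qualitative
#' readouts that must hold in every replicate:
#' \describe{
#'   \item{dead transitions}{never enabled at any visited state;}
#'   \item{accumulating places}{the token count sampled every `window` steps
#'     is non-decreasing and gains at least `min_gain` tokens overall, and
#'     the place lies in no P-invariant of the knocked-out net (a place
#'     covered by a P-invariant is provably bounded by the conserved sum, so
#'     a small saturating pool is never mistaken for unbounded growth);}
#'   \item{depleted places}{held tokens at some point, and the count is zero
#'     throughout the final quarter of the samples;}
#'   \item{inactivated MCTS}{classes of `part` all of whose members are dead.}
#' }
#' Accumulation and depletion are operational proxies for the visual
#' "grows without bound" / "runs out" judgements of an animated token game.
#'
#' @param net a flattened [petri_net()] (the intact model).
#' @param spec a [knockout_spec()].
#' @param seeds integer vector of replicate seeds.
#' @param max_steps steps per replicate.
#' @param window sampling stride for the token trend.
#' @param min_gain minimum total gain for an accumulation call.
#' @param part optional [mcts()] partition of the intact net used to report
#'   inactivated MCTS.
#' @return an object of class `knockout_report` with fields `spec`,
#'   `dead_transitions`, `accumulating_places`, `depleted_places`,
#'   `inactivated_mcts`, `fired_counts` (summed over replicates), `seeds`.
#' @export
run_experiment <- function(net, spec, seeds = 1:10, max_steps = 5000L,
                           window = 50L, min_gain = 3L, part = NULL) {
  if (length(seeds) == 0) stop("empty seed list")
  ko <- apply_knockout(net, spec)
  t_ids <- ko$transitions$id
  p_ids <- ko$places$id
  pinv_ko <- minimal_p_invariants(ko)
  bounded <- colnames(pinv_ko$vectors)[colSums(pinv_ko$vectors > 0) > 0]
  dead <- rep(TRUE, length(t_ids))
  accum <- rep(TRUE, length(p_ids))
  depl <- rep(TRUE, length(p_ids))
  fired_total <- stats::setNames(numeric(length(t_ids)), t_ids)
  for (s in seeds) {
    tr <- simulate_net(ko, max_steps = max_steps, seed = s,
                       record = "sampled", sample_every = window)
    dead <- dead & !tr$ever_enabled[t_ids]
    fired_total <- fired_total + tr$fired_counts[t_ids]
    sm <- tr$markings[, p_ids, drop = FALSE]
    n <- nrow(sm)
    nondec <- apply(sm, 2, function(x) all(diff(x) >= 0))
    gain <- sm[n, ] - sm[1, ] >= min_gain
    accum <- accum & nondec & gain
    tail_rows <- max(1, ceiling(0.75 * n)):n
    was_positive <- apply(sm, 2, max) > 0
    zero_tail <- apply(sm[tail_rows, , drop = FALSE] == 0, 2, all)
    depl <- depl & was_positive & zero_tail
  }
  accum <- accum & !(p_ids %in% bounded)
  dead_ids <- t_ids[dead]
  inactivated <- character()
  if (!is.null(part)) {
    ## an MCTS is inactivated when every member is removed or dead
    inactivated <- names(part$sets)[vapply(part$sets, function(g) {
      all(g %in% c(dead_ids, spec$removed_transitions))
    }, logical(1))]
  }
  structure(list(spec = spec,
                 dead_transitions = sort_ids(dead_ids),
                 accumulating_places = sort_ids(p_ids[accum]),
                 depleted_places = sort_ids(p_ids[depl]),
                 inactivated_mcts = inactivated,
                 fired_counts = fired_total,
                 seeds = seeds, max_steps = max_steps,
                 net_ref = net$name),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("<knockout_report> [", x$net_ref, "] removed: ",
      paste(x$spec$removed_transitions, collapse = ", "),
      if (length(x$spec$clamped_places) > 0)
        paste0("; clamped: ",
               paste(names(x$spec$clamped_places), "=", x$spec$clamped_places,
                     collapse = ", ")),
      "\n", sep = "")
  cat("  dead transitions:    ", length(x$dead_transitions), "\n")
  cat("  accumulating places: ",
      paste(x$accumulating_places, collapse = ", "), "\n")
  cat("  depleted places:     ",
      paste(x$depleted_places, collapse = ", "), "\n")
  if (length(x$inactivated_mcts) > 0) {
    cat("  inactivated MCTS:    ",
        paste(x$inactivated_mcts, collapse = ", "), "\n")
  }
  invisible(x)
}
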