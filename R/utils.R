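#' @keywords internal
"_PACKAGE"

## Integer gcd helpers. Invariant vectors stay small (entries rarely exceed
## single digits) but all reductions are exact.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

gcd_vec <- function(x) {
  g <- 0
  for (v in x) {
    g <- gcd2(g, v)
    if (g == 1) break
  }
  g
}

#' Round half away from zero to a fixed number of decimals
#'
#' Plain decimal rounding (0.0005 -> 0.001) used for reported occurrence
#' percentages, where R's default round-half-even would be surprising.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Order identifier strings "t_12", "p_3" numerically where possible,
## falling back to plain lexicographic order for named aliases.
order_ids <- function(ids) {
  if (length(ids) == 0) return(integer(0))
  num <- suppressWarnings(as.numeric(sub("^[a-zA-Z]+_", "", ids)))
  order(is.na(num), num, ids)
}

sort_ids <- function(ids) ids[order_ids(ids)]
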