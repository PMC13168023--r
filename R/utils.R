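#' Derive a child random seed from a master seed
#'
#' All randomness in coabnet flows from a single master seed. Each stochastic
#' step derives its own seed with `make_seed(master, offset)` using a documented
#' integer offset (see [run_pipeline()] for the offset registry), so stages are
#' reproducible independently of evaluation order and no global random state is
#' shared between stages.
#'
#' @param master Integer master seed (>= 0).
#' @param offset Integer counter identifying the consuming step.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' make_seed(1, 7)
make_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  # Lehmer-style mixing keeps distinct (master, offset) pairs well separated
  s <- (abs(as.numeric(master)) * 48271 + abs(as.numeric(offset)) * 16807 + 1) %%
    2147483629
  as.integer(s + 1)
}

#' Round half-up to a fixed number of decimals
#'
#' `base::round()` rounds halves to even; printed percentages in reports use
#' conventional half-up rounding (56.395 -> 56.40).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a total, rounded half-up
#'
#' @param k Count.
#' @param n Total.
#' @param digits Decimal places (default 2, matching reported precision).
#' @return `100 * k / n` rounded half-up.
#' @export
#' @examples
#' fraction_pct(370, 656) # 56.40
fraction_pct <- function(k, n, digits = 2) {
  stopifnot(n > 0)
  round_half_up(100 * k / n, digits)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index comparing two partitions of the same
#' items. Used to compare detected guild membership with planted truth.
#'
#' @param a,b Vectors of cluster labels (same length; any atomic type).
#' @return Numeric scalar; 1 for identical partitions, ~0 for random agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# canonical (lexicographically sorted) unordered pair key
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# sort two id vectors so that from < to lexicographically
sort_pairs <- function(a, b) {
  swap <- a > b
  data.frame(from = ifelse(swap, b, a), to = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}
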