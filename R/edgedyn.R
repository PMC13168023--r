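#' Match edges across stage networks
#'
#' Builds the union of all edges over a list of stage networks, keyed by the
#' unordered taxon pair, with per-stage correlation, p, q, sample size and a
#' presence flag. Subsets such as "shared by all stages" are derivable from
#' the presence columns.
#'
#' @param networks List of `coab_network` objects with distinct stage labels.
#' @return A `cross_stage_edges` data.frame with columns `from`, `to` and,
#'   per stage `<s>`: `r_<s>`, `p_<s>`, `q_<s>`, `n_<s>`, `present_<s>`.
#' @export
match_edges <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2)
  stages <- vapply(networks, function(x) as.character(x$stage), character(1))
  if (anyDuplicated(stages)) stop("duplicate stage labels: ",
                                  paste(stages[duplicated(stages)],
                                        collapse = ", "))
  keys <- unique(unlist(lapply(networks, function(x) {
    edge_key(x$edges$from, x$edges$to)
  })))
  keys <- sort(keys)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    s <- stages[k]
    ek <- edge_key(net$edges$from, net$edges$to)
    idx <- match(keys, ek)
    out[[paste0("r_", s)]] <- net$edges$r[idx]
    out[[paste0("p_", s)]] <- net$edges$p[idx]
    out[[paste0("q_", s)]] <- net$edges$q[idx]
    out[[paste0("n_", s)]] <- ifelse(is.na(idx), NA_integer_, net$n_samples)
    out[[paste0("present_", s)]] <- !is.na(idx)
  }
  attr(out, "stages") <- stages
  class(out) <- c("cross_stage_edges", "data.frame")
  out
}

#' Fixed-effect heterogeneity meta-analysis of correlations
#'
#' Fisher-z fixed-effect pooling of per-stage correlations: `z_k = atanh(r_k)`
#' with large-sample weights `w_k = n_k - 3`; pooled
#' `z = sum(w z) / sum(w)`; Cochran's `Q = sum(w (z - pooled)^2)` with
#' `K - 1` degrees of freedom; `p_Q` from the chi-square distribution; and
#' `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param r Vector of correlations, all `|r| < 1`.
#' @param n Vector of sample sizes, all `> 3`.
#' @return A `meta_result` list: `pooled_z`, `pooled_r`, `Q`, `df`, `p_Q`,
#'   `I2`.
#' @export
meta_heterogeneity <- function(r, n) {
  stopifnot(length(r) == length(n), length(r) >= 2)
  if (any(abs(r) >= 1)) stop("|r| = 1 gives an infinite Fisher z")
  if (any(n <= 3)) stop("all sample sizes must exceed 3")
  z <- atanh(r)
  w <- n - 3
  pooled <- sum(w * z) / sum(w)
  q_stat <- sum(w * (z - pooled)^2)
  df <- length(r) - 1
  p_q <- stats::pchisq(q_stat, df, lower.tail = FALSE)
  i2 <- if (q_stat > 0) max(0, (q_stat - df) / q_stat) * 100 else 0
  structure(list(pooled_z = pooled, pooled_r = tanh(pooled), Q = q_stat,
                 df = df, p_Q = p_q, I2 = i2),
            class = "meta_result")
}

#' Classify edge conservation across stages
#'
#' For every edge present in all compared stages, runs
#' [meta_heterogeneity()] and labels the edge `stable` if `p_Q >
#' alpha_stable`, `heterogeneous` if `I2 > i2_cut` and the BH-adjusted `p_Q`
#' (adjusted over the compared edge set) is below `fdr_cut`, and
#' `intermediate` otherwise. Edges missing in any compared stage are
#' excluded and reported via the `n_excluded` attribute.
#'
#' @param table A `cross_stage_edges` table from [match_edges()].
#' @param stages Stage labels to compare (default: all stages in the table).
#' @param alpha_stable Stability threshold on `p_Q` (default 0.05).
#' @param i2_cut Heterogeneity threshold on I2 percentage (default 75).
#' @param fdr_cut FDR threshold on the adjusted `p_Q` (default 0.05).
#' @return data.frame with `from`, `to`, per-stage `r`/`n`, `Q`, `df`,
#'   `p_Q`, `q_Q`, `I2` and `label`.
#' @export
classify_conservation <- function(table, stages = NULL, alpha_stable = 0.05,
                                  i2_cut = 75, fdr_cut = 0.05) {
  stopifnot(inherits(table, "cross_stage_edges"))
  all_stages <- attr(table, "stages")
  if (is.null(stages)) stages <- all_stages
  stopifnot(all(stages %in% all_stages), length(stages) >= 2)
  pres <- as.matrix(table[paste0("present_", stages)])
  shared <- rowSums(pres) == length(stages)
  n_excluded <- sum(!shared)
  tab <- table[shared, , drop = FALSE]
  r_mat <- as.matrix(tab[paste0("r_", stages)])
  n_mat <- as.matrix(tab[paste0("n_", stages)])
  res <- t(vapply(seq_len(nrow(tab)), function(e) {
    m <- meta_heterogeneity(r_mat[e, ], n_mat[e, ])
    c(m$Q, m$df, m$p_Q, m$I2)
  }, numeric(4)))
  out <- data.frame(from = tab$from, to = tab$to, stringsAsFactors = FALSE)
  for (s in stages) {
    out[[paste0("r_", s)]] <- tab[[paste0("r_", s)]]
    out[[paste0("n_", s)]] <- tab[[paste0("n_", s)]]
  }
  out$Q <- res[, 1]; out$df <- res[, 2]; out$p_Q <- res[, 3]
  out$q_Q <- stats::p.adjust(out$p_Q, method = "BH")
  out$I2 <- res[, 4]
  out$label <- ifelse(out$p_Q > alpha_stable, "stable",
                      ifelse(out$I2 > i2_cut & out$q_Q < fdr_cut,
                             "heterogeneous", "intermediate"))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "stages") <- stages
  out
}

#' Categorize the pairwise change of a heterogeneous edge
#'
#' Between two stages A and B: `reversed` if the correlation signs differ,
#' otherwise `increased_at_A` / `decreased_at_A` by magnitude. A zero
#' correlation on either side makes the category `indeterminate`. The
#' per-stage significance flags are summarized as a sub-annotation.
#'
#' @param rA,rB Correlations at the two stages (vectorized).
#' @param sigA,sigB Logical significance flags at the two stages.
#' @return data.frame with `category` and `significant_at`
#'   (`both`/`A_only`/`B_only`/`none`).
#' @export
classify_pairwise_change <- function(rA, rB, sigA = NA, sigB = NA) {
  stopifnot(length(rA) == length(rB))
  category <- ifelse(rA == 0 | rB == 0, "indeterminate",
              ifelse(sign(rA) != sign(rB), "reversed",
              ifelse(abs(rA) > abs(rB), "increased_at_A", "decreased_at_A")))
  sigA <- rep_len(sigA, length(rA)); sigB <- rep_len(sigB, length(rA))
  significant_at <- ifelse(is.na(sigA) | is.na(sigB), NA_character_,
                    ifelse(sigA & sigB, "both",
                    ifelse(sigA, "A_only", ifelse(sigB, "B_only", "none"))))
  if (any(category == "indeterminate")) {
    message(sum(category == "indeterminate"),
            " edge(s) with a zero correlation flagged indeterminate")
  }
  data.frame(category = category, significant_at = significant_at,
             stringsAsFactors = FALSE)
}

#' Summarize conservation labels as counts and percentages
#'
#' Counts each label and reports its percentage of the total, rounded
#' half-up to 2 decimals (the precision used when such proportions are
#' printed). With `strata`, the same summary is produced per stratum.
#'
#' @param labels Character vector of labels.
#' @param strata Optional factor of the same length (e.g. beneficial-linked
#'   vs other edges, or `|r|` bands).
#' @return data.frame with `stratum`, `category`, `count`, `total`, `pct`.
#' @export
summarize_conservation <- function(labels, strata = NULL) {
  stopifnot(length(labels) > 0)
  one <- function(lab, name) {
    tb <- table(lab)
    data.frame(stratum = name, category = names(tb),
               count = as.integer(tb), total = length(lab),
               pct = fraction_pct(as.integer(tb), length(lab)),
               stringsAsFactors = FALSE)
  }
  out <- one(labels, "overall")
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(labels))
    for (lv in levels(factor(strata))) {
      out <- rbind(out, one(labels[strata == lv], lv))
    }
  }
  rownames(out) <- NULL
  out
}

#' Jaccard similarity between two module partitions
#'
#' `J(M1, M2) = |intersection| / |union|` for every module pair. The
#' network-level similarity is the symmetrized best-match mean: for each
#' module the best-matching counterpart in the other partition is found, and
#' the mean is taken over both directions.
#'
#' @param partA,partB Lists of node-id vectors (modules); none may be empty.
#' @return List with `jaccard` (matrix, modules of A x modules of B) and
#'   `mean_similarity`.
#' @export
module_jaccard <- function(partA, partB) {
  stopifnot(is.list(partA), is.list(partB),
            length(partA) > 0, length(partB) > 0)
  if (any(lengths(partA) == 0) || any(lengths(partB) == 0)) {
    stop("empty module in partition")
  }
  jac <- matrix(0, length(partA), length(partB),
                dimnames = list(names(partA), names(partB)))
  for (a in seq_along(partA)) {
    for (b in seq_along(partB)) {
      jac[a, b] <- length(intersect(partA[[a]], partB[[b]])) /
        length(union(partA[[a]], partB[[b]]))
    }
  }
  list(jaccard = jac,
       mean_similarity = mean(c(apply(jac, 1, max), apply(jac, 2, max))))
}
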