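#' Filter taxa by prevalence
#'
#' Retains taxa with a nonzero count in at least
#' `ceiling(min_prevalence * n_samples)` samples, the conventional
#' inclusion rule before network construction.
#'
#' @param counts Counts matrix, taxa x samples.
#' @param min_prevalence Fraction of samples in (0, 1] (default 0.10).
#' @return The row-subset counts matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.10) {
  stopifnot(is.matrix(counts), min_prevalence > 0, min_prevalence <= 1)
  need <- ceiling(min_prevalence * ncol(counts))
  keep <- rowSums(counts > 0) >= need
  if (!any(keep)) stop("prevalence filter removed all taxa")
  counts[keep, , drop = FALSE]
}

#' Dirichlet-posterior-mean fraction estimates
#'
#' Converts counts to strictly positive compositional fractions using the
#' +1 pseudocount posterior mean: `(c + 1) / (sample total + n_taxa)`.
#'
#' @param counts Counts matrix, taxa x samples, nonnegative integers.
#' @return Fractions matrix, samples x taxa; each row sums to 1.
#' @export
estimate_fractions <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("sample with all-zero counts: ", paste(bad, collapse = ", "))
  }
  p <- nrow(counts)
  fr <- t((counts + 1) / rep(totals + p, each = p))
  fr
}

#' Solve the SparCC basis-variance system from a log-ratio variation matrix
#'
#' Core of the SparCC estimator. Given the matrix of pairwise log-ratio
#' variances `t_ij = Var[log(f_i / f_j)]`, basis variances solve
#' `((p - 2) I + 1 1') w = rowSums(t)` under the sparsity assumption, and
#' correlations are `r_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped
#' to `[-1, 1]`. Strongly correlated pairs are iteratively excluded from the
#' system (one per iteration, strongest first, while `|r| >` the exclusion
#' threshold), re-solving after each exclusion, up to `max_exclusions` pairs.
#' Exclusion stops early if it would leave fewer than 4 effective taxa.
#'
#' @param t_mat Symmetric nonnegative variation matrix (zero diagonal).
#' @param exclusion_threshold Minimum `|r|` for a pair to be excluded
#'   (default 0.1).
#' @param max_exclusions Maximum number of excluded pairs (default 10).
#' @return List with `r` (correlation matrix), `basis_var` (basis variances)
#'   and `excluded` (data.frame of excluded index pairs).
#' @export
sparcc_from_variation <- function(t_mat, exclusion_threshold = 0.1,
                                  max_exclusions = 10) {
  p <- nrow(t_mat)
  stopifnot(ncol(t_mat) == p, p >= 4)
  m_mat <- matrix(1, p, p)
  diag(m_mat) <- p - 1
  t_work <- t_mat
  excl_i <- integer(); excl_j <- integer()
  excl_count <- integer(p)
  excluded_pair <- matrix(FALSE, p, p)
  repeat {
    omega2 <- tryCatch(solve(m_mat, rowSums(t_work)),
                       error = function(e) NULL)
    if (is.null(omega2)) break
    omega2 <- pmax(omega2, 1e-12)
    w <- sqrt(omega2)
    # correlations always use the original variation matrix; exclusion only
    # removes pairs from the basis-variance system
    r <- (outer(omega2, omega2, "+") - t_mat) / (2 * outer(w, w))
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    if (length(excl_i) >= max_exclusions) break
    cand <- abs(r)
    cand[lower.tri(cand, diag = TRUE)] <- -Inf
    cand[excluded_pair] <- -Inf
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    i <- ij[1]; j <- ij[2]
    # a taxon excluded from p-1 pairs has left the system entirely
    new_count <- excl_count
    new_count[c(i, j)] <- new_count[c(i, j)] + 1L
    if (sum(new_count < p - 1) < 4) break
    excl_count <- new_count
    excluded_pair[i, j] <- excluded_pair[j, i] <- TRUE
    excl_i <- c(excl_i, i); excl_j <- c(excl_j, j)
    t_work[i, j] <- t_work[j, i] <- 0
    m_mat[i, i] <- m_mat[i, i] - 1
    m_mat[j, j] <- m_mat[j, j] - 1
    m_mat[i, j] <- m_mat[i, j] - 1
    m_mat[j, i] <- m_mat[j, i] - 1
  }
  dimnames(r) <- dimnames(t_mat)
  list(r = r, basis_var = omega2,
       excluded = data.frame(i = excl_i, j = excl_j))
}

# variation matrix t_ij = Var[log(f_i/f_j)] from a fractions matrix
# (samples x taxa), via the covariance of log fractions
variation_matrix <- function(fractions) {
  lf <- log(fractions)
  v <- stats::cov(lf)
  dv <- diag(v)
  t_mat <- outer(dv, dv, "+") - 2 * v
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  t_mat
}

#' SparCC correlations from a fraction matrix
#'
#' Computes the log-ratio variation matrix of a single fraction matrix and
#' solves the SparCC system (no Dirichlet resampling).
#'
#' @param fractions Samples x taxa fraction matrix, strictly positive rows
#'   summing to 1.
#' @inheritParams sparcc_from_variation
#' @return As [sparcc_from_variation()].
#' @export
sparcc_fraction_cor <- function(fractions, exclusion_threshold = 0.1,
                                max_exclusions = 10) {
  stopifnot(is.matrix(fractions), all(fractions > 0))
  sparcc_from_variation(variation_matrix(fractions),
                        exclusion_threshold, max_exclusions)
}

#' SparCC compositional correlation inference
#'
#' Full SparCC estimate from a counts table. When `n_inner > 1` the final
#' correlation matrix is the average over `n_inner` Dirichlet resamplings of
#' the per-sample fractions (Dirichlet(counts + 1)); with `n_inner = 1` the
#' deterministic posterior-mean fractions of [estimate_fractions()] are used.
#'
#' @param counts Counts matrix, taxa x samples; at least 4 taxa.
#' @param exclusion_threshold,max_exclusions See [sparcc_from_variation()].
#' @param n_inner Number of Dirichlet resamplings to average (default 20).
#' @param seed Seed for the resampling draws.
#' @return List with `r` (averaged correlation matrix), `basis_var`
#'   (averaged basis variances) and `n_inner`.
#' @export
sparcc <- function(counts, exclusion_threshold = 0.1, max_exclusions = 10,
                   n_inner = 20, seed = 1) {
  stopifnot(is.matrix(counts), nrow(counts) >= 4, n_inner >= 1)
  p <- nrow(counts)
  if (n_inner == 1) {
    fit <- sparcc_fraction_cor(estimate_fractions(counts),
                               exclusion_threshold, max_exclusions)
    return(list(r = fit$r, basis_var = fit$basis_var, n_inner = 1L))
  }
  r_sum <- matrix(0, p, p)
  v_sum <- numeric(p)
  for (b in seq_len(n_inner)) {
    set.seed(make_seed(seed, 500 + b))
    g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                nrow = p)
    fr <- t(g) / colSums(g)
    fit <- sparcc_fraction_cor(fr, exclusion_threshold, max_exclusions)
    r_sum <- r_sum + fit$r
    v_sum <- v_sum + fit$basis_var
  }
  r <- r_sum / n_inner
  dimnames(r) <- list(rownames(counts), rownames(counts))
  list(r = r, basis_var = v_sum / n_inner, n_inner = as.integer(n_inner))
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Builds the null by destroying inter-taxon association while preserving
#' marginal counts: each permutation independently shuffles every taxon's
#' counts across samples (`scheme = "permute"`, default) or resamples them
#' with replacement (`scheme = "bootstrap"`), then recomputes the SparCC
#' correlation matrix. The smoothed pseudo p-value is
#' `(1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_permutations)`, so p is always
#' positive with floor `1/(n_permutations + 1)`.
#'
#' @param counts Counts matrix, taxa x samples.
#' @param observed_r Observed SparCC correlation matrix.
#' @param n_permutations Number of null draws (>= 100; 1000 is the
#'   conventional choice).
#' @param seed Seed; permutation `b` uses `make_seed(seed, 700 + b)`.
#' @param scheme Null scheme, `"permute"` or `"bootstrap"`.
#' @param exclusion_threshold,max_exclusions Passed to the null SparCC fits.
#' @return Symmetric matrix of p-values in (0, 1] (diagonal set to NA).
#' @export
permutation_pvalues <- function(counts, observed_r, n_permutations = 1000,
                                seed = 1, scheme = c("permute", "bootstrap"),
                                exclusion_threshold = 0.1,
                                max_exclusions = 10) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(counts), n_permutations >= 100,
            all(dim(observed_r) == nrow(counts)))
  p <- nrow(counts)
  n <- ncol(counts)
  abs_obs <- abs(observed_r)
  exceed <- matrix(0L, p, p)
  replace <- scheme == "bootstrap"
  for (b in seq_len(n_permutations)) {
    set.seed(make_seed(seed, 700 + b))
    idx <- matrix(0L, p, n)
    for (i in seq_len(p)) idx[i, ] <- sample.int(n, n, replace = replace)
    null_counts <- matrix(counts[cbind(rep(seq_len(p), n), as.vector(idx))],
                          nrow = p)
    fit <- sparcc_fraction_cor(estimate_fractions(null_counts),
                               exclusion_threshold, max_exclusions)
    exceed <- exceed + (abs(fit$r) >= abs_obs)
  }
  pv <- (1 + exceed) / (1 + n_permutations)
  diag(pv) <- NA_real_
  dimnames(pv) <- dimnames(observed_r)
  pv
}

#' Benjamini-Hochberg adjustment
#'
#' BH step-up adjustment. For a symmetric p-value matrix the adjustment is
#' computed over the upper triangle only and mirrored back.
#'
#' @param p Numeric vector, or symmetric matrix of p-values.
#' @return Adjusted q-values with the same shape.
#' @export
bh_adjust <- function(p) {
  if (is.matrix(p)) {
    ut <- upper.tri(p)
    q <- p
    q[ut] <- stats::p.adjust(p[ut], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    return(q)
  }
  stats::p.adjust(p, method = "BH")
}

#' Build a co-abundance network from correlation and q-value matrices
#'
#' Retains the unordered taxon pairs with `q < q_cutoff` as undirected edges
#' carrying `r`, `p`, and `q`. Edge endpoints are stored lexicographically
#' sorted so each pair appears exactly once.
#'
#' @param r,p,q Conformable symmetric matrices (p may be NULL if unavailable).
#' @param q_cutoff FDR threshold (default 0.05).
#' @param stage Stage label attached to the network.
#' @param mean_abundance Optional named per-taxon mean relative abundance.
#' @param beneficial Optional named logical per-taxon beneficial flag.
#' @param n_samples Number of samples behind the correlations (used by the
#'   cross-stage meta-analysis).
#' @return A `coab_network` object: list with `nodes` (data.frame: taxon,
#'   mean_abundance, beneficial), `edges` (data.frame: from, to, r, p, q),
#'   `stage`, `n_samples`.
#' @export
build_network <- function(r, p = NULL, q, q_cutoff = 0.05, stage = NA,
                          mean_abundance = NULL, beneficial = NULL,
                          n_samples = NA_integer_) {
  stopifnot(is.matrix(r), all(dim(r) == dim(q)))
  taxa <- rownames(r)
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(nrow(r)))
  ut <- which(upper.tri(q) & q < q_cutoff, arr.ind = TRUE)
  edges <- data.frame(from = taxa[ut[, 1]], to = taxa[ut[, 2]],
                      r = r[ut],
                      p = if (is.null(p)) rep(NA_real_, nrow(ut)) else p[ut],
                      q = q[ut], stringsAsFactors = FALSE)
  sp <- sort_pairs(edges$from, edges$to)
  edges$from <- sp$from; edges$to <- sp$to
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  ma <- if (is.null(mean_abundance)) rep(NA_real_, length(taxa)) else
    unname(mean_abundance[taxa])
  bf <- if (is.null(beneficial)) rep(FALSE, length(taxa)) else
    unname(beneficial[taxa])
  nodes <- data.frame(taxon = taxa, mean_abundance = ma, beneficial = bf,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, stage = stage,
                 n_samples = as.integer(n_samples)),
            class = "coab_network")
}

#' Construct a `coab_network` directly from an edge list
#'
#' Convenience constructor for tests and for networks read back from disk.
#'
#' @param edges data.frame with columns `from`, `to`, `r` (optionally `p`,
#'   `q`).
#' @param nodes Optional data.frame with column `taxon` (optionally
#'   `mean_abundance`, `beneficial`); defaults to the nodes seen in `edges`.
#' @param stage,n_samples Metadata fields.
#' @return A `coab_network`.
#' @export
coab_network <- function(edges, nodes = NULL, stage = NA,
                         n_samples = NA_integer_) {
  stopifnot(all(c("from", "to", "r") %in% names(edges)))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (!"p" %in% names(edges)) edges$p <- rep(NA_real_, nrow(edges))
  if (!"q" %in% names(edges)) edges$q <- rep(NA_real_, nrow(edges))
  sp <- sort_pairs(edges$from, edges$to)
  edges$from <- sp$from; edges$to <- sp$to
  edges <- edges[order(edges$from, edges$to),
                 c("from", "to", "r", "p", "q"), drop = FALSE]
  if (anyDuplicated(edge_key(edges$from, edges$to))) {
    stop("duplicate undirected edge in edge list")
  }
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    nodes <- data.frame(taxon = sort(unique(c(edges$from, edges$to))),
                        stringsAsFactors = FALSE)
  }
  if (!"mean_abundance" %in% names(nodes)) nodes$mean_abundance <- NA_real_
  if (!"beneficial" %in% names(nodes)) nodes$beneficial <- FALSE
  nodes <- nodes[order(nodes$taxon), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, stage = stage,
                 n_samples = as.integer(n_samples)),
            class = "coab_network")
}

#' @export
print.coab_network <- function(x, ...) {
  cat("coab_network", if (!is.na(x$stage)) paste0("[", x$stage, "]"), ":",
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(%d positive / %d negative)\n",
              sum(x$edges$r > 0), sum(x$edges$r < 0)))
  invisible(x)
}

#' Convert a `coab_network` to an igraph graph
#'
#' Edge attribute `weight` is `|r|`; `r`, `p`, `q`, `sign` are carried as
#' edge attributes, node metadata as vertex attributes.
#'
#' @param net A `coab_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  ed <- net$edges
  ed$weight <- abs(ed$r)
  ed$sign <- ifelse(ed$r >= 0, 1, -1)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = net$nodes)
}

#' Extract the beneficial-taxon subnetwork
#'
#' Induced subgraph on the beneficial taxa plus their first neighbors; an
#' edge is retained iff both endpoints are retained.
#'
#' @param net A `coab_network`.
#' @param beneficial Optional named logical vector overriding the node flags.
#' @return A `coab_network` restricted to the beneficial neighborhood.
#' @export
extract_beneficial_subnetwork <- function(net, beneficial = NULL) {
  stopifnot(inherits(net, "coab_network"))
  flags <- if (is.null(beneficial)) {
    stats::setNames(net$nodes$beneficial, net$nodes$taxon)
  } else beneficial[net$nodes$taxon]
  if (!any(flags, na.rm = TRUE)) stop("no beneficial taxa flagged")
  core <- net$nodes$taxon[which(flags)]
  touch <- net$edges$from %in% core | net$edges$to %in% core
  keep <- union(core, unique(c(net$edges$from[touch], net$edges$to[touch])))
  sub_edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                         drop = FALSE]
  sub_nodes <- net$nodes[net$nodes$taxon %in% keep, , drop = FALSE]
  rownames(sub_edges) <- rownames(sub_nodes) <- NULL
  structure(list(nodes = sub_nodes, edges = sub_edges, stage = net$stage,
                 n_samples = net$n_samples),
            class = "coab_network")
}
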