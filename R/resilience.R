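#' Abundance-weighted mean interaction strength (wMIS)
#'
#' For node i, `wMIS_i = sum_j a_j r_ij / sum_j a_j` over the neighbors j of
#' i: the mean signed correlation with its partners, weighted by partner
#' abundance. Isolated nodes score 0; a node whose neighbors all have zero
#' abundance is reported as 0 with a warning.
#'
#' @param net A `coab_network`.
#' @param abundances Named nonnegative abundance vector covering all nodes;
#'   defaults to the `mean_abundance` node metadata.
#' @return Named numeric vector of per-node wMIS values.
#' @export
wmis <- function(net, abundances = NULL) {
  stopifnot(inherits(net, "coab_network"))
  nodes <- net$nodes$taxon
  if (is.null(abundances)) {
    abundances <- stats::setNames(net$nodes$mean_abundance, nodes)
  }
  if (any(is.na(abundances[nodes]))) stop("missing abundance for a node")
  if (any(abundances[nodes] < 0)) stop("abundances must be nonnegative")
  edges <- net$edges
  out <- stats::setNames(numeric(length(nodes)), nodes)
  warned <- FALSE
  for (v in nodes) {
    sel <- edges$from == v | edges$to == v
    if (!any(sel)) next
    nb <- ifelse(edges$from[sel] == v, edges$to[sel], edges$from[sel])
    a <- abundances[nb]
    if (sum(a) == 0) {
      if (!warned) {
        warning("node with all-zero neighbor abundances; wMIS set to 0")
        warned <- TRUE
      }
      next
    }
    out[v] <- sum(a * edges$r[sel]) / sum(a)
  }
  out
}

#' Core nodes shared across stage networks
#'
#' @param networks List of at least 2 `coab_network` objects.
#' @return Character vector of node ids present in every network (possibly
#'   empty).
#' @export
core_nodes <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2)
  out <- Reduce(intersect, lapply(networks, function(x) x$nodes$taxon))
  if (length(out) == 0) message("core node set is empty")
  sort(out)
}

#' Network stability index from wMIS and core nodes
#'
#' `S = (|core| / |nodes|) * (sum_core |wMIS| / sum_all |wMIS|)`: the share
#' of nodes that persist across all stages, scaled by the share of total
#' interaction strength those persistent nodes carry. S = 1 when every node
#' is core; S = 0 when no interaction strength (or no node) persists.
#'
#' @param net A `coab_network`.
#' @param abundances Abundances for [wmis()] (optional).
#' @param core Character vector of core node ids (subset of the nodes).
#' @return Numeric stability index in `[0, 1]`.
#' @export
stability_index <- function(net, abundances = NULL, core) {
  stopifnot(inherits(net, "coab_network"))
  nodes <- net$nodes$taxon
  if (!all(core %in% nodes)) stop("core must be a subset of the nodes")
  w <- abs(wmis(net, abundances))
  total <- sum(w)
  if (total == 0) return(0)
  (length(core) / length(nodes)) * (sum(w[core]) / total)
}

#' Global efficiency
#'
#' `E = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij` over ordered pairs with
#' unweighted shortest-path distances; disconnected pairs contribute 0.
#'
#' @param net A `coab_network` with at least 2 nodes.
#' @return Numeric efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  n <- nrow(net$nodes)
  if (n < 2) stop("efficiency needs at least 2 nodes")
  if (nrow(net$edges) == 0) return(0)
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Node and network vulnerability
#'
#' `V_i = (E - E_-i) / E` where `E_-i` is the global efficiency after
#' deleting node i and its edges (computed on the remaining node set). The
#' network vulnerability is `max_i V_i`.
#'
#' @param net A `coab_network` with at least 3 nodes and `E > 0`.
#' @return List with `node_vulnerability` (named vector) and
#'   `network_vulnerability`.
#' @export
vulnerability <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  n <- nrow(net$nodes)
  if (n < 3) stop("vulnerability needs at least 3 nodes")
  e0 <- global_efficiency(net)
  if (e0 == 0) stop("vulnerability undefined: zero global efficiency")
  nodes <- net$nodes$taxon
  v <- vapply(nodes, function(nd) {
    sub <- drop_nodes(net, nd)
    (e0 - global_efficiency(sub)) / e0
  }, numeric(1))
  list(node_vulnerability = v, network_vulnerability = max(v))
}

# remove nodes (and incident edges) from a network, keeping remaining
# isolated nodes in place
drop_nodes <- function(net, drop) {
  nodes <- net$nodes[!net$nodes$taxon %in% drop, , drop = FALSE]
  edges <- net$edges[!(net$edges$from %in% drop | net$edges$to %in% drop), ,
                     drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, stage = net$stage,
                 n_samples = net$n_samples),
            class = "coab_network")
}

#' Robustness under targeted versus random node removal
#'
#' Per replicate, the targeted-removal arm (TR) deletes
#' `max(1, floor(|hubs| / 2))` hub nodes chosen uniformly and the
#' random-attack arm (RA) deletes the same number of non-hub nodes; each
#' arm's retention ratio is `sum |wMIS| after removal / sum |wMIS| before`,
#' with wMIS recomputed on the reduced network. The two ratio lists are
#' compared by a two-sided Wilcoxon rank-sum test (normal approximation; if
#' every ratio is identical the comparison p is 1).
#'
#' @param net A `coab_network`.
#' @param abundances Abundances for [wmis()] (optional).
#' @param hub_ids Character vector of hub node ids (>= 2); the complement
#'   must hold at least as many non-hubs as hubs removed per replicate.
#' @param n_reps Number of replicates (default 10).
#' @param seed Seed; replicate b uses offsets `4000 + b` (TR) and
#'   `4500 + b` (RA).
#' @return List with `tr_ratios`, `ra_ratios` (length `n_reps` each),
#'   `n_removed` and `p_value`.
#' @export
robustness_simulation <- function(net, abundances = NULL, hub_ids,
                                  n_reps = 10, seed = 1) {
  stopifnot(inherits(net, "coab_network"), n_reps >= 1)
  nodes <- net$nodes$taxon
  hub_ids <- intersect(hub_ids, nodes)
  if (length(hub_ids) < 2) stop("need at least 2 hub nodes")
  non_hubs <- setdiff(nodes, hub_ids)
  m <- max(1L, floor(length(hub_ids) / 2))
  if (length(non_hubs) < m) stop("not enough non-hub nodes to remove")
  if (length(nodes) - m < 2) stop("removal would empty the network")
  if (is.null(abundances)) {
    abundances <- stats::setNames(net$nodes$mean_abundance, nodes)
  }
  base_total <- sum(abs(wmis(net, abundances)))
  if (base_total == 0) stop("total |wMIS| is zero; ratios undefined")
  ratio_after <- function(drop) {
    sub <- drop_nodes(net, drop)
    sum(abs(wmis(sub, abundances))) / base_total
  }
  tr <- ra <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    set.seed(make_seed(seed, 4000 + b))
    tr[b] <- ratio_after(sample(hub_ids, m))
    set.seed(make_seed(seed, 4500 + b))
    ra[b] <- ratio_after(sample(non_hubs, m))
  }
  p <- if (stats::sd(c(tr, ra)) == 0) 1 else
    suppressWarnings(stats::wilcox.test(tr, ra, exact = FALSE)$p.value)
  list(tr_ratios = tr, ra_ratios = ra, n_removed = m, p_value = p)
}
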