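# shared fixtures: small planted scenarios and toy networks built in code

# compact three-stage scenario: two guilds among 9 taxa, one strong
# conserved pair, one sign-flipping pair, 20 taxa total
small_scenario <- function(stages = c("D25", "D120", "D240")) {
  g1 <- 1:5
  g2 <- 6:9
  gs <- planted_guild_spec(g1, g2)
  po <- function(m) {
    idx <- utils::combn(m, 2)
    data.frame(i = idx[1, ], j = idx[2, ])
  }
  cons <- rbind(cbind(po(g1), rho = 0.6), cbind(po(g2), rho = 0.6),
                cbind(expand.grid(i = g1, j = g2, KEEP.OUT.ATTRS = FALSE),
                      rho = -0.5),
                data.frame(i = c(11, 13), j = c(12, 14), rho = 0.7))
  var <- data.frame(i = 15, j = 16)
  var[[paste0("rho_", stages[1])]] <- 0.6
  var[[paste0("rho_", stages[2])]] <- -0.6
  var[[paste0("rho_", stages[3])]] <- 0.6
  ben <- rep(FALSE, 20)
  ben[c(g1, 11:14)] <- TRUE
  list(network_spec = planted_network_spec(20, stages, cons, var, 0, ben),
       guild_spec = gs)
}

# toy network from a compact edge spec: list of c(from, to, r)
toy_network <- function(..., stage = "S", n_samples = 50L, nodes = NULL,
                        abundance = 1) {
  sp <- list(...)
  edges <- data.frame(
    from = vapply(sp, function(e) as.character(e[[1]]), ""),
    to = vapply(sp, function(e) as.character(e[[2]]), ""),
    r = vapply(sp, function(e) as.numeric(e[[3]]), 0),
    stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    nodes <- data.frame(taxon = sort(unique(c(edges$from, edges$to))))
  } else {
    nodes <- data.frame(taxon = nodes)
  }
  nodes$mean_abundance <- rep_len(abundance, nrow(nodes))
  coab_network(edges, nodes, stage = stage, n_samples = n_samples)
}

# star graph: center plus k leaves, all edges r
star_network <- function(k = 3, r = 0.5) {
  do.call(toy_network,
          lapply(seq_len(k), function(i) c("c", paste0("l", i), r)))
}

# complete graph on n nodes
complete_network <- function(n = 5, r = 0.5, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("v", seq_len(n))
  idx <- utils::combn(n, 2)
  do.call(toy_network, lapply(seq_len(ncol(idx)), function(e) {
    c(nodes[idx[1, e]], nodes[idx[2, e]], r)
  }))
}

# coab_network from an igraph graph, constant |r| on edges
igraph_to_network <- function(g, r = 0.5, stage = "S") {
  ed <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = paste0("v", ed[, 1]), to = paste0("v", ed[, 2]),
                      r = r, stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = paste0("v", seq_len(igraph::vcount(g))),
                      mean_abundance = 1)
  coab_network(edges, nodes, stage = stage)
}

# sample correlation of a bivariate normal draw with population rho
simulate_edge_r <- function(rho, n, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  stats::cor(x, y)
}

# three single-edge networks per simulated edge so match_edges /
# classify_conservation can be exercised on planted per-stage correlations;
# rho_mat: edges x stages population correlations
simulated_edge_networks <- function(rho_mat, n, seed,
                                    stages = c("A", "B", "C")) {
  n_edge <- nrow(rho_mat)
  lapply(seq_along(stages), function(k) {
    edges <- data.frame(
      from = sprintf("x%04d", seq_len(n_edge)),
      to = sprintf("y%04d", seq_len(n_edge)),
      r = vapply(seq_len(n_edge), function(e) {
        simulate_edge_r(rho_mat[e, k], n, seed * 1000 + e * 7 + k)
      }, 0),
      stringsAsFactors = FALSE)
    coab_network(edges, stage = stages[k], n_samples = n)
  })
}
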