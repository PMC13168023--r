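#' Filter a network by correlation strength
#'
#' Retains edges with `|r| > r_cut` (absolute mode, default) or `r > r_cut`
#' (signed mode) and drops nodes left isolated. Topological analyses are
#' conventionally run on such strength-filtered ("robust correlation")
#' networks.
#'
#' @param net A `coab_network`.
#' @param r_cut Strength threshold in `[0, 1)` (default 0.2).
#' @param mode `"absolute"` (keep strong edges of either sign) or
#'   `"signed"` (keep only `r > r_cut`).
#' @return The filtered `coab_network`.
#' @export
filter_by_strength <- function(net, r_cut = 0.2,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "coab_network"), r_cut >= 0, r_cut < 1)
  keep <- if (mode == "absolute") abs(net$edges$r) > r_cut else
    net$edges$r > r_cut
  edges <- net$edges[keep, , drop = FALSE]
  nodes <- net$nodes[net$nodes$taxon %in% c(edges$from, edges$to), ,
                     drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, stage = net$stage,
                 n_samples = net$n_samples),
            class = "coab_network")
}

#' Detect modules by greedy modularity maximization
#'
#' Greedy (fast-greedy) modularity optimization on the `|r|`-weighted graph.
#' The algorithm is deterministic; `seed` is set for interface uniformity
#' and only breaks hypothetical ties.
#'
#' @param net A `coab_network`.
#' @param seed Seed (default 1).
#' @return List with `membership` (named integer vector) and `modularity`
#'   (of the returned partition, |r|-weighted).
#' @export
detect_modules <- function(net, seed = 1) {
  stopifnot(inherits(net, "coab_network"))
  if (nrow(net$edges) == 0) {
    mem <- seq_len(nrow(net$nodes))
    names(mem) <- net$nodes$taxon
    return(list(membership = mem, modularity = 0))
  }
  g <- as_igraph(net)
  set.seed(make_seed(seed, 3000))
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  q_val <- igraph::modularity(g, mem, weights = igraph::E(g)$weight)
  if (q_val <= 0) {
    # no partition beats the trivial one (e.g. a complete graph): report a
    # single module, whose modularity is 0 by definition
    mem[] <- 1L
    q_val <- 0
  }
  list(membership = stats::setNames(as.integer(mem), names(mem)),
       modularity = q_val)
}

#' Within-module degree z-score and participation coefficient
#'
#' For node i with degree `k_i` and module assignment from `partition`:
#' `Zi = (k_i,own - mean_own) / sd_own` over the node's module (0 when the
#' within-module degrees have zero spread) and
#' `Pi = 1 - sum_s (k_is / k_i)^2`. Roles follow the Guimera-Amaral
#' quadrants: `peripheral` (Zi <= zi_cut, Pi <= pi_cut), `connector`
#' (Zi <= zi_cut, Pi > pi_cut), `module_hub` (Zi > zi_cut, Pi <= pi_cut),
#' `network_hub` (both above). Isolated nodes are peripheral with
#' Zi = Pi = 0. All non-peripheral roles together form the hub set.
#'
#' @param net A `coab_network`.
#' @param membership Named module membership covering all nodes (e.g. from
#'   [detect_modules()]).
#' @param zi_cut,pi_cut Role thresholds (defaults 2.5 and 0.62).
#' @return data.frame with `node`, `degree`, `module`, `Zi`, `Pi`, `role`,
#'   `is_hub`.
#' @export
zi_pi <- function(net, membership, zi_cut = 2.5, pi_cut = 0.62) {
  stopifnot(inherits(net, "coab_network"))
  nodes <- net$nodes$taxon
  if (!all(nodes %in% names(membership))) {
    stop("node absent from partition: ",
         paste(setdiff(nodes, names(membership))[1], collapse = ", "))
  }
  mem <- membership[nodes]
  edges <- net$edges
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  degree <- lengths(adj)
  k_within <- vapply(nodes, function(v) {
    sum(mem[adj[[v]]] == mem[v])
  }, numeric(1))
  zi <- numeric(length(nodes))
  for (m in unique(mem)) {
    in_m <- mem == m
    s <- stats::sd(k_within[in_m])
    zi[in_m] <- if (is.na(s) || s == 0) 0 else
      (k_within[in_m] - mean(k_within[in_m])) / s
  }
  pi_coef <- vapply(nodes, function(v) {
    if (degree[v] == 0) return(0)
    ks <- table(mem[adj[[v]]])
    1 - sum((as.numeric(ks) / degree[v])^2)
  }, numeric(1))
  role <- ifelse(zi > zi_cut & pi_coef > pi_cut, "network_hub",
          ifelse(zi > zi_cut, "module_hub",
          ifelse(pi_coef > pi_cut, "connector", "peripheral")))
  data.frame(node = nodes, degree = as.integer(degree),
             module = as.integer(mem), Zi = zi, Pi = pi_coef, role = role,
             is_hub = role != "peripheral",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global topology metrics of a co-abundance network
#'
#' Node/edge counts with signs, average degree, average local clustering
#' coefficient (unweighted; nodes with degree < 2 contribute 0), Freeman
#' degree centralization `sum(k_max - k_i) / ((N - 1)(N - 2))`, modularity of
#' the greedy partition, and the hub nodes from the Zi-Pi classification.
#'
#' @param net A `coab_network` with at least 3 nodes.
#' @param seed Seed passed to module detection.
#' @param zi_cut,pi_cut Role thresholds for the hub classification.
#' @return A `topology_report` list.
#' @export
topology_metrics <- function(net, seed = 1, zi_cut = 2.5, pi_cut = 0.62) {
  stopifnot(inherits(net, "coab_network"))
  n <- nrow(net$nodes)
  if (n < 3) stop("topology metrics need at least 3 nodes")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  n_edges <- nrow(net$edges)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero",
                                   weights = NA)
  mod <- detect_modules(net, seed = seed)
  roles <- zi_pi(net, mod$membership, zi_cut = zi_cut, pi_cut = pi_cut)
  centralization <- if (n > 2) {
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  } else NA_real_
  structure(list(
    stage = net$stage,
    n_nodes = n,
    n_edges = n_edges,
    n_positive_edges = sum(net$edges$r > 0),
    n_negative_edges = sum(net$edges$r < 0),
    average_degree = 2 * n_edges / n,
    clustering_coefficient = mean(cc_local),
    modularity = mod$modularity,
    centralization = centralization,
    hub_node_ids = roles$node[roles$is_hub],
    node_roles = roles,
    membership = mod$membership), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("topology_report", if (!is.na(x$stage)) paste0("[", x$stage, "]"), "\n")
  cat(sprintf(
    "  nodes %d  edges %d (+%d/-%d)  <k> %.3f  clustering %.3f\n",
    x$n_nodes, x$n_edges, x$n_positive_edges, x$n_negative_edges,
    x$average_degree, x$clustering_coefficient))
  cat(sprintf("  modularity %.3f  centralization %.3f  hubs %d\n",
              x$modularity, x$centralization, length(x$hub_node_ids)))
  invisible(x)
}

#' Continuous-approximation power-law exponent
#'
#' `alpha = 1 + n_tail / sum(log(x / xmin))` over the tail `x >= xmin`.
#'
#' @param degrees Degree sequence.
#' @param xmin Lower cutoff of the power-law tail.
#' @return The MLE exponent.
#' @export
power_law_alpha <- function(degrees, xmin) {
  x <- degrees[degrees >= xmin]
  stopifnot(length(x) > 0)
  s <- sum(log(x / xmin))
  if (s <= 0) stop("degenerate tail: all degrees equal xmin")
  1 + length(x) / s
}

#' Fit a power law to a degree sequence
#'
#' Continuous-approximation maximum likelihood: for a candidate `xmin`,
#' `alpha = 1 + n_tail / sum(log(x / xmin))` over the tail `x >= xmin`;
#' `xmin` is chosen by minimizing the Kolmogorov-Smirnov distance between
#' the empirical tail and the fitted CDF `1 - (x / xmin)^(1 - alpha)`. The
#' plausibility verdict is calibrated by parametric bootstrap: `n_boot`
#' synthetic tails are drawn from the fitted law, refit, and the fit is
#' called plausible when the observed KS distance is not extreme among the
#' bootstrap distances (p > 0.1).
#'
#' @param degrees Degree sequence; needs >= 20 nodes with degree >= 1 and
#'   more than one distinct value.
#' @param n_boot Bootstrap resamples for the verdict (default 100).
#' @param seed Seed for the bootstrap.
#' @param min_tail Smallest admissible tail size per xmin candidate
#'   (default 10).
#' @return A `power_law_fit` list: `alpha`, `xmin`, `ks`, `p_boot`,
#'   `plausible`, `n_tail`.
#' @export
fit_degree_distribution <- function(degrees, n_boot = 100, seed = 1,
                                    min_tail = 10) {
  x <- degrees[degrees >= 1]
  if (length(x) < 20) stop("need at least 20 nodes with degree >= 1")
  if (length(unique(x)) < 2) stop("degenerate degree sequence: all equal")
  fit_tail <- function(x) {
    cands <- sort(unique(x))
    cands <- cands[vapply(cands, function(xm) sum(x >= xm) >= min_tail,
                          logical(1))]
    if (length(cands) == 0) cands <- min(x)
    best <- NULL
    for (xm in cands) {
      tail_x <- x[x >= xm]
      slog <- sum(log(tail_x / xm))
      if (slog <= 0) next
      alpha <- 1 + length(tail_x) / slog
      ecdf_v <- stats::ecdf(tail_x)(sort(tail_x))
      fit_v <- 1 - (sort(tail_x) / xm)^(1 - alpha)
      ks <- max(abs(ecdf_v - fit_v))
      if (is.null(best) || ks < best$ks) {
        best <- list(alpha = alpha, xmin = xm, ks = ks,
                     n_tail = length(tail_x))
      }
    }
    best
  }
  obs <- fit_tail(x)
  if (is.null(obs)) stop("degenerate degree sequence")
  set.seed(make_seed(seed, 3100))
  boot_ks <- vapply(seq_len(n_boot), function(b) {
    u <- stats::runif(obs$n_tail)
    xb <- obs$xmin * (1 - u)^(-1 / (obs$alpha - 1))
    fb <- fit_tail(xb)
    if (is.null(fb)) NA_real_ else fb$ks
  }, numeric(1))
  p_boot <- mean(boot_ks >= obs$ks, na.rm = TRUE)
  structure(list(alpha = obs$alpha, xmin = obs$xmin, ks = obs$ks,
                 p_boot = p_boot, plausible = p_boot > 0.1,
                 n_tail = obs$n_tail),
            class = "power_law_fit")
}

#' Two-sample KS comparison of degree sequences
#'
#' @param degreesA,degreesB Nonempty degree sequences.
#' @return List with `statistic` and `p`.
#' @export
compare_degree_distributions <- function(degreesA, degreesB) {
  stopifnot(length(degreesA) > 0, length(degreesB) > 0)
  ks <- suppressWarnings(stats::ks.test(degreesA, degreesB, exact = FALSE))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}

#' Node partition as a list of modules
#'
#' Helper turning a membership vector into the list-of-node-sets form used
#' by [module_jaccard()].
#'
#' @param membership Named membership vector.
#' @return Named list of node-id character vectors.
#' @export
membership_to_modules <- function(membership) {
  split(names(membership), membership)
}
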