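test_that("strength filtering honors absolute and signed modes", {
  net <- toy_network(c("a", "b", 0.1), c("b", "c", 0.25), c("c", "d", -0.3))
  expect_equal(nrow(filter_by_strength(net, 0.2)$edges), 2)
  expect_equal(nrow(filter_by_strength(net, 0.2, mode = "signed")$edges), 1)
  all_kept <- filter_by_strength(net, 0)
  expect_equal(nrow(all_kept$edges), 3)
  # isolated nodes are dropped
  strong <- filter_by_strength(net, 0.26)
  expect_setequal(strong$nodes$taxon, c("c", "d"))
})

test_that("topology metrics match hand-computed values on canonical graphs", {
  star <- star_network(5)
  ts <- topology_metrics(star)
  expect_equal(ts$centralization, 1)
  expect_equal(ts$n_nodes, 6)
  expect_equal(ts$average_degree, 2 * 5 / 6)

  k5 <- complete_network(5)
  tk <- topology_metrics(k5)
  expect_equal(tk$clustering_coefficient, 1)
  expect_equal(tk$centralization, 0)
  expect_equal(tk$n_edges, 10)

  path <- toy_network(c("A", "B", 0.5), c("B", "C", -0.5))
  tp <- topology_metrics(path)
  expect_equal(tp$average_degree, 4 / 3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$n_positive_edges, 1)
  expect_equal(tp$n_negative_edges, 1)

  expect_error(topology_metrics(toy_network(c("A", "B", 0.5))), "3 nodes")
})

test_that("degree sum equals twice the edge count", {
  set.seed(5)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(30, 0.2)
    net <- igraph_to_network(g)
    tr <- topology_metrics(net)
    expect_equal(sum(tr$node_roles$degree), 2 * tr$n_edges)
  }
})

test_that("greedy modules recover planted cliques", {
  cl1 <- utils::combn(paste0("a", 1:4), 2)
  cl2 <- utils::combn(paste0("b", 1:4), 2)
  args <- c(lapply(seq_len(ncol(cl1)), function(e) c(cl1[1, e], cl1[2, e], 0.5)),
            lapply(seq_len(ncol(cl2)), function(e) c(cl2[1, e], cl2[2, e], 0.5)),
            list(c("a1", "b1", 0.5)))
  net <- do.call(toy_network, args)
  mod <- detect_modules(net)
  mem <- mod$membership
  expect_equal(length(unique(mem[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(mem[paste0("b", 1:4)])), 1)
  expect_false(mem[["a1"]] == mem[["b1"]])
  expect_gt(mod$modularity, 0.3)

  k4 <- complete_network(4)
  expect_equal(length(unique(detect_modules(k4)$membership)), 1)

  lone <- coab_network(data.frame(from = character(0), to = character(0),
                                  r = numeric(0)),
                       nodes = data.frame(taxon = c("x", "y", "z")))
  expect_equal(length(unique(detect_modules(lone)$membership)), 3)
})

test_that("modularity of the detected partition beats the trivial one", {
  set.seed(6)
  g <- igraph::sample_gnp(25, 0.15)
  net <- igraph_to_network(g)
  mod <- detect_modules(net)
  gi <- as_igraph(net)
  trivial <- igraph::modularity(gi, rep(1, igraph::vcount(gi)),
                                weights = igraph::E(gi)$weight)
  expect_gte(mod$modularity, trivial)
})

test_that("Zi-Pi roles follow the quadrant rules and partition all nodes", {
  # two 4-cliques bridged by one edge: bridge endpoints split links
  cl1 <- utils::combn(paste0("a", 1:4), 2)
  cl2 <- utils::combn(paste0("b", 1:4), 2)
  args <- c(lapply(seq_len(ncol(cl1)), function(e) c(cl1[1, e], cl1[2, e], 0.5)),
            lapply(seq_len(ncol(cl2)), function(e) c(cl2[1, e], cl2[2, e], 0.5)),
            list(c("a1", "b1", 0.5)))
  net <- do.call(toy_network, args)
  mem <- detect_modules(net)$membership
  roles <- zi_pi(net, mem)
  # all links inside own module -> Pi 0
  expect_equal(roles$Pi[roles$node == "a2"], 0)
  # a1: 3 links in own module, 1 to the other -> Pi = 1 - (3/4)^2 - (1/4)^2
  expect_equal(roles$Pi[roles$node == "a1"], 1 - (3 / 4)^2 - (1 / 4)^2)
  expect_setequal(unique(roles$role),
                  intersect(unique(roles$role),
                            c("peripheral", "connector", "module_hub",
                              "network_hub")))
  expect_true(all(table(roles$node) == 1))

  # node with equal links to two modules -> Pi = 0.5
  bridge <- toy_network(c("m", "a1", 0.5), c("m", "b1", 0.5),
                        c("a1", "a2", 0.5), c("b1", "b2", 0.5))
  mem2 <- c(m = 3L, a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  roles2 <- zi_pi(bridge, mem2)
  expect_equal(roles2$Pi[roles2$node == "m"], 0.5)
  # equal within-degree inside a module -> Zi = 0
  expect_equal(roles2$Zi[roles2$node == "a1"], 0)

  expect_error(zi_pi(bridge, mem2[-1]), "absent")
})

test_that("power-law fitting recovers a planted exponent and rejects ER", {
  expect_equal(power_law_alpha(c(1, 2, 4), 1), 1 + 3 / (log(2) + log(4)),
               tolerance = 1e-12)

  set.seed(2)
  u <- runif(500)
  x <- pmax(floor((1 - u)^(-1 / 1.5)), 1)
  f <- fit_degree_distribution(x, seed = 1)
  expect_gt(f$alpha, 2.2)
  expect_lt(f$alpha, 2.8)

  set.seed(3)
  er <- igraph::sample_gnm(500, 1500)
  f_er <- fit_degree_distribution(igraph::degree(er), seed = 1)
  expect_false(f_er$plausible)

  set.seed(4)
  ba <- igraph::sample_pa(500, m = 2, directed = FALSE)
  f_ba <- fit_degree_distribution(igraph::degree(ba), seed = 1)
  expect_true(f_ba$plausible)

  expect_error(fit_degree_distribution(rep(3, 50)), "all equal")
  expect_error(fit_degree_distribution(c(1, 2, 4)), "at least 20")
})

test_that("two-sample degree comparison behaves at the boundaries", {
  same <- compare_degree_distributions(1:20, 1:20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  apart <- compare_degree_distributions(1:5, 101:105)
  expect_equal(apart$statistic, 1)
  # null coverage: same distribution, n = 200 each
  set.seed(7)
  cover <- mean(vapply(1:100, function(b) {
    compare_degree_distributions(rpois(200, 5), rpois(200, 5))$p > 0.05
  }, logical(1)))
  expect_gte(cover, 0.9)
})
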