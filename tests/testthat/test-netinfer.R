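test_that("prevalence filter applies the ceiling rule", {
  mk <- function(prevalences, n) {
    m <- matrix(0L, length(prevalences), n)
    for (i in seq_along(prevalences)) m[i, seq_len(prevalences[i])] <- 5L
    rownames(m) <- paste0("t", seq_along(prevalences))
    m
  }
  m <- mk(c(9, 10), 100)
  kept <- prevalence_filter(m, 0.10)
  expect_identical(rownames(kept), "t2")

  m2 <- mk(c(2, 5, 8, 10, 10), 10)
  expect_equal(nrow(prevalence_filter(m2, 0.5)), 4)

  expect_error(prevalence_filter(mk(1, 100), 0.5), "all taxa")
})

test_that("fraction estimates are Dirichlet posterior means", {
  cnt <- matrix(c(9, 0, 0, 0), 4, 1,
                dimnames = list(paste0("t", 1:4), "s1"))
  fr <- estimate_fractions(cnt)
  expect_equal(as.numeric(fr), c(10, 1, 1, 1) / 13)

  cnt2 <- matrix(rpois(40, 20), 4, 10)
  expect_equal(unname(rowSums(estimate_fractions(cnt2))), rep(1, 10))

  cnt3 <- cbind(cnt2, bad = c(0, 0, 0, 0))
  expect_error(estimate_fractions(cnt3), "bad")
})

test_that("equal log-ratio variances give zero correlations analytically", {
  p <- 6
  t_const <- matrix(0.8, p, p)
  diag(t_const) <- 0
  fit <- sparcc_from_variation(t_const)
  expect_equal(fit$basis_var, rep(0.4, p), tolerance = 1e-12)
  off <- fit$r[upper.tri(fit$r)]
  expect_equal(off, rep(0, length(off)), tolerance = 1e-12)
  expect_equal(diag(fit$r), rep(1, p))
})

test_that("proportional taxa reach correlation one", {
  set.seed(8)
  base <- matrix(rgamma(5 * 40, 2), 40, 5)
  base[, 2] <- 3 * base[, 1]     # exactly proportional pair
  fr <- base / rowSums(base)
  fit <- sparcc_fraction_cor(fr)
  expect_gt(fit$r[1, 2], 0.99)
})

test_that("sparcc matches an independent brute-force solve on toy tables", {
  for (p in 4:8) {
    fr <- random_fractions(30, p, seed = 100 + p)
    mine <- sparcc_fraction_cor(fr)$r
    oracle <- brute_force_sparcc(fr)
    expect_equal(mine, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("permutation p-values hit the smoothing floor on a planted edge", {
  spec <- planted_network_spec(10, "A",
                               conserved_edges = data.frame(i = 1, j = 2,
                                                            rho = 0.8))
  sc <- generate_stage_correlations(spec)
  cnt <- generate_counts(sc$correlations$A, n_samples = 300, depth = 20000,
                         seed = 9)
  fit <- sparcc(cnt, n_inner = 1)
  pm <- permutation_pvalues(cnt, fit$r, n_permutations = 200, seed = 2)
  expect_equal(pm[1, 2], 1 / 201)
  ut <- pm[upper.tri(pm)]
  expect_true(all(ut > 0 & ut <= 1))
  pm2 <- permutation_pvalues(cnt, fit$r, n_permutations = 200, seed = 2)
  expect_identical(pm, pm2)
})

test_that("permutation p-values are near-uniform under the global null", {
  cnt <- generate_counts(diag(21), n_samples = 50, depth = 20000, seed = 11)
  fit <- sparcc(cnt, n_inner = 1)
  pm <- permutation_pvalues(cnt, fit$r, n_permutations = 500, seed = 12)
  pv <- pm[upper.tri(pm)]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # matrix form adjusts the upper triangle and mirrors it
  p <- matrix(0.5, 4, 4)
  p[1, 2] <- p[2, 1] <- 0.001
  q <- bh_adjust(p)
  expect_equal(q[1, 2], q[2, 1])
  expect_equal(q[1, 2], 0.006)
})

test_that("network building respects the FDR cutoff", {
  r <- matrix(0.5, 4, 4); diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("t", 1:4)
  q1 <- matrix(1, 4, 4)
  expect_equal(nrow(build_network(r, NULL, q1, 0.05)$edges), 0)

  q2 <- q1
  q2[1, 2] <- q2[1, 3] <- q2[2, 4] <- 0.01
  net <- build_network(r, NULL, q2, 0.05)
  expect_equal(nrow(net$edges), 3)

  # edge count is monotone non-increasing as the cutoff tightens
  set.seed(21)
  qr_ <- matrix(runif(100), 10, 10)
  qr_[lower.tri(qr_)] <- t(qr_)[lower.tri(qr_)]
  rr <- matrix(0.3, 10, 10); diag(rr) <- 1
  counts <- vapply(c(1, 0.5, 0.2, 0.1, 0.05, 0.01), function(cut) {
    nrow(build_network(rr, NULL, qr_, cut)$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("beneficial subnetwork is the closed neighborhood subgraph", {
  star <- star_network(4)
  star$nodes$beneficial <- star$nodes$taxon == "c"
  sub <- extract_beneficial_subnetwork(star)
  expect_setequal(sub$nodes$taxon, star$nodes$taxon)
  expect_equal(nrow(sub$edges), 4)

  path <- toy_network(c("A", "B", 0.4), c("B", "C", 0.4))
  path$nodes$beneficial <- path$nodes$taxon == "B"
  sub2 <- extract_beneficial_subnetwork(path)
  expect_setequal(sub2$nodes$taxon, c("A", "B", "C"))
  expect_equal(nrow(sub2$edges), 2)

  # beneficial node with no incident edges stays as an isolated node
  iso <- toy_network(c("A", "B", 0.4), nodes = c("A", "B", "Z"))
  iso$nodes$beneficial <- iso$nodes$taxon == "Z"
  sub3 <- extract_beneficial_subnetwork(iso)
  expect_identical(sub3$nodes$taxon, "Z")
  expect_equal(nrow(sub3$edges), 0)

  iso$nodes$beneficial <- FALSE
  expect_error(extract_beneficial_subnetwork(iso), "no beneficial")
})

test_that("planted edges are recovered through the full inference chain", {
  # 10 planted strong edges among 24 taxa, n = 300
  cons <- data.frame(i = seq(1, 19, 2), j = seq(2, 20, 2), rho = 0.7)
  spec <- planted_network_spec(24, "A", conserved_edges = cons)
  sc <- generate_stage_correlations(spec)
  cnt <- generate_counts(sc$correlations$A, n_samples = 300, depth = 20000,
                         seed = 13)
  fit <- sparcc(cnt, n_inner = 5, seed = 1)
  pm <- permutation_pvalues(cnt, fit$r, n_permutations = 600, seed = 3)
  qm <- bh_adjust(pm)
  net <- build_network(fit$r, pm, qm, q_cutoff = 0.05, stage = "A")
  keys <- edge_key(net$edges$from, net$edges$to)
  planted <- edge_key(sprintf("t%03d", cons$i), sprintf("t%03d", cons$j))
  expect_gte(sum(planted %in% keys), 9)
  # recovered planted edges carry the planted (positive) sign
  rec <- net$edges$r[keys %in% planted]
  expect_true(all(rec > 0))
})
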