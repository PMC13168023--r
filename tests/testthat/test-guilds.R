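test_that("association scan ranks a perfect predictor first and controls the null", {
  set.seed(31)
  n <- 40
  counts <- matrix(rpois(50 * n, 100), 50, n,
                   dimnames = list(sprintf("f%02d", 1:50),
                                   sprintf("s%02d", 1:n)))
  pheno <- log2((counts[7, ] + 0.5) / colSums(counts))
  res <- associate_features(counts, pheno)
  expect_identical(res$feature[1], "f07")
  expect_equal(res$q[1], min(res$q))

  # phenotype independent of all features: few false positives at q < 0.2
  set.seed(32)
  null_counts <- matrix(rpois(200 * n, 50), 200, n,
                        dimnames = list(sprintf("g%03d", 1:200), NULL))
  null_pheno <- rnorm(n)
  null_res <- associate_features(null_counts, null_pheno)
  expect_lte(mean(null_res$significant), 0.25)
})

test_that("association scan recovers planted guild members with sign", {
  scn <- small_scenario()
  sc <- generate_stage_correlations(scn$network_spec)
  cnt <- generate_counts(sc$correlations$D120, n_samples = 200,
                         depth = 50000, seed = 15)
  pheno <- generate_phenotype(cnt, scn$guild_spec, seed = 15)
  res <- associate_features(cnt, pheno)
  g1 <- sprintf("t%03d", 1:5)
  hits <- res$significant & res$direction == "positive" &
    res$feature %in% g1
  expect_gte(sum(hits) / length(g1), 0.8)
})

test_that("guild detection two-colors the signed graph", {
  net <- toy_network(c("1", "2", 0.5), c("3", "4", 0.5),
                     c("1", "3", -0.5), c("2", "4", -0.5))
  part <- detect_guilds(net)
  expect_setequal(part$guild1, c("1", "2"))
  expect_setequal(part$guild2, c("3", "4"))
  expect_equal(nrow(part$frustrated), 0)
  expect_equal(check_guild_partition(part, net), 0)

  tri <- toy_network(c("a", "b", 0.5), c("b", "c", 0.5), c("a", "c", 0.5))
  expect_message(part_tri <- detect_guilds(tri), "single guild")
  expect_setequal(part_tri$guild1, c("a", "b", "c"))
  expect_length(part_tri$unassigned, 0)

  # negative triangle: an odd cycle cannot be two-colored
  ntri <- toy_network(c("a", "b", -0.5), c("b", "c", -0.5),
                      c("a", "c", -0.5))
  part_n <- detect_guilds(ntri)
  expect_gte(nrow(part_n$frustrated), 1)
  expect_equal(check_guild_partition(part_n, ntri), 0)

  # supernode with no negative edges stays unassigned
  mixed <- toy_network(c("1", "2", 0.5), c("3", "4", 0.5),
                       c("1", "3", -0.5), c("8", "9", 0.5))
  part_m <- detect_guilds(mixed)
  expect_setequal(part_m$unassigned, c("8", "9"))
})

test_that("guild orientation follows the phenotype association signs", {
  net <- toy_network(c("1", "2", 0.5), c("3", "4", 0.5), c("1", "3", -0.5))
  assoc <- data.frame(feature = c("1", "2", "3", "4"),
                      direction = c("negative", "negative", "positive",
                                    "positive"))
  part <- detect_guilds(net, association = assoc)
  expect_setequal(part$guild1, c("3", "4"))
})

test_that("guild abundance sums close under full coverage", {
  counts <- matrix(c(10, 20, 30, 40, 5, 15, 25, 55), 4, 2,
                   dimnames = list(c("1", "2", "3", "4"), c("s1", "s2")))
  part <- structure(list(guild1 = c("1", "2"), guild2 = c("3", "4"),
                         unassigned = character(0),
                         frustrated = data.frame()),
                    class = "guild_partition")
  gab <- guild_abundance(counts, part)
  expect_equal(gab$guild1 + gab$guild2, c(1, 1))
  single <- structure(list(guild1 = "1", guild2 = "3",
                           unassigned = character(0),
                           frustrated = data.frame()),
                      class = "guild_partition")
  g1 <- guild_abundance(counts, single)
  expect_equal(g1$guild1, counts["1", ] / colSums(counts),
               ignore_attr = TRUE)
})

test_that("rank-sum comparison is exact for small separated groups", {
  sep <- compare_groups(c(1:5, 11:15), rep(c("a", "b"), each = 5))
  expect_equal(sep$p, 2 / choose(10, 5))

  ident <- compare_groups(c(1:6, 1:6), rep(c("a", "b"), each = 6))
  expect_gt(ident$p, 0.99)

  set.seed(33)
  power <- mean(vapply(1:100, function(b) {
    x <- rnorm(30); y <- rnorm(30, 2)
    compare_groups(c(x, y), rep(c("a", "b"), each = 30))$p < 0.01
  }, logical(1)))
  expect_gte(power, 0.95)

  expect_error(compare_groups(1:5, c("a", "a", "a", "b", "b")), ">= 3")
})

test_that("functional Shannon diversity follows the entropy formula", {
  m <- rbind(one = c(7, 0, 0, 0), four = c(3, 3, 3, 3),
             mix = c(1, 1, 2, 0))
  h <- ko_shannon(m)
  expect_equal(unname(h["one"]), 0)
  expect_equal(unname(h["four"]), log(4))
  expect_equal(unname(h["mix"]),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-10)
  expect_error(ko_shannon(rbind(m, none = c(0, 0, 0, 0))), "none")
})

test_that("enrichment scan flags separation and controls the null", {
  guild <- rep(c("g1", "g2"), each = 20)
  sep_feat <- c(rep(1, 20), rep(0, 20))
  flat_feat <- rep(c(0, 1), 20)
  m <- cbind(sep = sep_feat, flat = flat_feat)
  rownames(m) <- sprintf("mag%02d", 1:40)
  res <- enrichment_scan(m, guild)
  expect_true(res$significant[res$feature == "sep"])
  expect_identical(res$enriched_in[res$feature == "sep"], "g1")
  expect_false(res$significant[res$feature == "flat"])

  set.seed(34)
  null_m <- matrix(rbinom(40 * 500, 1, 0.4), 40, 500,
                   dimnames = list(NULL, sprintf("k%03d", 1:500)))
  null_res <- enrichment_scan(null_m, guild)
  expect_lte(mean(null_res$significant), 0.07)

  # count features go through the overdispersion-robust branch
  set.seed(35)
  cm <- cbind(up = c(rpois(20, 20), rpois(20, 5)), noise = rpois(40, 10))
  cres <- enrichment_scan(cm, guild)
  expect_true(cres$significant[cres$feature == "up"])
})

test_that("Fisher proportion test matches hypergeometric arithmetic", {
  flat <- proportion_test(5, 5, 5, 5)
  expect_equal(flat$p, 1)
  skew <- proportion_test(1, 9, 9, 1)
  expect_lt(skew$p, 0.0015)
  expect_gt(skew$p, 0.0008)
  extreme <- proportion_test(10, 0, 0, 10)
  expect_lt(extreme$p, 1e-4)
})
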