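test_that("stage correlation matrices reproduce the planted structure", {
  # no edges, zero background -> identity at every stage
  spec0 <- planted_network_spec(6, c("A", "B"))
  out0 <- generate_stage_correlations(spec0)
  expect_equal(out0$correlations$A, diag(6), ignore_attr = TRUE)
  expect_equal(out0$correlations$B, diag(6), ignore_attr = TRUE)

  # one conserved edge appears identically at all stages
  spec1 <- planted_network_spec(8, c("A", "B", "C"),
                                conserved_edges = data.frame(i = 2, j = 5,
                                                             rho = 0.5))
  out1 <- generate_stage_correlations(spec1)
  for (s in c("A", "B", "C")) {
    expect_equal(out1$correlations[[s]][2, 5], 0.5)
    expect_equal(out1$correlations[[s]][5, 2], 0.5)
  }

  # a variable edge is the only entry where stages differ
  var <- data.frame(i = 1, j = 4, rho_A = 0.4, rho_B = -0.4, rho_C = 0.4)
  spec2 <- planted_network_spec(8, c("A", "B", "C"), variable_edges = var)
  out2 <- generate_stage_correlations(spec2)
  d_ab <- out2$correlations$A - out2$correlations$B
  nz <- which(d_ab != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("1 4", "4 1"))
  expect_equal(out2$correlations$A[1, 4], 0.4)
  expect_equal(out2$correlations$B[1, 4], -0.4)
  expect_equal(out2$correlations$A, out2$correlations$C)
  expect_equal(out2$truth$edges$label, "variable")
})

test_that("invalid planted specs are rejected", {
  expect_error(planted_network_spec(5, "A",
                                    conserved_edges = data.frame(i = 1, j = 9,
                                                                 rho = 0.5)),
               "out of range")
  expect_error(planted_network_spec(5, "A",
                                    conserved_edges = data.frame(
                                      i = c(1, 2), j = c(2, 1),
                                      rho = c(0.5, 0.3))),
               "listed twice")
  expect_error(planted_network_spec(5, "A",
                                    conserved_edges = data.frame(i = 1, j = 1,
                                                                 rho = 0.5)),
               "self-pairs")
  # frustrated triangle cannot be repaired within the planted tolerance
  bad <- planted_network_spec(3, "A",
                              conserved_edges = data.frame(
                                i = c(1, 1, 2), j = c(2, 3, 3),
                                rho = c(0.9, 0.9, -0.9)))
  expect_error(generate_stage_correlations(bad), "not repairable")
})

test_that("counts close to the stated depth and reproduce under the seed", {
  spec <- planted_network_spec(12, c("A", "B"),
                               conserved_edges = data.frame(i = 1, j = 2,
                                                            rho = 0.8))
  sc <- generate_stage_correlations(spec)
  cnts <- generate_counts(sc$correlations, n_samples = 15, depth = 2000,
                          seed = 4)
  for (s in c("A", "B")) {
    expect_true(all(colSums(cnts[[s]]) == 2000))
    expect_equal(dim(cnts[[s]]), c(12, 15))
  }
  again <- generate_counts(sc$correlations, n_samples = 15, depth = 2000,
                           seed = 4)
  expect_identical(cnts, again)
  other <- generate_counts(sc$correlations, n_samples = 15, depth = 2000,
                           seed = 5)
  expect_false(identical(cnts, other))
})

test_that("a strongly correlated planted pair survives the CLR transform", {
  spec <- planted_network_spec(20, "A",
                               conserved_edges = data.frame(i = 1, j = 2,
                                                            rho = 0.8))
  sc <- generate_stage_correlations(spec)
  cnt <- generate_counts(sc$correlations$A, n_samples = 500, depth = 50000,
                         seed = 3)
  clr <- apply(log(cnt + 0.5), 2, function(x) x - mean(x))
  expect_gt(stats::cor(clr[1, ], clr[2, ]), 0.5)
})

test_that("phenotype follows the planted guild model", {
  scn <- small_scenario()
  sc <- generate_stage_correlations(scn$network_spec)
  cnt <- generate_counts(sc$correlations$D120, n_samples = 200,
                         depth = 50000, seed = 5)
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  diff <- colSums(rel[1:5, ]) - colSums(rel[6:9, ])

  null_spec <- planted_guild_spec(1:5, 6:9, effect_size = 0, noise_sd = 0)
  expect_equal(max(abs(generate_phenotype(cnt, null_spec, seed = 1))), 0,
               tolerance = 1e-10)

  exact_spec <- planted_guild_spec(1:5, 6:9, effect_size = 1, noise_sd = 0)
  expect_equal(unname(generate_phenotype(cnt, exact_spec, seed = 1)),
               unname(diff), tolerance = 1e-12)

  noisy <- generate_phenotype(cnt, scn$guild_spec, seed = 5)
  expect_gt(stats::cor(noisy, diff), 0.8)
  expect_identical(noisy, generate_phenotype(cnt, scn$guild_spec, seed = 5))

  expect_error(generate_phenotype(cnt[1:3, ],
                                  planted_guild_spec(1:2, 4:5)),
               "exceeds")
})

test_that("planted truth serializes round-trip identical", {
  scn <- small_scenario()
  sc <- generate_stage_correlations(scn$network_spec)
  path <- withr::local_tempfile(fileext = ".json")
  truth_to_json(sc$truth, path)
  back <- truth_from_json(path)
  expect_identical(back$taxa, sc$truth$taxa)
  expect_identical(back$stages, sc$truth$stages)
  expect_identical(back$beneficial, sc$truth$beneficial)
  expect_equal(back$edges, sc$truth$edges)
})

test_that("metabolic fixtures carry the planted anti-correlation structure", {
  gs <- planted_guild_spec(1:6, 7:12)
  fix <- generate_metabolic_fixtures(gs, n_pathways = 40, seed = 2)
  n <- length(fix$strains)
  expect_equal(n, 12)
  ut <- upper.tri(fix$mro)
  expect_true(all(fix$mro[ut] >= 0 & fix$mro[ut] <= 1))
  expect_true(all(fix$mip[ut] >= 0 & fix$mip[ut] <= 1))
  expect_equal(fix$mro, t(fix$mro))
  expect_equal(fix$mip, t(fix$mip))
  expect_true(all(fix$pathways %in% c(0, 1)))
  # competition and complementarity anti-correlated across pairs
  expect_lt(stats::cor(fix$mro[ut], fix$mip[ut]), 0)
  # complementarity grows with phylogenetic distance
  expect_gt(stats::cor(fix$mip[ut], fix$phylo_dist[ut]), 0)
  # MRO is the pathway overlap coefficient (oracle recomputation)
  sizes <- rowSums(fix$pathways)
  i <- 3; j <- 9
  ov <- sum(fix$pathways[i, ] & fix$pathways[j, ]) / min(sizes[i], sizes[j])
  expect_equal(fix$mro[i, j], ov)
  # identical pathway repertoires would give overlap 1: check the formula
  # on the diagonal (a strain against itself)
  expect_true(all(diag(fix$mro) == 1))

  expect_identical(fix, generate_metabolic_fixtures(gs, n_pathways = 40,
                                                    seed = 2))
  expect_error(generate_metabolic_fixtures(planted_guild_spec(1:2, 3)),
               "at least 4")
})
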