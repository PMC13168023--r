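#' Pipeline configuration
#'
#' Collects every threshold the pipeline applies, with the conventional
#' defaults: prevalence 0.10, network FDR 0.05, strength cut 0.2, stability
#' alpha 0.05, I2 cut 75, heterogeneity FDR 0.05, association FDR 0.2,
#' Zi 2.5 / Pi 0.62, outlier Z 2.698, core 0.90 / cloud 0.10 pathway
#' prevalence, 10 robustness replicates, 1000 permutations. All thresholds
#' are validated against their documented domains and the configuration
#' round-trips through YAML unchanged.
#'
#' @param seed Master seed (every stochastic step derives from it).
#' @param stages Ordered stage labels.
#' @param simulate Generate synthetic data (default TRUE); otherwise
#'   `abundance_paths` (named by stage) and `metadata_path` must be set.
#' @param abundance_paths,metadata_path Input paths when `simulate = FALSE`.
#' @param n_taxa,n_samples,depth Synthetic scenario size.
#' @param phenotype_stage Stage whose samples carry the phenotype scan.
#' @param min_prevalence,network_fdr,n_permutations,n_inner,exclusion_threshold,max_exclusions
#'   Network-inference settings.
#' @param strength_cut,zi_cut,pi_cut Topology settings.
#' @param alpha_stable,i2_cut,heterogeneity_fdr Conservation settings.
#' @param association_fdr,guild_edge_p Guild settings.
#' @param outlier_z,core_prevalence,cloud_prevalence Metabolic settings.
#' @param robustness_reps Robustness replicates.
#' @return A validated `coab_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("D25", "D120", "D240"),
                            simulate = TRUE,
                            abundance_paths = NULL,
                            metadata_path = NULL,
                            n_taxa = 150, n_samples = 300, depth = 50000,
                            phenotype_stage = "D120",
                            min_prevalence = 0.10, network_fdr = 0.05,
                            n_permutations = 1000, n_inner = 20,
                            exclusion_threshold = 0.1, max_exclusions = 10,
                            strength_cut = 0.2, zi_cut = 2.5, pi_cut = 0.62,
                            alpha_stable = 0.05, i2_cut = 75,
                            heterogeneity_fdr = 0.05,
                            association_fdr = 0.2, guild_edge_p = 0.05,
                            outlier_z = 2.698, core_prevalence = 0.90,
                            cloud_prevalence = 0.10, robustness_reps = 10) {
  cfg <- list(seed = as.integer(seed), stages = stages,
              simulate = isTRUE(simulate),
              abundance_paths = abundance_paths,
              metadata_path = metadata_path,
              n_taxa = as.integer(n_taxa),
              n_samples = as.integer(n_samples),
              depth = as.integer(depth),
              phenotype_stage = phenotype_stage,
              min_prevalence = min_prevalence, network_fdr = network_fdr,
              n_permutations = as.integer(n_permutations),
              n_inner = as.integer(n_inner),
              exclusion_threshold = exclusion_threshold,
              max_exclusions = as.integer(max_exclusions),
              strength_cut = strength_cut, zi_cut = zi_cut, pi_cut = pi_cut,
              alpha_stable = alpha_stable, i2_cut = i2_cut,
              heterogeneity_fdr = heterogeneity_fdr,
              association_fdr = association_fdr,
              guild_edge_p = guild_edge_p,
              outlier_z = outlier_z, core_prevalence = core_prevalence,
              cloud_prevalence = cloud_prevalence,
              robustness_reps = as.integer(robustness_reps))
  validate_config(cfg)
  class(cfg) <- "coab_config"
  cfg
}

validate_config <- function(cfg) {
  in_range <- function(x, lo, hi, name, lo_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) && x <= hi
    if (!ok) stop("config field ", name, " outside its domain [",
                  lo, ", ", hi, "]")
  }
  stopifnot(length(cfg$stages) >= 2, !anyDuplicated(cfg$stages))
  if (!cfg$phenotype_stage %in% cfg$stages) {
    stop("phenotype_stage must be one of the stages")
  }
  in_range(cfg$min_prevalence, 0, 1, "min_prevalence", lo_open = TRUE)
  in_range(cfg$network_fdr, 0, 1, "network_fdr", lo_open = TRUE)
  in_range(cfg$strength_cut, 0, 1, "strength_cut")
  in_range(cfg$alpha_stable, 0, 1, "alpha_stable", lo_open = TRUE)
  in_range(cfg$i2_cut, 0, 100, "i2_cut")
  in_range(cfg$heterogeneity_fdr, 0, 1, "heterogeneity_fdr", lo_open = TRUE)
  in_range(cfg$association_fdr, 0, 1, "association_fdr", lo_open = TRUE)
  in_range(cfg$guild_edge_p, 0, 1, "guild_edge_p", lo_open = TRUE)
  in_range(cfg$zi_cut, 0, Inf, "zi_cut")
  in_range(cfg$pi_cut, 0, 1, "pi_cut")
  in_range(cfg$outlier_z, 0, Inf, "outlier_z", lo_open = TRUE)
  in_range(cfg$core_prevalence, 0, 1, "core_prevalence")
  in_range(cfg$cloud_prevalence, 0, 1, "cloud_prevalence")
  if (cfg$n_permutations < 100) stop("n_permutations must be >= 100")
  if (cfg$robustness_reps < 1) stop("robustness_reps must be >= 1")
  if (!cfg$simulate) {
    if (is.null(cfg$abundance_paths) || is.null(cfg$metadata_path)) {
      stop("abundance_paths and metadata_path are required when ",
           "simulate = FALSE")
    }
    if (!all(cfg$stages %in% names(cfg$abundance_paths))) {
      stop("abundance_paths must be named by stage")
    }
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `coab_config`.
#' @param path File path.
#' @return `read_config()` returns the restored, re-validated
#'   `coab_config`; the round trip is exact.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coab_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stages <- as.character(raw$stages)
  if (!is.null(raw$abundance_paths)) {
    raw$abundance_paths <- unlist(raw$abundance_paths)
  }
  cfg <- do.call(pipeline_config, raw)
  cfg
}

#' Default synthetic study scenario
#'
#' The planted structure exercised by the full pipeline. With the default
#' 150 taxa: two antagonistic guilds among the dominant taxa (members
#' 1-12 and 13-22; within-guild latent correlation +0.6, between-guild
#' -0.5, phenotype effect 5 with unit noise), 20 strong conserved pairs
#' (rho 0.7) and 10 weak conserved pairs (rho 0.25) among mid-abundance
#' taxa, and 10 variable pairs whose correlation flips sign across stages
#' (+0.6, -0.6, +0.6). Guild-1 members plus ten mid-abundance taxa carry
#' the beneficial flag.
#'
#' @param n_taxa Number of taxa (>= 110 for the default layout).
#' @param stages Stage labels (3 stages for the default layout).
#' @return List with `network_spec` (a [planted_network_spec()]) and
#'   `guild_spec` (a [planted_guild_spec()]).
#' @export
default_synthetic_scenario <- function(n_taxa = 150,
                                       stages = c("D25", "D120", "D240")) {
  stopifnot(n_taxa >= 110, length(stages) == 3)
  g1 <- 1:12; g2 <- 13:22
  guild_spec <- planted_guild_spec(g1, g2, within_rho = 0.6,
                                   between_rho = -0.5, effect_size = 5,
                                   noise_sd = 1)
  pairs_of <- function(members) {
    idx <- utils::combn(members, 2)
    data.frame(i = idx[1, ], j = idx[2, ])
  }
  within1 <- cbind(pairs_of(g1), rho = 0.6)
  within2 <- cbind(pairs_of(g2), rho = 0.6)
  between <- cbind(expand.grid(i = g1, j = g2, KEEP.OUT.ATTRS = FALSE),
                   rho = -0.5)
  strong <- data.frame(i = seq(31, 69, 2), j = seq(32, 70, 2), rho = 0.7)
  weak <- data.frame(i = seq(91, 109, 2), j = seq(92, 110, 2), rho = 0.25)
  conserved <- rbind(within1, within2, between, strong, weak)
  variable <- data.frame(i = seq(71, 89, 2), j = seq(72, 90, 2))
  variable[[paste0("rho_", stages[1])]] <- 0.6
  variable[[paste0("rho_", stages[2])]] <- -0.6
  variable[[paste0("rho_", stages[3])]] <- 0.6
  beneficial <- rep(FALSE, n_taxa)
  beneficial[c(g1, 31:40)] <- TRUE
  spec <- planted_network_spec(n_taxa, stages,
                               conserved_edges = conserved,
                               variable_edges = variable,
                               background_rho = 0,
                               beneficial = beneficial)
  list(network_spec = spec, guild_spec = guild_spec)
}

#' Run the full co-abundance analysis pipeline
#'
#' Executes, in order: (1) simulate (or load) stage abundance tables and
#' phenotype; (2) per-stage network inference (prevalence filter, SparCC,
#' permutation p-values, BH, FDR edge filter); (3) beneficial subnetwork
#' extraction; (4) cross-stage edge dynamics (conservation /
#' heterogeneity classification, pairwise change categories, summary);
#' (5) topology of the strength-filtered networks (metrics, modules,
#' Zi-Pi roles, degree-distribution fits and comparisons); (6) resilience
#' (wMIS, core nodes, stability, efficiency, vulnerability, robustness
#' simulation); (7) phenotype-associated guild detection; (8) metabolic
#' competition / complementarity scoring of the guild members. Every
#' artifact is written under `out_dir` with a JSON manifest (config, seed,
#' versions, file checksums), and the run is fully reproducible under a
#' fixed seed.
#'
#' Seed-offset registry (all derived with [make_seed()] from
#' `config$seed`): counts per stage `200 + k`; phenotype noise `300`;
#' metabolic fixtures `400`; SparCC inner resampling `500 + i` (from the
#' per-stage seed); permutations `700 + b` (from the per-stage seed);
#' per-stage SparCC `1000 + k`; per-stage permutation base `2000 + k`;
#' module detection `3000`; degree bootstrap `3100`; robustness replicate
#' `4000/4500 + b` (from the per-stage seed `6000 + k`); guild network
#' SparCC `5000`, permutations `5100`.
#'
#' @param config A `coab_config` from [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param scenario Optional synthetic scenario overriding
#'   [default_synthetic_scenario()] (must match `config$n_taxa`).
#' @return Invisibly, a list with all stage results (`counts`,
#'   `phenotype`, `truth`, `networks`, `subnetworks`, `edge_table`,
#'   `conservation`, `conservation_summary`, `pairwise_changes`,
#'   `topology`, `degree_comparisons`, `resilience`, `association`,
#'   `guilds`, `guild_network`, `guild_abundance`, `group_comparison`,
#'   `metabolic`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, scenario = NULL) {
  stopifnot(inherits(config, "coab_config"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stages <- config$stages
  done <- character()
  res <- list()

  # -- 1: simulate or load ---------------------------------------------
  run_stage("simulate", {
    if (config$simulate) {
      if (is.null(scenario)) {
        scenario <- default_synthetic_scenario(config$n_taxa, stages)
      }
      stopifnot(scenario$network_spec$n_taxa == config$n_taxa)
      sc <- generate_stage_correlations(scenario$network_spec)
      counts <- generate_counts(sc$correlations, config$n_samples,
                                depth = config$depth, seed = seed)
      phenotype <- generate_phenotype(counts[[config$phenotype_stage]],
                                      scenario$guild_spec, seed = seed)
      res$truth <- sc$truth
      res$guild_spec <- scenario$guild_spec
      res$counts <- counts
      res$phenotype <- phenotype
      res$beneficial <- stats::setNames(scenario$network_spec$beneficial,
                                         sc$truth$taxa)
      for (s in stages) {
        write_abundance(counts[[s]],
                        file.path(out_dir, paste0("abundance_", s, ".tsv")))
      }
      meta <- data.frame(
        sample = unlist(lapply(counts, colnames), use.names = FALSE),
        stage = rep(stages, vapply(counts, ncol, integer(1))))
      meta$phenotype <- phenotype[meta$sample]
      write_metadata(meta, file.path(out_dir, "metadata.tsv"))
      write_taxonomy(sc$truth$taxa, scenario$network_spec$beneficial,
                     file.path(out_dir, "taxonomy.tsv"))
      truth_to_json(sc$truth, file.path(out_dir, "truth.json"))
    } else {
      counts <- lapply(config$abundance_paths[stages], read_abundance)
      names(counts) <- stages
      meta <- utils::read.delim(config$metadata_path,
                                stringsAsFactors = FALSE)
      res$counts <- counts
      res$phenotype <- stats::setNames(meta$phenotype, meta$sample)
      res$beneficial <- NULL
      res$truth <- NULL
    }
  }, done)

  # -- 2: per-stage networks -------------------------------------------
  run_stage("network", {
    networks <- list()
    for (k in seq_along(stages)) {
      s <- stages[k]
      filt <- prevalence_filter(res$counts[[s]], config$min_prevalence)
      fit <- sparcc(filt, exclusion_threshold = config$exclusion_threshold,
                    max_exclusions = config$max_exclusions,
                    n_inner = config$n_inner,
                    seed = make_seed(seed, 1000 + k))
      pmat <- permutation_pvalues(filt, fit$r,
                                  n_permutations = config$n_permutations,
                                  seed = make_seed(seed, 2000 + k),
                                  exclusion_threshold =
                                    config$exclusion_threshold,
                                  max_exclusions = config$max_exclusions)
      qmat <- bh_adjust(pmat)
      rel <- sweep(filt, 2, colSums(filt), "/")
      networks[[s]] <- build_network(
        fit$r, pmat, qmat, q_cutoff = config$network_fdr, stage = s,
        mean_abundance = rowMeans(rel),
        beneficial = res$beneficial,
        n_samples = ncol(filt))
      write_edge_table(networks[[s]],
                       file.path(out_dir, paste0("edges_", s, ".tsv")))
      write_graphml(networks[[s]],
                    file.path(out_dir, paste0("network_", s, ".graphml")))
    }
    res$networks <- networks
  }, done)

  # -- 3: beneficial subnetworks ---------------------------------------
  run_stage("subnetwork", {
    if (!is.null(res$beneficial) && any(res$beneficial)) {
      res$subnetworks <- lapply(res$networks,
                                 extract_beneficial_subnetwork)
      for (s in stages) {
        write_edge_table(res$subnetworks[[s]],
                         file.path(out_dir,
                                   paste0("subnetwork_", s, ".tsv")))
      }
    } else {
      res$subnetworks <- NULL
    }
  }, done)

  # -- 4: cross-stage edge dynamics ------------------------------------
  run_stage("dynamics", {
    tab <- match_edges(res$networks)
    cons <- classify_conservation(tab, alpha_stable = config$alpha_stable,
                                  i2_cut = config$i2_cut,
                                  fdr_cut = config$heterogeneity_fdr)
    pair_cons <- classify_conservation(tab, stages = stages[1:2],
                                       alpha_stable = config$alpha_stable,
                                       i2_cut = config$i2_cut,
                                       fdr_cut = config$heterogeneity_fdr)
    het <- pair_cons[pair_cons$label == "heterogeneous", , drop = FALSE]
    changes <- if (nrow(het) > 0) {
      qa <- tab[[paste0("q_", stages[1])]][match(
        edge_key(het$from, het$to), edge_key(tab$from, tab$to))]
      qb <- tab[[paste0("q_", stages[2])]][match(
        edge_key(het$from, het$to), edge_key(tab$from, tab$to))]
      cbind(het[c("from", "to")],
            classify_pairwise_change(het[[paste0("r_", stages[1])]],
                                     het[[paste0("r_", stages[2])]],
                                     qa < config$network_fdr,
                                     qb < config$network_fdr))
    } else NULL
    res$edge_table <- tab
    res$conservation <- cons
    res$pairwise_conservation <- pair_cons
    res$pairwise_changes <- changes
    res$conservation_summary <- if (nrow(cons) > 0)
      summarize_conservation(cons$label) else NULL
    utils::write.table(cons, file.path(out_dir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, done)

  # -- 5: topology ------------------------------------------------------
  run_stage("topology", {
    topo <- list(); degfits <- list()
    for (s in stages) {
      strong <- filter_by_strength(res$networks[[s]], config$strength_cut)
      if (nrow(strong$nodes) >= 3) {
        topo[[s]] <- topology_metrics(strong, seed = seed,
                                      zi_cut = config$zi_cut,
                                      pi_cut = config$pi_cut)
        roles <- topo[[s]]$node_roles
        utils::write.table(roles,
                           file.path(out_dir, paste0("roles_", s, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        degfits[[s]] <- tryCatch(
          fit_degree_distribution(roles$degree, seed = seed),
          error = function(e) NULL)
      }
      res$strong_networks[[s]] <- strong
    }
    cmp <- list()
    pairs <- utils::combn(names(topo), 2)
    for (cidx in seq_len(ncol(pairs))) {
      a <- pairs[1, cidx]; b <- pairs[2, cidx]
      cmp[[paste(a, b, sep = "_vs_")]] <- compare_degree_distributions(
        topo[[a]]$node_roles$degree, topo[[b]]$node_roles$degree)
    }
    res$topology <- topo
    res$degree_fits <- degfits
    res$degree_comparisons <- cmp
    report <- lapply(topo, function(x) x[c(
      "n_nodes", "n_edges", "n_positive_edges", "n_negative_edges",
      "average_degree", "clustering_coefficient", "modularity",
      "centralization")])
    jsonlite::write_json(report, file.path(out_dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA)
  }, done)

  # -- 6: resilience ----------------------------------------------------
  run_stage("resilience", {
    nets <- res$strong_networks
    core <- core_nodes(nets)
    resil <- list()
    for (k in seq_along(stages)) {
      s <- stages[k]
      net <- nets[[s]]
      if (nrow(net$nodes) < 3) next
      w <- wmis(net)
      vuln <- vulnerability(net)
      hubs <- res$topology[[s]]$hub_node_ids
      if (length(hubs) < 2) {
        # robustness contrast needs a hub set; fall back to the top degree
        # decile when the Zi-Pi classification yields fewer than two hubs
        deg <- res$topology[[s]]$node_roles
        hubs <- deg$node[order(-deg$degree)][
          seq_len(max(2, ceiling(nrow(deg) / 10)))]
      }
      rob <- robustness_simulation(net, hub_ids = hubs,
                                   n_reps = config$robustness_reps,
                                   seed = make_seed(seed, 6000 + k))
      resil[[s]] <- list(
        wmis = w,
        core_nodes = intersect(core, net$nodes$taxon),
        stability = stability_index(net, core = intersect(core,
                                                          net$nodes$taxon)),
        efficiency = global_efficiency(net),
        vulnerability = vuln$network_vulnerability,
        node_vulnerability = vuln$node_vulnerability,
        robustness = rob)
    }
    res$core_nodes <- core
    res$resilience <- resil
    report <- lapply(resil, function(x) list(
      stability = x$stability, efficiency = x$efficiency,
      vulnerability = x$vulnerability,
      tr_ratios = x$robustness$tr_ratios,
      ra_ratios = x$robustness$ra_ratios,
      robustness_p = x$robustness$p_value))
    jsonlite::write_json(report, file.path(out_dir, "resilience.json"),
                         auto_unbox = TRUE, digits = NA)
  }, done)

  # -- 7: guilds --------------------------------------------------------
  run_stage("guilds", {
    s <- config$phenotype_stage
    filt <- prevalence_filter(res$counts[[s]], config$min_prevalence)
    assoc <- associate_features(filt, res$phenotype[colnames(filt)],
                                q_cutoff = config$association_fdr)
    sig <- assoc$feature[assoc$significant]
    if (length(sig) < 4) stop("fewer than 4 phenotype-associated features")
    sub <- filt[sig, , drop = FALSE]
    fit <- sparcc(sub, exclusion_threshold = config$exclusion_threshold,
                  max_exclusions = config$max_exclusions,
                  n_inner = config$n_inner,
                  seed = make_seed(seed, 5000))
    pmat <- permutation_pvalues(sub, fit$r,
                                n_permutations = config$n_permutations,
                                seed = make_seed(seed, 5100),
                                exclusion_threshold =
                                  config$exclusion_threshold,
                                max_exclusions = config$max_exclusions)
    gnet <- build_network(fit$r, pmat, pmat,
                          q_cutoff = config$guild_edge_p,
                          stage = s, n_samples = ncol(sub))
    part <- detect_guilds(gnet, association = assoc)
    violations <- check_guild_partition(part, gnet)
    gab <- guild_abundance(res$counts[[s]], part)
    # extreme-phenotype groups: top vs bottom quartile of the phenotype
    ph <- res$phenotype[gab$sample]
    qs <- stats::quantile(ph, c(0.25, 0.75))
    grp <- ifelse(ph <= qs[1], "low", ifelse(ph >= qs[2], "high", NA))
    sel <- !is.na(grp)
    cmp <- list(
      guild1 = compare_groups(gab$guild1[sel], grp[sel]),
      guild2 = compare_groups(gab$guild2[sel], grp[sel]))
    res$association <- assoc
    res$guild_network <- gnet
    res$guilds <- part
    res$guild_violations <- violations
    res$guild_abundance <- gab
    res$group_comparison <- cmp
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    membership <- data.frame(
      feature = c(part$guild1, part$guild2, part$unassigned),
      guild = c(rep("guild1", length(part$guild1)),
                rep("guild2", length(part$guild2)),
                rep("unassigned", length(part$unassigned))))
    utils::write.table(membership,
                       file.path(out_dir, "guild_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, done)

  # -- 8: metabolic scoring ---------------------------------------------
  run_stage("metabolic", {
    part <- res$guilds
    taxa <- rownames(res$counts[[config$phenotype_stage]])
    idx1 <- match(part$guild1, taxa); idx2 <- match(part$guild2, taxa)
    if (length(idx1) + length(idx2) < 4 || length(idx1) == 0 ||
        length(idx2) == 0) {
      stop("metabolic scoring needs members in both guilds (>= 4 total)")
    }
    mg_spec <- planted_guild_spec(idx1, idx2)
    fix <- generate_metabolic_fixtures(mg_spec, seed = seed, taxa = taxa)
    scores <- score_metabolic_pairs(part, fix$mro, fix$mip)
    bt <- scores$pair_class == "between"
    pd <- fix$phylo_dist[cbind(match(scores$a, fix$strains),
                               match(scores$b, fix$strains))]
    outl <- if (sum(bt) >= 10) {
      phylo_outliers(scores$mip[bt], pd[bt], z_cutoff = config$outlier_z)
    } else NULL
    guild_of <- ifelse(fix$strains %in% part$guild1, "guild1", "guild2")
    pathways <- core_cloud_pathways(fix$pathways, guild_of,
                                    core_cut = config$core_prevalence,
                                    cloud_cut = config$cloud_prevalence)
    comp_pairs <- scores[scores$competitive, c("a", "b")]
    demand <- shared_demand_ranking(fix$uptake, comp_pairs, top_k = 30)
    res$metabolic <- list(fixtures = fix, scores = scores,
                           outliers = outl, pathway_classes = pathways,
                           shared_demand = demand)
    utils::write.table(scores, file.path(out_dir, "metabolic_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(demand, file.path(out_dir, "shared_demand.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }, done)

  # -- manifest ---------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    stages_complete = done,
    config = unclass(config),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("coabnet")),
    files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# evaluate a pipeline stage, halting with the stage name on failure;
# `done` is grown by reference in the caller
run_stage <- function(name, expr, done) {
  caller <- parent.frame()
  ok <- tryCatch({
    eval(substitute(expr), envir = caller)
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  assign("done", c(get("done", envir = caller), name), envir = caller)
  invisible(ok)
}
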