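#' Specify a planted multi-stage correlation structure
#'
#' Declares the latent taxon-taxon correlation structure used by the synthetic
#' data generator: a set of conserved edges (same correlation at every stage),
#' a set of variable edges (stage-specific correlations, sign flips allowed),
#' and a background correlation for all unlisted pairs.
#'
#' @param n_taxa Number of taxa (positive integer).
#' @param stages Character vector of ordered stage labels (e.g. developmental
#'   ages).
#' @param conserved_edges `data.frame` with columns `i`, `j` (taxon indices)
#'   and `rho` (shared latent correlation in (-1, 1)); may be empty.
#' @param variable_edges `data.frame` with columns `i`, `j` and one column
#'   `rho_<stage>` per stage; may be empty.
#' @param background_rho Latent correlation of every unlisted pair (default 0).
#' @param beneficial Logical vector of length `n_taxa` flagging beneficial
#'   taxa (default all `FALSE`).
#' @return An object of class `planted_network_spec`.
#' @seealso [generate_stage_correlations()], [generate_counts()]
#' @export
planted_network_spec <- function(n_taxa, stages,
                                 conserved_edges = NULL,
                                 variable_edges = NULL,
                                 background_rho = 0,
                                 beneficial = NULL) {
  stopifnot(is.numeric(n_taxa), n_taxa >= 2,
            is.character(stages), length(stages) >= 1,
            !anyDuplicated(stages),
            is.numeric(background_rho), abs(background_rho) < 1)
  n_taxa <- as.integer(n_taxa)
  if (is.null(beneficial)) beneficial <- rep(FALSE, n_taxa)
  stopifnot(is.logical(beneficial), length(beneficial) == n_taxa)

  empty_edges <- data.frame(i = integer(), j = integer())
  if (is.null(conserved_edges)) {
    conserved_edges <- cbind(empty_edges, rho = numeric())
  }
  rho_cols <- paste0("rho_", stages)
  if (is.null(variable_edges)) {
    variable_edges <- empty_edges
    for (cl in rho_cols) variable_edges[[cl]] <- numeric()
  }
  check_pairs <- function(df, what) {
    stopifnot(all(c("i", "j") %in% names(df)))
    if (nrow(df) == 0) return(invisible())
    if (!all(df$i >= 1 & df$i <= n_taxa & df$j >= 1 & df$j <= n_taxa)) {
      stop(what, ": taxon index out of range 1..", n_taxa)
    }
    if (any(df$i == df$j)) stop(what, ": self-pairs are not allowed")
  }
  check_pairs(conserved_edges, "conserved_edges")
  check_pairs(variable_edges, "variable_edges")
  if (nrow(conserved_edges) > 0 && any(abs(conserved_edges$rho) >= 1)) {
    stop("conserved_edges: rho must lie in (-1, 1)")
  }
  if (!all(rho_cols %in% names(variable_edges))) {
    stop("variable_edges must carry one rho_<stage> column per stage: ",
         paste(rho_cols, collapse = ", "))
  }
  if (nrow(variable_edges) > 0 &&
      any(abs(as.matrix(variable_edges[rho_cols])) >= 1)) {
    stop("variable_edges: rho must lie in (-1, 1)")
  }
  keys <- c(edge_key(conserved_edges$i, conserved_edges$j),
            edge_key(variable_edges$i, variable_edges$j))
  if (anyDuplicated(keys)) {
    stop("a taxon pair is listed twice: ", keys[duplicated(keys)][1])
  }
  structure(list(n_taxa = n_taxa, stages = stages,
                 conserved_edges = conserved_edges,
                 variable_edges = variable_edges,
                 background_rho = background_rho,
                 beneficial = beneficial),
            class = "planted_network_spec")
}

# eigenvalue-clipping nearest-PD repair, re-normalized to unit diagonal
nearest_pd <- function(mat, eps = 1e-6) {
  es <- eigen(mat, symmetric = TRUE)
  if (min(es$values) >= eps) return(mat)
  vals <- pmax(es$values, eps)
  rep_mat <- es$vectors %*% (vals * t(es$vectors))
  rep_mat <- stats::cov2cor(rep_mat)
  (rep_mat + t(rep_mat)) / 2
}

#' Build per-stage latent correlation matrices from a planted spec
#'
#' Assembles, for every stage, the latent correlation matrix implied by the
#' spec. Matrices that are not positive definite are repaired by clipping
#' eigenvalues at 1e-6 and re-normalizing to unit diagonal; if the repair
#' moves any planted entry by more than `tol` the spec is rejected.
#'
#' @param spec A [planted_network_spec()].
#' @param tol Maximum tolerated deviation of a planted entry after PD repair
#'   (default 0.02).
#' @return A list with `correlations` (named list of stage matrices) and
#'   `truth` (a `synthetic_truth` object recording planted edges, their
#'   per-stage correlations and a stable/variable label).
#' @export
generate_stage_correlations <- function(spec, tol = 0.02) {
  stopifnot(inherits(spec, "planted_network_spec"))
  p <- spec$n_taxa
  taxa <- sprintf("t%03d", seq_len(p))
  mats <- list()
  repaired <- character()
  for (k in seq_along(spec$stages)) {
    stage <- spec$stages[k]
    sigma <- matrix(spec$background_rho, p, p)
    diag(sigma) <- 1
    ce <- spec$conserved_edges
    if (nrow(ce) > 0) {
      sigma[cbind(ce$i, ce$j)] <- ce$rho
      sigma[cbind(ce$j, ce$i)] <- ce$rho
    }
    ve <- spec$variable_edges
    if (nrow(ve) > 0) {
      rho_k <- ve[[paste0("rho_", stage)]]
      sigma[cbind(ve$i, ve$j)] <- rho_k
      sigma[cbind(ve$j, ve$i)] <- rho_k
    }
    target <- sigma
    sigma <- nearest_pd(sigma)
    if (!isTRUE(all.equal(sigma, target, tolerance = 1e-12))) {
      repaired <- c(repaired, stage)
      planted_idx <- rbind(as.matrix(ce[c("i", "j")]),
                          as.matrix(ve[c("i", "j")]))
      if (nrow(planted_idx) > 0) {
        dev <- max(abs(sigma[planted_idx] - target[planted_idx]))
        if (dev > tol) {
          stop("stage ", stage, ": correlation spec not repairable; ",
               "nearest-PD projection moves a planted entry by ",
               signif(dev, 3), " (> ", tol, ")")
        }
      }
    }
    dimnames(sigma) <- list(taxa, taxa)
    mats[[stage]] <- sigma
  }
  labels <- rbind(
    if (nrow(spec$conserved_edges) > 0)
      data.frame(i = spec$conserved_edges$i, j = spec$conserved_edges$j,
                 label = "stable") else NULL,
    if (nrow(spec$variable_edges) > 0)
      data.frame(i = spec$variable_edges$i, j = spec$variable_edges$j,
                 label = "variable") else NULL)
  if (is.null(labels)) labels <- data.frame(i = integer(), j = integer(),
                                            label = character())
  if (nrow(labels) > 0) {
    labels$from <- taxa[pmin(labels$i, labels$j)]
    labels$to <- taxa[pmax(labels$i, labels$j)]
    for (stage in spec$stages) {
      labels[[paste0("rho_", stage)]] <- mats[[stage]][cbind(labels$i, labels$j)]
    }
  } else {
    labels$from <- character(); labels$to <- character()
    for (stage in spec$stages) labels[[paste0("rho_", stage)]] <- numeric()
  }
  truth <- structure(list(taxa = taxa, stages = spec$stages,
                          edges = labels, beneficial = spec$beneficial,
                          repaired_stages = repaired),
                     class = "synthetic_truth")
  list(correlations = mats, truth = truth)
}

#' Serialize / restore planted ground truth
#'
#' `truth_to_json()` writes a `synthetic_truth` object to JSON;
#' `truth_from_json()` restores it. The round trip is exact.
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output / input file path.
#' @return `truth_from_json()` returns the restored `synthetic_truth`.
#' @export
truth_to_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname truth_to_json
#' @export
truth_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(raw$edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    edges$i <- as.integer(edges$i); edges$j <- as.integer(edges$j)
  }
  structure(list(taxa = as.character(raw$taxa),
                 stages = as.character(raw$stages),
                 edges = edges,
                 beneficial = as.logical(raw$beneficial),
                 repaired_stages = as.character(raw$repaired_stages)),
            class = "synthetic_truth")
}

#' Simulate compositional count tables from latent correlations
#'
#' Logistic-normal-multinomial sampler: per sample, latent log-abundances are
#' drawn from a multivariate normal with the stage correlation matrix (scaled
#' by `latent_sd`), passed through a softmax to relative abundances, and
#' sequencing counts are drawn multinomially at fixed `depth`. This is the
#' regime SparCC's assumptions target, so planted correlations are recoverable
#' by the inference module.
#'
#' @param correlations A single correlation matrix or a named list of stage
#'   matrices as returned by [generate_stage_correlations()].
#' @param n_samples Samples per stage (>= 10).
#' @param depth Total counts per sample (>= 1000).
#' @param seed Master seed; stage `k` uses `make_seed(seed, 200 + k)`.
#' @param base_log_mean Optional per-taxon latent log-mean. Default is a
#'   geometric rank-abundance gradient spanning a 50-fold range, so the table
#'   has dominant and rare taxa like a real community.
#' @param latent_sd Per-taxon latent log-scale standard deviation (scalar or
#'   vector; default 1.3, bloom-like variability of gut taxa).
#' @return A counts matrix (taxa x samples), or a named list of one matrix per
#'   stage when `correlations` is a list.
#' @export
generate_counts <- function(correlations, n_samples, depth = 50000, seed = 1,
                            base_log_mean = NULL, latent_sd = 1.3) {
  if (is.list(correlations)) {
    out <- vector("list", length(correlations))
    names(out) <- names(correlations)
    for (k in seq_along(correlations)) {
      out[[k]] <- generate_counts_one(correlations[[k]], n_samples, depth,
                                      make_seed(seed, 200 + k),
                                      base_log_mean, latent_sd,
                                      stage = names(correlations)[k])
    }
    return(out)
  }
  generate_counts_one(correlations, n_samples, depth, make_seed(seed, 201),
                      base_log_mean, latent_sd, stage = "s1")
}

generate_counts_one <- function(sigma, n_samples, depth, seed,
                                base_log_mean, latent_sd, stage) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma),
            n_samples >= 10, depth >= 1000)
  p <- nrow(sigma)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  if (is.null(base_log_mean)) {
    base_log_mean <- seq(log(50), log(1), length.out = p)
  }
  stopifnot(length(base_log_mean) == p)
  sd_vec <- rep_len(latent_sd, p)
  cov_mat <- sigma * tcrossprod(sd_vec)
  set.seed(seed)
  z <- MASS::mvrnorm(n_samples, mu = base_log_mean, Sigma = cov_mat)
  w <- exp(z - apply(z, 1, max))
  fr <- w / rowSums(w)
  counts <- apply(fr, 1, function(pr) stats::rmultinom(1, depth, pr))
  taxa <- rownames(sigma)
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(p))
  dimnames(counts) <- list(taxa,
                           sprintf("%s_s%03d", stage, seq_len(n_samples)))
  counts
}

#' Specify a planted two-guild structure
#'
#' Two disjoint taxon sets with positive within-guild and negative
#' between-guild latent correlations, jointly driving a continuous host
#' phenotype (growth-rate-like) through the difference of their summed
#' relative abundances.
#'
#' @param guild1,guild2 Disjoint integer vectors of taxon indices.
#' @param within_rho Positive within-guild latent correlation (default 0.6).
#' @param between_rho Negative between-guild latent correlation (default
#'   -0.5).
#' @param effect_size Slope mapping (guild1 - guild2) summed relative
#'   abundance to the phenotype (default 5).
#' @param noise_sd Phenotype noise standard deviation (default 1).
#' @return An object of class `planted_guild_spec`.
#' @export
planted_guild_spec <- function(guild1, guild2, within_rho = 0.6,
                               between_rho = -0.5, effect_size = 5,
                               noise_sd = 1) {
  stopifnot(length(guild1) > 0, length(guild2) > 0,
            length(intersect(guild1, guild2)) == 0,
            within_rho > 0, between_rho < 0, noise_sd >= 0)
  structure(list(guild1 = as.integer(guild1), guild2 = as.integer(guild2),
                 within_rho = within_rho, between_rho = between_rho,
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "planted_guild_spec")
}

#' Generate a phenotype from planted guild abundances
#'
#' `phenotype = effect_size * (sum guild1 relative abundance - sum guild2
#' relative abundance) + Normal(0, noise_sd)`.
#'
#' @param counts Counts or relative-abundance matrix (taxa x samples).
#' @param guild_spec A [planted_guild_spec()].
#' @param seed Seed for the noise draw.
#' @return Named numeric vector of per-sample phenotype values.
#' @export
generate_phenotype <- function(counts, guild_spec, seed = 1) {
  stopifnot(inherits(guild_spec, "planted_guild_spec"))
  p <- nrow(counts)
  if (max(guild_spec$guild1, guild_spec$guild2) > p) {
    stop("guild member index exceeds number of taxa in the table")
  }
  rel <- sweep(counts, 2, colSums(counts), "/")
  diff <- colSums(rel[guild_spec$guild1, , drop = FALSE]) -
    colSums(rel[guild_spec$guild2, , drop = FALSE])
  set.seed(make_seed(seed, 300))
  y <- guild_spec$effect_size * diff +
    stats::rnorm(ncol(counts), 0, guild_spec$noise_sd)
  names(y) <- colnames(counts)
  y
}

#' Generate synthetic metabolic-model score fixtures
#'
#' Emulates the pairwise outputs of genome-scale metabolic model comparison
#' for the guild members: a phylogeny (random tree), a phylogenetically
#' structured binary pathway-presence matrix, a metabolic resource overlap
#' (MRO, competition) matrix computed from pathway overlap, a metabolic
#' interaction potential (MIP, complementarity) matrix increasing with
#' phylogenetic distance, and per-strain uptake/secretion metabolite sets.
#' Because pathway sharing decays with phylogenetic distance while MIP grows
#' with it, MRO and MIP are anti-correlated by construction, mirroring the
#' empirical behaviour of competition and complementarity indices.
#'
#' @param guild_spec A [planted_guild_spec()] naming the strains (taxon
#'   indices); at least 4 strains in total.
#' @param n_pathways Number of metabolic pathways (>= 20).
#' @param seed Master seed.
#' @param n_metabolites Size of the metabolite pool backing uptake/secretion
#'   sets (default 80).
#' @param taxa Optional character vector of taxon ids indexed by the guild
#'   spec (default `t%03d`).
#' @return List with elements `strains`, `guild` (1/2 per strain), `mro`,
#'   `mip`, `phylo_dist` (all symmetric strain x strain matrices in `[0,1]`),
#'   `pathways` (binary strains x pathways), `uptake` and `secretion` (named
#'   lists of metabolite character vectors).
#' @export
generate_metabolic_fixtures <- function(guild_spec, n_pathways = 60, seed = 1,
                                        n_metabolites = 80, taxa = NULL) {
  stopifnot(inherits(guild_spec, "planted_guild_spec"), n_pathways >= 20)
  members <- c(guild_spec$guild1, guild_spec$guild2)
  n <- length(members)
  if (n < 4) stop("metabolic fixtures need at least 4 strains")
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(max(members)))
  strains <- taxa[members]
  guild <- rep(c(1L, 2L), c(length(guild_spec$guild1),
                            length(guild_spec$guild2)))
  names(guild) <- strains

  set.seed(make_seed(seed, 400))
  tree <- ape::rtree(n, tip.label = strains)
  d <- ape::cophenetic.phylo(tree)[strains, strains]
  d <- d / max(d)

  # phylogenetically structured pathways: each pathway occupies the ball of
  # strains around a focal strain; 5 universal housekeeping pathways anchor
  # every strain with a non-empty repertoire
  path_names <- sprintf("pwy%03d", seq_len(n_pathways))
  presence <- matrix(0L, n, n_pathways, dimnames = list(strains, path_names))
  presence[, 1:5] <- 1L
  for (k in 6:n_pathways) {
    focal <- sample.int(n, 1)
    radius <- stats::runif(1, 0.15, 0.9)
    presence[d[focal, ] <= radius, k] <- 1L
  }

  # MRO: pairwise pathway overlap coefficient |Pi n Pj| / min(|Pi|, |Pj|);
  # identical repertoires give exactly 1
  sizes <- rowSums(presence)
  inter <- tcrossprod(presence)
  mro <- inter / outer(sizes, sizes, pmin)
  diag(mro) <- 1

  # MIP grows with phylogenetic distance (+ small noise), clipped to [0, 1]
  noise <- matrix(stats::rnorm(n * n, 0, 0.05), n)
  noise <- (noise + t(noise)) / 2
  mip <- pmin(pmax(0.15 + 0.6 * d + noise, 0), 1)
  diag(mip) <- 0
  dimnames(mip) <- dimnames(d)

  # uptake sets derive from pathway repertoires via a fixed pathway ->
  # metabolite map; first 5 metabolites are universally required
  met_names <- sprintf("m%03d", seq_len(n_metabolites))
  pw_met <- lapply(seq_len(n_pathways), function(k) {
    met_names[sample.int(n_metabolites, 2)]
  })
  uptake <- lapply(strains, function(s) {
    sort(unique(c(met_names[1:5],
                  unlist(pw_met[presence[s, ] == 1L]))))
  })
  names(uptake) <- strains
  secretion <- lapply(strains, function(s) {
    sort(sample(met_names, 8))
  })
  names(secretion) <- strains

  list(strains = strains, guild = guild, mro = mro, mip = mip,
       phylo_dist = d, pathways = presence, uptake = uptake,
       secretion = secretion)
}
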