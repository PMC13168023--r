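#' Combined metabolic distance from competition and complementarity
#'
#' `D = 1 - (MRO - MIP)`: pairs with high resource overlap and no
#' complementarity sit near 0 (maximal competition), pairs with identical
#' indices at 1, and purely complementary pairs approach 2.
#'
#' @param mro,mip Competition (resource overlap) and complementarity
#'   (interaction potential) indices, vectors or matrices with entries in
#'   `[0, 1]`.
#' @return `1 - (mro - mip)`, same shape as the inputs.
#' @export
metabolic_distance <- function(mro, mip) {
  if (any(mro < 0 | mro > 1, na.rm = TRUE) ||
      any(mip < 0 | mip > 1, na.rm = TRUE)) {
    stop("MRO and MIP must lie in [0, 1]")
  }
  1 - (mro - mip)
}

#' Composite competition intensity
#'
#' Z-standardizes MRO and MIP over the pair set under analysis and returns
#' `C = Z(MRO) - Z(MIP)`. Because the two indices are anti-correlated, C
#' separates strongly competitive pairs (high overlap, low complementarity)
#' from cooperative ones.
#'
#' @param mro_values,mip_values Numeric vectors over the same pairs
#'   (>= 3 pairs, both with positive variance).
#' @return Numeric vector of competition intensities (mean 0 over the set).
#' @export
competition_intensity <- function(mro_values, mip_values) {
  stopifnot(length(mro_values) == length(mip_values),
            length(mro_values) >= 3)
  if (stats::sd(mro_values) == 0 || stats::sd(mip_values) == 0) {
    stop("zero variance in MRO or MIP; Z-scores undefined")
  }
  as.numeric(scale(mro_values)) - as.numeric(scale(mip_values))
}

#' Flag the upper quartile of competition intensities as competitive
#'
#' Pairs ranked in the top `ceiling(N / 4)` by C are flagged competitive.
#' Ties are broken by pair id order, so exactly `ceiling(N / 4)` pairs are
#' flagged regardless of ties.
#'
#' @param c_values Competition intensities.
#' @param pair_ids Optional pair identifiers used for deterministic tie
#'   breaking (default: input order).
#' @return Logical vector of competitive flags.
#' @export
classify_competitive <- function(c_values, pair_ids = NULL) {
  n <- length(c_values)
  stopifnot(n >= 1)
  if (is.null(pair_ids)) pair_ids <- seq_len(n)
  k <- ceiling(n / 4)
  ord <- order(-c_values, pair_ids)
  flags <- rep(FALSE, n)
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Phylogeny-adjusted complementarity outliers
#'
#' Ordinary least-squares regression of MIP on phylogenetic distance;
#' residuals are standardized by their SD and pairs with a standardized
#' residual above `z_cutoff` (complementarity markedly elevated relative to
#' phylogenetic expectation) are flagged.
#'
#' @param mip_values,phylo_distances Equal-length numeric vectors over
#'   strain pairs (>= 10 pairs).
#' @param z_cutoff Positive standardized-residual threshold (default 2.698).
#' @return List with `outliers` (indices), `residual_z` and the fitted
#'   `slope`/`intercept`.
#' @export
phylo_outliers <- function(mip_values, phylo_distances, z_cutoff = 2.698) {
  stopifnot(length(mip_values) == length(phylo_distances), z_cutoff > 0)
  if (length(mip_values) < 10) {
    stop("need at least 10 pairs for a stable regression")
  }
  fit <- stats::lm(mip_values ~ phylo_distances)
  rs <- stats::resid(fit)
  s <- stats::sd(rs)
  # an (essentially) exact linear fit has no outliers
  z <- if (s < 1e-12 * max(1, max(abs(mip_values)))) rep(0, length(rs))
    else rs / s
  list(outliers = which(z > z_cutoff), residual_z = unname(z),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Classify pathways as core, shell, or cloud per guild
#'
#' Per guild, a pathway is `core` when present in at least 90% of the
#' guild's genomes, `cloud` when present in a single genome or in at most
#' 10% of them, and `shell` otherwise. Only pathways present in at least
#' one genome of the guild are classified; the summary attribute reports
#' core/cloud proportions among those.
#'
#' @param pathway_presence Binary genomes x pathways matrix.
#' @param guild_labels Guild assignment per genome (any number of guilds).
#' @param core_cut,cloud_cut Prevalence thresholds (defaults 0.90, 0.10).
#' @return data.frame with `pathway`, `guild`, `n_carriers`, `prevalence`,
#'   `class`; attribute `summary` holds per-guild core/cloud percentages.
#' @export
core_cloud_pathways <- function(pathway_presence, guild_labels,
                                core_cut = 0.90, cloud_cut = 0.10) {
  m <- as.matrix(pathway_presence)
  stopifnot(all(m %in% c(0, 1)), nrow(m) == length(guild_labels))
  guilds <- unique(guild_labels)
  out <- NULL
  summ <- NULL
  for (g in guilds) {
    sub <- m[guild_labels == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty guild: ", g)
    carriers <- colSums(sub)
    prev <- carriers / nrow(sub)
    present <- carriers >= 1
    cls <- ifelse(prev >= core_cut, "core",
           ifelse(carriers == 1 | prev <= cloud_cut, "cloud", "shell"))
    df <- data.frame(pathway = colnames(sub)[present], guild = g,
                     n_carriers = carriers[present],
                     prevalence = prev[present], class = cls[present],
                     stringsAsFactors = FALSE, row.names = NULL)
    out <- rbind(out, df)
    summ <- rbind(summ, data.frame(
      guild = g, n_pathways = sum(present),
      pct_core = fraction_pct(sum(df$class == "core"), sum(present)),
      pct_cloud = fraction_pct(sum(df$class == "cloud"), sum(present)),
      stringsAsFactors = FALSE))
  }
  attr(out, "summary") <- summ
  out
}

#' Enumerate strain pairs by guild class
#'
#' All unordered strain pairs of a guild partition labeled
#' `within_guild1`, `within_guild2`, or `between`.
#'
#' @param partition A `guild_partition` (or list with `guild1`, `guild2`).
#' @return data.frame with `a`, `b`, `pair_class`.
#' @export
guild_pairs <- function(partition) {
  g1 <- partition$guild1; g2 <- partition$guild2
  pair_df <- function(members) {
    if (length(members) < 2) {
      return(data.frame(a = character(0), b = character(0)))
    }
    idx <- utils::combn(sort(members), 2)
    data.frame(a = idx[1, ], b = idx[2, ], stringsAsFactors = FALSE)
  }
  w1 <- pair_df(g1); w2 <- pair_df(g2)
  bt <- expand.grid(a = sort(g1), b = sort(g2), stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  out <- rbind(
    if (nrow(w1)) cbind(w1, pair_class = "within_guild1") else NULL,
    if (nrow(w2)) cbind(w2, pair_class = "within_guild2") else NULL,
    if (nrow(bt)) cbind(bt, pair_class = "between") else NULL)
  rownames(out) <- NULL
  out
}

#' Score all strain pairs of a guild partition
#'
#' Extracts per-pair MRO/MIP from symmetric matrices, computes the combined
#' metabolic distance for every pair, the competition intensity
#' (Z-standardized over the between-guild pair set, the set on which
#' competitive pairs are defined; a global standardization over all pairs
#' is also reported), and flags the upper quartile of between-guild pairs
#' as competitive.
#'
#' @param partition A `guild_partition`.
#' @param mro,mip Symmetric strain x strain index matrices.
#' @return data.frame with `a`, `b`, `pair_class`, `mro`, `mip`,
#'   `distance`, `c_between` (NA for within pairs), `c_global`,
#'   `competitive`.
#' @export
score_metabolic_pairs <- function(partition, mro, mip) {
  pairs <- guild_pairs(partition)
  strains <- rownames(mro)
  stopifnot(all(c(pairs$a, pairs$b) %in% strains),
            all(dim(mro) == dim(mip)))
  idx <- cbind(match(pairs$a, strains), match(pairs$b, strains))
  pairs$mro <- mro[idx]
  pairs$mip <- mip[idx]
  pairs$distance <- metabolic_distance(pairs$mro, pairs$mip)
  pairs$c_global <- competition_intensity(pairs$mro, pairs$mip)
  pairs$c_between <- NA_real_
  bt <- pairs$pair_class == "between"
  pairs$competitive <- FALSE
  if (sum(bt) >= 3) {
    pairs$c_between[bt] <- competition_intensity(pairs$mro[bt],
                                                 pairs$mip[bt])
    pairs$competitive[bt] <- classify_competitive(
      pairs$c_between[bt], paste(pairs$a[bt], pairs$b[bt]))
  }
  pairs
}

#' Rank metabolites by shared demand among competitive pairs
#'
#' For each competitive pair the shared demand is the intersection of the
#' two strains' uptake sets; each metabolite scores the number of
#' competitive pairs whose shared demand contains it. The top `top_k`
#' metabolites are returned (ties broken alphabetically).
#'
#' @param uptake_sets Named list of per-strain uptake metabolite vectors.
#' @param competitive_pairs data.frame with columns `a`, `b`.
#' @param top_k Number of metabolites to return (default 30).
#' @return data.frame with `metabolite` and `n_pairs`, sorted by rank.
#' @export
shared_demand_ranking <- function(uptake_sets, competitive_pairs,
                                  top_k = 30) {
  stopifnot(all(c("a", "b") %in% names(competitive_pairs)))
  counts <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(competitive_pairs))) {
    a <- competitive_pairs$a[e]; b <- competitive_pairs$b[e]
    shared <- intersect(uptake_sets[[a]], uptake_sets[[b]])
    for (met in shared) {
      counts[[met]] <- (if (is.null(counts[[met]])) 0L else counts[[met]]) + 1L
    }
  }
  mets <- ls(counts)
  if (length(mets) == 0) {
    return(data.frame(metabolite = character(0), n_pairs = integer(0)))
  }
  df <- data.frame(metabolite = mets,
                   n_pairs = vapply(mets, function(m) counts[[m]],
                                    integer(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$n_pairs, df$metabolite), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
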