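#' Linear-model association scan of features against a phenotype
#'
#' Per-feature fixed-effects linear model of transformed abundance on a
#' continuous phenotype (plus optional covariates), in the style of standard
#' microbiome association scans: abundances are total-sum scaled, zeros are
#' replaced by half the feature's smallest nonzero value, log2-transformed,
#' and each feature is regressed on the phenotype. P-values are BH-adjusted
#' across features.
#'
#' @param abundances Counts or relative abundances, features x samples
#'   (>= 20 samples).
#' @param phenotype Numeric per-sample phenotype (continuous).
#' @param covariates Optional data.frame of per-sample covariates.
#' @param q_cutoff Significance threshold on the adjusted p (default 0.2).
#' @param min_prevalence Features must be nonzero in at least this fraction
#'   of samples (default 0.1).
#' @return data.frame with `feature`, `coef`, `se`, `t`, `p`, `q`,
#'   `direction` (`positive`/`negative`), `significant`. Constant features
#'   are skipped with a message.
#' @export
associate_features <- function(abundances, phenotype, covariates = NULL,
                               q_cutoff = 0.2, min_prevalence = 0.1) {
  stopifnot(is.matrix(abundances), ncol(abundances) >= 20,
            length(phenotype) == ncol(abundances),
            is.numeric(phenotype))
  ab <- prevalence_filter(abundances, min_prevalence)
  rel <- sweep(ab, 2, colSums(abundances), "/")
  logged <- t(apply(rel, 1, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) return(rep(NA_real_, length(x)))
    x[x == 0] <- min(nz) / 2
    log2(x)
  }))
  keep <- apply(logged, 1, function(x) !anyNA(x) && stats::sd(x) > 0)
  if (any(!keep)) {
    message(sum(!keep), " constant feature(s) skipped")
    logged <- logged[keep, , drop = FALSE]
  }
  if (is.null(covariates)) {
    x_mat <- cbind(`(Intercept)` = 1, phenotype = phenotype)
  } else {
    x_mat <- stats::model.matrix(~., data = cbind(phenotype = phenotype,
                                                  covariates))
  }
  qr_x <- qr(x_mat)
  rank <- qr_x$rank
  n <- ncol(logged)
  y_t <- t(logged)                              # samples x features
  coefs <- qr.coef(qr_x, y_t)                   # predictors x features
  fitted <- x_mat %*% coefs
  resid <- y_t - fitted
  dfree <- n - rank
  sigma2 <- colSums(resid^2) / dfree
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match("phenotype", colnames(x_mat))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- coefs[j, ]
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), dfree, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = rownames(logged), coef = unname(beta),
                    se = unname(se), t = unname(t_stat), p = unname(p),
                    q = unname(q),
                    direction = ifelse(beta >= 0, "positive", "negative"),
                    significant = q < q_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}

#' Detect two antagonistic guilds from a signed co-abundance graph
#'
#' Connected components of the positive-edge subgraph are contracted into
#' supernodes; the supernode graph induced by the negative edges is
#' two-colored by breadth-first traversal. The two colors define the guilds
#' (members of one guild are connected exclusively by positive edges,
#' members of opposite guilds only by negative ones, up to reported
#' frustrated edges). Supernodes untouched by any negative edge are left
#' unassigned. Guild 1 is the side with more positively phenotype-associated
#' members when `association` is supplied, otherwise the side containing the
#' lexicographically smallest node.
#'
#' @param net A `coab_network` of significant features whose edges carry
#'   signed correlations (the p < 0.05 filter is assumed already applied).
#' @param association Optional result of [associate_features()] used to
#'   orient the guild labels.
#' @return A `guild_partition`: list with `guild1`, `guild2`, `unassigned`
#'   (character vectors), `frustrated` (data.frame of sign-violating edges
#'   with a reason) and `n_components`.
#' @export
detect_guilds <- function(net, association = NULL) {
  stopifnot(inherits(net, "coab_network"))
  nodes <- net$nodes$taxon
  edges <- net$edges
  pos <- edges[edges$r > 0, , drop = FALSE]
  neg <- edges[edges$r < 0, , drop = FALSE]
  g_pos <- igraph::graph_from_data_frame(pos[c("from", "to")],
                                         directed = FALSE,
                                         vertices = data.frame(name = nodes))
  comp <- igraph::components(g_pos)$membership[nodes]
  frustrated <- edges[0, ]
  frustrated$reason <- character(0)
  # negative edge inside a positive component violates the guild pattern
  if (nrow(neg) > 0) {
    internal <- comp[neg$from] == comp[neg$to]
    if (any(internal)) {
      fr <- neg[internal, , drop = FALSE]
      fr$reason <- "negative_edge_within_positive_component"
      frustrated <- rbind(frustrated, fr)
      neg <- neg[!internal, , drop = FALSE]
    }
  }
  n_comp <- max(comp)
  color <- rep(NA_integer_, n_comp)
  if (nrow(neg) == 0) {
    message("no negative edges: returning a single guild")
    members <- sort(nodes)
    part <- structure(list(guild1 = members, guild2 = character(0),
                           unassigned = character(0),
                           frustrated = frustrated,
                           n_components = n_comp),
                      class = "guild_partition")
    return(part)
  }
  # supernode adjacency over negative edges
  sn_a <- comp[neg$from]; sn_b <- comp[neg$to]
  adj <- vector("list", n_comp)
  for (e in seq_len(nrow(neg))) {
    adj[[sn_a[e]]] <- c(adj[[sn_a[e]]], sn_b[e])
    adj[[sn_b[e]]] <- c(adj[[sn_b[e]]], sn_a[e])
  }
  touched <- sort(unique(c(sn_a, sn_b)))
  conflict_pairs <- matrix(integer(0), ncol = 2)
  for (start in touched) {
    if (!is.na(color[start])) next
    color[start] <- 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in unique(adj[[v]])) {
        if (is.na(color[u])) {
          color[u] <- 3L - color[v]
          queue <- c(queue, u)
        } else if (color[u] == color[v]) {
          conflict_pairs <- rbind(conflict_pairs, c(v, u))
        }
      }
    }
  }
  if (nrow(conflict_pairs) > 0) {
    ea <- comp[neg$from]; eb <- comp[neg$to]
    bad <- rep(FALSE, nrow(neg))
    for (cp in seq_len(nrow(conflict_pairs))) {
      v <- conflict_pairs[cp, 1]; u <- conflict_pairs[cp, 2]
      bad <- bad | (ea == v & eb == u) | (ea == u & eb == v)
    }
    fr <- neg[bad, , drop = FALSE]
    if (nrow(fr) > 0) {
      fr$reason <- "odd_cycle_two_coloring_conflict"
      frustrated <- rbind(frustrated, fr)
    }
  }
  side1 <- sort(nodes[!is.na(color[comp]) & color[comp] == 1L])
  side2 <- sort(nodes[!is.na(color[comp]) & color[comp] == 2L])
  unassigned <- sort(nodes[is.na(color[comp])])
  if (!is.null(association)) {
    dir_pos <- association$feature[association$direction == "positive"]
    if (sum(side2 %in% dir_pos) > sum(side1 %in% dir_pos)) {
      tmp <- side1; side1 <- side2; side2 <- tmp
    }
  } else if (length(side2) > 0 && length(side1) > 0 &&
             min(side2) < min(side1)) {
    tmp <- side1; side1 <- side2; side2 <- tmp
  }
  rownames(frustrated) <- NULL
  structure(list(guild1 = side1, guild2 = side2, unassigned = unassigned,
                 frustrated = frustrated, n_components = n_comp),
            class = "guild_partition")
}

#' Verify the guild sign pattern of a partition
#'
#' Machine check of the guild invariant: every within-guild edge positive,
#' every between-guild edge negative, except edges already reported as
#' frustrated.
#'
#' @param partition A `guild_partition`.
#' @param net The `coab_network` it was derived from.
#' @return Number of unreported violations (0 when the invariant holds).
#' @export
check_guild_partition <- function(partition, net) {
  stopifnot(inherits(partition, "guild_partition"),
            inherits(net, "coab_network"))
  edges <- net$edges
  g1 <- partition$guild1; g2 <- partition$guild2
  lab <- function(x) ifelse(x %in% g1, 1L, ifelse(x %in% g2, 2L, NA))
  la <- lab(edges$from); lb <- lab(edges$to)
  scope <- !is.na(la) & !is.na(lb)
  within <- scope & la == lb
  between <- scope & la != lb
  bad <- (within & edges$r < 0) | (between & edges$r > 0)
  fr_keys <- edge_key(partition$frustrated$from, partition$frustrated$to)
  sum(bad & !(edge_key(edges$from, edges$to) %in% fr_keys))
}

#' Per-sample guild abundance sums
#'
#' @param abundances Counts or relative abundances, features x samples.
#' @param partition A `guild_partition`.
#' @param relative Convert to relative abundance first (default TRUE).
#' @return data.frame with per-sample `guild1` and `guild2` sums.
#' @export
guild_abundance <- function(abundances, partition, relative = TRUE) {
  stopifnot(inherits(partition, "guild_partition"))
  members <- c(partition$guild1, partition$guild2)
  if (!all(members %in% rownames(abundances))) {
    stop("guild member missing from abundance table")
  }
  ab <- if (relative) sweep(abundances, 2, colSums(abundances), "/") else
    abundances
  data.frame(sample = colnames(abundances),
             guild1 = colSums(ab[partition$guild1, , drop = FALSE]),
             guild2 = colSums(ab[partition$guild2, , drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact test for small samples (combined n <= 25 and no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector; both groups need >= 3 values.
#' @return List with `statistic`, `p`, and the group labels compared.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 3 || length(y) < 3) stop("each group needs >= 3 values")
  exact <- (length(x) + length(y) <= 25) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       groups = levels(groups))
}

#' Shannon diversity of functional annotations per genome
#'
#' `H = -sum p log p` over the annotation counts of each genome (natural
#' log), computed with the standard ecology implementation.
#'
#' @param ko_table Nonnegative count matrix, genomes x annotations (e.g. KEGG
#'   Orthologs).
#' @return Named numeric vector of per-genome Shannon indices.
#' @export
ko_shannon <- function(ko_table) {
  stopifnot(is.matrix(ko_table) || is.data.frame(ko_table))
  m <- as.matrix(ko_table)
  if (any(m < 0)) stop("annotation counts must be nonnegative")
  if (any(rowSums(m) == 0)) {
    bad <- rownames(m)[rowSums(m) == 0]
    stop("genome with zero annotations: ", paste(bad, collapse = ", "))
  }
  vegan::diversity(m, index = "shannon")
}

#' Guild enrichment scan over genome features
#'
#' Per feature, a two-group generalized linear model of the feature on guild
#' membership: binomial for presence/absence features, quasi-Poisson
#' (overdispersion-robust) for counts. On complete separation (binomial fit
#' degenerate) the p-value falls back to Fisher's exact test on the 2x2
#' presence table. Significance at BH FDR < `fdr`.
#'
#' @param feature_matrix Genomes x features matrix, binary or counts.
#' @param guild_labels Two-level guild assignment per genome.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame with `feature`, `estimate`, `p`, `q`, `significant`,
#'   `enriched_in`. Constant features are skipped.
#' @export
enrichment_scan <- function(feature_matrix, guild_labels, fdr = 0.05) {
  m <- as.matrix(feature_matrix)
  guild <- factor(guild_labels)
  stopifnot(nrow(m) == length(guild), nlevels(guild) == 2)
  lv <- levels(guild)
  res <- lapply(colnames(m), function(f) {
    y <- m[, f]
    if (stats::sd(y) == 0) return(NULL)
    binary <- all(y %in% c(0, 1))
    if (binary) {
      fit <- suppressWarnings(stats::glm(y ~ guild, family = stats::binomial()))
      est <- stats::coef(fit)[2]
      separated <- !fit$converged || abs(est) > 15
      if (separated) {
        tab <- table(factor(y, levels = c(0, 1)), guild)
        p <- stats::fisher.test(tab)$p.value
      } else {
        p <- summary(fit)$coefficients[2, 4]
      }
    } else {
      fit <- suppressWarnings(
        stats::glm(y ~ guild, family = stats::quasipoisson()))
      est <- stats::coef(fit)[2]
      p <- summary(fit)$coefficients[2, 4]
    }
    mean1 <- mean(y[guild == lv[1]]); mean2 <- mean(y[guild == lv[2]])
    data.frame(feature = f, estimate = unname(est), p = p,
               enriched_in = if (mean1 >= mean2) lv[1] else lv[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no non-constant features")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out[order(out$p), c("feature", "estimate", "p", "q", "significant",
                      "enriched_in")]
}

#' Fisher's exact test on a 2x2 table
#'
#' @param a,b,c,d Nonnegative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return List with `odds_ratio` and `p` (two-sided).
#' @export
proportion_test <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  ht <- stats::fisher.test(matrix(c(a, c, b, d), 2))
  list(odds_ratio = unname(ht$estimate), p = ht$p.value)
}
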