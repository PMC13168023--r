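# coabnet

Longitudinal analysis of microbial co-abundance networks: who interacts with
whom in a gut community, which of those interactions persist as the host
develops, and how network structure relates to a host phenotype such as
growth rate.

`coabnet` is aimed at microbiome researchers working with stage-structured
metagenomic abundance tables (species or MAG level, one table per host age).
It implements the full analysis chain as composable R functions:

1. **Compositionality-aware network inference.** Relative-abundance data make
   naive correlations spurious; `coabnet` implements the SparCC estimator:
   from pairwise log-ratio variances `t_ij = Var[log(x_i/x_j)]`, basis
   variances `ω²` solve `((p−2)I + 11ᵀ) ω² = rowSums(t)` under a sparsity
   assumption, and correlations are
   `r_ij = (ω_i² + ω_j² − t_ij) / (2 ω_i ω_j)`, with iterative exclusion of
   strongly correlated pairs from the solve and averaging over Dirichlet
   resamplings of the fractions. Significance comes from permutation pseudo
   p-values `(1 + #{|r_perm| ≥ |r_obs|}) / (1 + B)` with Benjamini–Hochberg
   FDR filtering of edges.
2. **Cross-age edge dynamics.** Each edge shared between age stages is
   classified by fixed-effect Fisher-z meta-analysis: `z_k = atanh(r_k)`,
   weights `w_k = n_k − 3`, Cochran's `Q = Σ w_k (z_k − z̄)²`, and
   `I² = max(0, (Q − df)/Q)·100`. Edges with `p_Q > 0.05` are *stable*;
   edges with `I² > 75%` and FDR < 0.05 are *heterogeneous* (changed
   strength or flipped sign between ages).
3. **Topology and resilience.** Strength-filtered networks (`|r| > 0.2`)
   are summarized by the standard metric set (degree, clustering,
   centralization, modularity), node roles by the Zi–Pi quadrants
   (module hubs, connectors, network hubs at Zi 2.5 / Pi 0.62), power-law
   degree fits, abundance-weighted mean interaction strength
   (`wMIS_i = Σ_j a_j r_ij / Σ_j a_j` over neighbors), a stability index
   over cross-age core nodes, efficiency-based vulnerability, and
   robustness simulations contrasting targeted hub removal with random
   non-hub removal.
4. **Guilds and metabolic interactions.** A per-feature linear-model scan
   associates taxa with a continuous phenotype (log total-sum-scaled
   abundances, BH FDR); significant taxa are organized into two
   antagonistic guilds by two-coloring the signed co-abundance graph
   (positive edges within, negative between). Guild members' metabolic
   competition (MRO) and complementarity (MIP) indices are combined into
   the distance `D = 1 − (MRO − MIP)` and the competition intensity
   `C = Z(MRO) − Z(MIP)`, with the upper quartile of between-guild pairs
   flagged competitive, phylogeny-adjusted complementarity outliers,
   core/cloud pathway classes, and shared-demand metabolite rankings.

Because the real data behind such studies are thousands of metagenomes, the
package ships a first-class synthetic-data module: a logistic-normal–
multinomial generator with planted conserved/variable correlations, two
antagonistic guilds driving a phenotype, and anti-correlated MRO/MIP
fixtures, so every stage of the pipeline is testable against known ground
truth.

## Worked example

Plant two conserved correlations (rho 0.7) and one sign-flipping pair
(+0.6 / −0.6 / +0.6) across three ages, simulate counts, infer the
networks, and classify edge conservation:

```r
library(coabnet)

spec <- planted_network_spec(
  n_taxa = 12, stages = c("D25", "D120", "D240"),
  conserved_edges = data.frame(i = c(1, 3), j = c(2, 4), rho = 0.7),
  variable_edges  = data.frame(i = 5, j = 6, rho_D25 = 0.6,
                               rho_D120 = -0.6, rho_D240 = 0.6))
sim    <- generate_stage_correlations(spec)
counts <- generate_counts(sim$correlations, n_samples = 150, seed = 42)

fit <- sparcc(counts$D120, n_inner = 10, seed = 1)
round(fit$r[1:6, 1:6], 2)
#>       t001  t002  t003  t004  t005  t006
#> t001  1.00  0.74  0.04 -0.03  0.04  0.07
#> t002  0.74  1.00  0.02  0.01  0.01 -0.05
#> t003  0.04  0.02  1.00  0.69 -0.04  0.04
#> t004 -0.03  0.01  0.69  1.00 -0.04  0.12
#> t005  0.04  0.01 -0.04 -0.04  1.00 -0.64
#> t006  0.07 -0.05  0.04  0.12 -0.64  1.00

nets <- lapply(names(counts), function(s) {
  f  <- sparcc(counts[[s]], n_inner = 10, seed = 1)
  pv <- permutation_pvalues(counts[[s]], f$r, n_permutations = 500, seed = 2)
  build_network(f$r, pv, bh_adjust(pv), q_cutoff = 0.05, stage = s,
                n_samples = 150)
})
cons <- classify_conservation(match_edges(nets))
cons[, c("from", "to", "r_D25", "r_D120", "r_D240", "Q", "I2", "label")]
#>   from   to r_D25 r_D120 r_D240      Q   I2         label
#> 1 t001 t002 0.674  0.736  0.702   1.15  0.0        stable
#> 2 t003 t004 0.761  0.693  0.678   2.51 20.4        stable
#> 3 t005 t006 0.717 -0.641  0.547 232.02 99.1 heterogeneous
```

The SparCC estimates recover the planted correlations (0.74 and 0.69 for
the rho-0.7 pairs, −0.64 for the flipped pair at D120); the three planted
edges survive the FDR filter at every age; the meta-analysis leaves the two
conserved edges `stable` (Q small, I² low) and flags the sign-flipping pair
`heterogeneous` (Q = 232 on 2 df, I² = 99%).

The whole chain — simulation, per-stage networks, beneficial subnetworks,
edge dynamics, topology, resilience, guilds, metabolic scoring — runs as
one call:

```r
cfg <- pipeline_config(seed = 1)       # 150 taxa, 3 stages x 300 samples
res <- run_pipeline(cfg, "out/")       # writes TSV/GraphML/JSON + manifest
```

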