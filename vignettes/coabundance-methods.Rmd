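---
title: "Methods: longitudinal co-abundance networks, guilds, and metabolic scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal co-abundance networks, guilds, and metabolic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `coabnet`, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the numerical decisions a maintainer would want
written down. Everything quantitative asserted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The inference problem

Shotgun metagenomics yields per-sample relative abundances: the data are
compositional, so Pearson correlations between taxa are distorted by the
shared denominator. `coabnet` implements the SparCC estimator, which works
on log-ratio variances

$$t_{ij} = \mathrm{Var}\!\left[\log(x_i/x_j)\right]
         = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j,$$

where $\omega_i^2$ is the latent (basis) variance of taxon $i$. Assuming the
correlation matrix is sparse, $\sum_{j \ne i}\rho_{ij}\omega_i\omega_j
\approx 0$, giving the linear system

$$\big((p-2)I + \mathbf{1}\mathbf{1}^\top\big)\,\omega^2 = t\,\mathbf{1},$$

solved for all basis variances at once, and
$r_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$, clipped
to $[-1, 1]$.

Key numerical decisions:

* **Fractions.** Counts are converted to strictly positive fractions by the
  Dirichlet posterior mean with a +1 pseudocount,
  $(c_{ij}+1)/(N_j + p)$. When `n_inner > 1` (default 20) the final $r$ is
  the average over full Dirichlet resamplings of the per-sample fractions,
  which propagates count noise; `n_inner = 1` uses the deterministic
  posterior mean (used inside permutation nulls for speed and determinism).
* **Exclusion iterations.** The sparsity assumption fails for strongly
  correlated pairs, so the pair with the largest $|r|$ above
  `exclusion_threshold` (default 0.1) is removed from the linear system —
  not from the final correlation formula — and the system is re-solved, up
  to `max_exclusions` (default 10) pairs. Exclusion stops early if it would
  leave fewer than four effective taxa, or if the system becomes singular.
  These defaults are the estimator's conventional settings.
* **Clipping.** Basis variances are floored at $10^{-12}$ before taking
  square roots; correlations are clipped to $[-1,1]$. Two exactly
  proportional taxa have $t_{ij}=0$ and reach $r_{ij}=1$.

The implementation is verified, to $10^{-10}$, against an independent
brute-force transcription of the same equations (explicit loops, literal
matrix inverse) on tables of 4–8 taxa, and against the closed-form case of
equal log-ratio variances, where $\omega^2 = t/2$ and all correlations are
exactly zero.

## Permutation significance and edge filtering

The null model destroys inter-taxon association while preserving each
taxon's marginal counts: every permutation shuffles each taxon's counts
across samples independently (`scheme = "permute"`; a bootstrap flavor that
resamples with replacement is available, since tools differ on this point)
and the full estimator is re-run. Pseudo p-values use +1 smoothing,
$p = (1 + \#\{|r^\ast| \ge |r|\})/(1 + B)$, so $p > 0$ always, with floor
$1/(B+1)$. BH adjustment runs over the upper triangle only, and edges with
$q <$ `network_fdr` (default 0.05) form the network.

**Why the default is 1,000 permutations.** The smoothed floor interacts
with BH: with $p$ taxa there are $m = p(p-1)/2$ hypotheses, and if $k$
edges sit at the floor their adjusted value is $m/(k(B+1))$. At the default
scale (150 taxa, $m = 11{,}175$, roughly 270 true edges) a 200-permutation
run has floor $1/201$ and a smallest attainable $q$ of about 0.21 — no
edge can ever pass FDR 0.05, regardless of effect size. $B = 1000$ makes
the attainable $q \approx 0.04$. This is an arithmetic constraint, not a
tuning choice: permutation resolution must exceed
$m\,/\,(k \cdot \mathrm{FDR})$.

## Cross-age conservation and heterogeneity

Edges present in all compared stages enter a fixed-effect Fisher-z
meta-analysis: $z_k = \mathrm{atanh}(r_k)$ with large-sample weights
$w_k = n_k - 3$, pooled $\bar z = \sum w z / \sum w$, Cochran's
$Q = \sum w (z - \bar z)^2$ on $K - 1$ df, and
$I^2 = \max(0, (Q - df)/Q) \cdot 100$. Labels: *stable* if $p_Q > 0.05$;
*heterogeneous* if $I^2 > 75$ and BH-adjusted $p_Q < 0.05$ (adjusted within
the compared edge set, since each stage comparison is its own analysis);
*intermediate* otherwise. The Fisher-z scale was chosen because it is the
statistically standard treatment of correlations in meta-analysis; the
implementation agrees with a generic fixed-effect meta-analysis package to
$10^{-8}$ on random inputs.

Heterogeneous edges between two stages are further categorized as
*reversed* (sign change), *increased_at_A*, or *decreased_at_A* by
magnitude, with per-stage significance carried as a sub-annotation; a zero
correlation makes the pair *indeterminate* and is logged. Reported
percentages are rounded half-up to two decimals, the precision used in
printed summaries.

One caveat the tests make visible: SparCC correlations carry estimation
noise beyond the $1/(n-3)$ Fisher-z variance (compositional estimation,
resampling averaging, stage-specific attenuation), so on real pipeline
output the stable rate among truly conserved edges runs a few points below
the nominal 95%. The calibration claim (95% ± 3 at $n = 300$) is therefore
tested on plain bivariate-normal correlations, which is the regime the
meta-analysis model actually assumes.

## Topology, roles, and degree distributions

Topological analyses run on strength-filtered networks. The filter defaults
to $|r| > 0.2$ (absolute mode): a literal reading of "r > 0.2" would
discard every negative edge, yet negative-edge counts are part of the
standard topology report, so the absolute rule is the default and the
signed rule is available as `mode = "signed"`. Metrics: average degree
$2E/N$; unweighted average local clustering (nodes of degree < 2 contribute
0); Freeman degree centralization $\sum(k_{max} - k_i)/((N-1)(N-2))$;
modularity of the greedy (fast-greedy) partition on the $|r|$-weighted
graph. Greedy modularity was chosen over Louvain because it is
deterministic — reproducibility matters more here than the last few
hundredths of modularity — and if no partition beats the trivial one the
single-module partition (modularity 0) is returned.

Node roles use the within-module degree z-score $Z_i$ (0 when the module's
within-degrees have zero spread) and participation coefficient
$P_i = 1 - \sum_s (k_{is}/k_i)^2$, with the standard quadrant thresholds
2.5 / 0.62: peripheral, connector, module hub, network hub. Threshold
conventions for "connector" versus "peripheral" are sometimes written down
inconsistently in applied work, so the package sticks to the standard
quadrant scheme that the field's tooling implements; all non-peripheral
roles together form the hub set.

Degree sequences are fit by the continuous-approximation MLE
$\hat\alpha = 1 + n / \sum \ln(x/x_{min})$ with $x_{min}$ selected by KS
minimization (tails of at least 10 nodes) and a 100-resample parametric
bootstrap verdict (plausible if the observed KS is not extreme,
$p > 0.1$). This is deliberately lighter than a full likelihood-ratio
model-comparison framework; it recovers a planted exponent of 2.5 within
±0.3 at $n = 500$ and rejects Erdős–Rényi degree sequences, which is the
discrimination the analysis needs.

## Resilience

* $\mathrm{wMIS}_i = \sum_{j \in N(i)} a_j r_{ij} / \sum_{j \in N(i)} a_j$:
  the abundance-weighted mean signed interaction strength over neighbors;
  isolated nodes score 0. The index circulates in applied work without a
  canonical printed equation, so this formula is the package's explicit
  instantiation (flagged in output metadata); totals use $|\mathrm{wMIS}|$
  so positive and negative interactions both count as influence.
* Stability $S = (|core|/N) \cdot
  (\sum_{core}|\mathrm{wMIS}|/\sum_{all}|\mathrm{wMIS}|)$, where core nodes
  are those present at every stage. $S$ is monotone in both stated
  ingredients and equals 1 when every node is core — again an explicit
  stand-in for a verbally described quantity.
* Global efficiency $E = \frac{1}{n(n-1)}\sum_{i \ne j} 1/d_{ij}$ with
  unweighted shortest paths (disconnected pairs contribute 0); node
  vulnerability $V_i = (E - E_{-i})/E$ and network vulnerability
  $\max_i V_i$.
* Robustness: per replicate, targeted removal deletes
  $\max(1, \lfloor |hubs|/2 \rfloor)$ hubs uniformly; random attack deletes
  the same number of non-hubs; the retention ratio is total
  $|\mathrm{wMIS}|$ after recomputation over the value before. Ten
  replicates by default, compared by a two-sided Wilcoxon rank-sum test
  (p = 1 when every ratio ties, which happens on vertex-transitive
  graphs). On scale-free (preferential-attachment) graphs hub removal
  retains significantly less than random removal; on Erdős–Rényi graphs
  the contrast vanishes — the structural asymmetry the analysis is designed
  to exhibit.

## Guilds

The association scan mirrors the common microbiome practice: total-sum
scaling, half-minimum replacement of zeros per feature, log2 transform, and
a per-feature fixed-effects linear model on the continuous phenotype with
optional covariates (no random effects: no grouping factor exists in the
single-stage scan; a covariate slot covers batch-like structure), BH over
features, significance at `association_fdr` (default 0.2, the conventional
screening threshold for such scans).

Guild detection formalizes "two groups, positive within, negative between"
as graph two-coloring: connected components of the positive-edge subgraph
are contracted to supernodes; the supernode graph induced by negative edges
is two-colored breadth-first. Odd cycles and negative edges inside positive
components are *frustrated* edges — reported, never silently dropped,
because real data need not be perfectly balanced. Supernodes untouched by
negative edges remain unassigned. Guild 1 is the side with more positively
phenotype-associated members, so labels are comparable across runs. The
partition invariant (all within-guild edges positive, all between-guild
edges negative, minus reported frustrations) is machine-checked by
`check_guild_partition()`.

## Metabolic scoring

MRO (resource overlap, competition) and MIP (interaction potential,
complementarity) are consumed as precomputed pairwise indices — genome-scale
metabolic model reconstruction is out of scope. Composites:
$D = 1 - (\mathrm{MRO} - \mathrm{MIP}) \in [0, 2]$ and
$C = Z(\mathrm{MRO}) - Z(\mathrm{MIP})$. Two standardization populations are
reported because the choice is genuinely open: $C$ standardized over the
between-guild pairs (the set on which competitive pairs are defined — the
only choice consistent with flagging exactly a quarter of between-guild
pairs) and over all pairs for global comparisons. Z-scores use the sample
(n−1) standard deviation. The upper quartile is the top
$\lceil N/4 \rceil$ ranks with ties broken by pair id, so the flagged count
is deterministic; phylogeny-adjusted complementarity outliers are pairs
whose OLS residual of MIP on phylogenetic distance exceeds
`outlier_z` (default 2.698) residual standard deviations, that threshold
being accepted as a parameter rather than re-derived. Pathways are *core*
at ≥ 90% prevalence within a guild, *cloud* at ≤ 10% or a single carrier,
*shell* otherwise; shared-demand ranking scores each metabolite by the
number of competitive pairs whose uptake-set intersection contains it.

Module similarity between partitions uses Jaccard indices on member sets;
the single network-level number is the symmetrized best-match mean (each
module matched to its best counterpart in the other partition, averaged
over both directions). The aggregation is a package choice — the full
pairwise matrix is always returned so any other aggregation can be
recomputed.

## The synthetic-data generator

`generate_counts()` draws latent log-abundances from a multivariate normal
with the planted stage correlation matrix (per-taxon SD `latent_sd`,
default 1.3), softmax-transforms to compositions, and samples multinomial
counts at fixed depth. The generator emulates:

* compositional closure and multinomial count noise at realistic depth
  (default 50,000 reads over 150 taxa);
* a rank-abundance gradient (50-fold range of latent means) with the guild
  taxa among the dominant community members, so guild sums are volatile
  enough (bloom-like dynamics) for the phenotype model
  `effect_size × (guild1 − guild2 relative abundance) + noise` to carry a
  strong signal at the planted effect size 5 and unit noise;
* planted conserved (rho 0.7 strong, 0.25 weak), variable
  (+0.6/−0.6/+0.6 sign flips), and two-guild (+0.6 within, −0.5 between)
  correlation structure, repaired to positive definiteness by eigenvalue
  clipping at $10^{-6}$ and unit-diagonal renormalization; a repair that
  moves any planted entry by more than 0.02 is an error, not a warning;
* anti-correlated MRO/MIP fixtures: pathway repertoires are
  phylogenetically structured balls on a random tree, MRO is the pathway
  overlap coefficient (identical repertoires give exactly 1), MIP rises
  with phylogenetic distance — so MRO and MIP are negatively correlated by
  construction.

It does **not** emulate: sequencing error or read-level artifacts,
prevalence sparsity patterns of real gut data (taxa are mostly prevalent at
the default depth), taxonomic correlation between guild membership and
lineage, time-series autocorrelation within individuals (stages are
independent cross-sections), or any real taxonomy. Passing tests therefore
demonstrate correctness of the estimators and the recoverability of planted
structure under the model's own assumptions — not performance on real
metagenomes.

All randomness flows from one master seed through `make_seed(master,
offset)` with a documented offset registry (see `?run_pipeline`); there is
no hidden global state, and the pipeline is byte-identical across runs at a
fixed seed.

## Problem sizes

The default study scale is 150 taxa, 3 stages × 300 samples, depth 50,000,
1,000 permutations per stage — a scale at which the full pipeline completes
in a few minutes on a single core while leaving all planted effects
comfortably recoverable (100% of |rho| ≥ 0.6 edges, guild ARI 1.0 in the
shipped acceptance run). Unit tests use 12–40 taxa and 100–600
permutations; the permutation count in each fixture respects the BH-floor
arithmetic above.

## Known limitations

* The wMIS and stability formulas are explicit stand-ins for verbally
  described indices; alternative formalizations would shift absolute
  values (comparisons across stages are unaffected by monotone rescaling).
* The power-law verdict is a KS bootstrap, not a full model comparison
  against log-normal or exponential alternatives.
* Meta-analysis treats per-stage SparCC correlations as if they were plain
  sample correlations; attenuation and estimation noise make the stable
  classification mildly anti-conservative on pipeline output (see above).
* Guild detection assumes the phenotype-associated subgraph is nearly
  balanced; heavily frustrated graphs yield a valid partition but a long
  frustrated-edge report, which is the intended signal to inspect.
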