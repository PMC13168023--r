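# independent brute-force oracle for the SparCC equations: pairwise
# log-ratio variances computed by explicit loops, the basis-variance linear
# system built and solved literally, exclusions applied by the same rule.
# Shares no code with the package implementation.
brute_force_sparcc <- function(fractions, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  n <- nrow(fractions)
  p <- ncol(fractions)
  t_mat <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) {
        t_mat[i, j] <- stats::var(log(fractions[, i] / fractions[, j]))
      }
    }
  }
  m_mat <- diag(p - 2, p) + matrix(1, p, p)
  t_sys <- t_mat
  excluded <- matrix(FALSE, p, p)
  excl_count <- rep(0, p)
  n_excl <- 0
  r <- NULL
  repeat {
    inv <- tryCatch(solve(m_mat), error = function(e) NULL)
    if (is.null(inv)) break       # singular system: stop excluding
    omega2 <- inv %*% rowSums(t_sys)
    omega2 <- pmax(as.numeric(omega2), 1e-12)
    r <- matrix(0, p, p)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        r[i, j] <- (omega2[i] + omega2[j] - t_mat[i, j]) /
          (2 * sqrt(omega2[i]) * sqrt(omega2[j]))
      }
    }
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    if (n_excl >= max_exclusions) break
    best <- c(NA, NA)
    best_v <- exclusion_threshold
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (!excluded[i, j] && abs(r[i, j]) > best_v) {
          best_v <- abs(r[i, j])
          best <- c(i, j)
        }
      }
    }
    if (is.na(best[1])) break
    nc <- excl_count
    nc[best] <- nc[best] + 1
    if (sum(nc < p - 1) < 4) break
    excl_count <- nc
    i <- best[1]; j <- best[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    t_sys[i, j] <- t_sys[j, i] <- 0
    m_mat[i, i] <- m_mat[i, i] - 1
    m_mat[j, j] <- m_mat[j, j] - 1
    m_mat[i, j] <- m_mat[j, i] <- m_mat[i, j] - 1
    n_excl <- n_excl + 1
  }
  r
}

# textbook fixed-effect meta-analysis of Fisher-z correlations, written
# directly from the formulas
brute_force_meta <- function(r, n) {
  z <- 0.5 * log((1 + r) / (1 - r))
  w <- n - 3
  zbar <- sum(w * z) / sum(w)
  q <- sum(w * (z - zbar)^2)
  df <- length(r) - 1
  list(Q = q, df = df, p_Q = 1 - stats::pchisq(q, df),
       I2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
       pooled_z = zbar)
}

# random strictly positive fraction table (rows sum to 1)
random_fractions <- function(n, p, seed) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * p, shape = 2), n, p)
  g / rowSums(g)
}
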