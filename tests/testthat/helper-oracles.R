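# Independent oracle implementations used across the suite. These are
# deliberately written as plain, slow, loop-based evaluations so that
# agreement with the vectorised package code is a genuine dual-route check.

# NormFinder grouped variance-components model, evaluated literally:
# double-centred residual variances with the a/(a-2) correction, moment
# estimate of the bias variance, shrunken biases, stability =
# group-mean of |shrunk bias| + SE.
oracle_normfinder <- function(x, groups) {
  groups <- factor(groups)
  a <- ncol(x)
  G <- nlevels(groups)
  ng <- as.numeric(table(groups))
  sigma2 <- matrix(0, a, G)
  z <- matrix(0, a, G)
  for (g in seq_len(G)) {
    y <- x[groups == levels(groups)[g], , drop = FALSE]
    n_g <- nrow(y)
    S <- numeric(a)
    for (i in seq_len(a)) {
      acc <- 0
      for (j in seq_len(n_g)) {
        r <- y[j, i] - mean(y[, i]) - mean(y[j, ]) + mean(y)
        acc <- acc + r^2
      }
      S[i] <- acc / (n_g - 1)
    }
    for (i in seq_len(a))
      sigma2[i, g] <- max(0, (S[i] - mean(S) / (a - 1)) * a / (a - 2))
    for (i in seq_len(a)) z[i, g] <- mean(y[, i]) - mean(y)
  }
  d <- z - rowMeans(z)
  samp_var <- matrix(0, a, G)
  for (g in seq_len(G)) samp_var[, g] <- sigma2[, g] / ng[g]
  gamma2 <- max(0, sum(d^2) / ((a - 1) * (G - 1)) - mean(samp_var))
  stab <- numeric(a)
  for (i in seq_len(a)) {
    acc <- 0
    for (g in seq_len(G)) {
      sh <- if (gamma2 > 0) gamma2 / (gamma2 + samp_var[i, g]) else 0
      acc <- acc + abs(d[i, g] * sh) + sqrt(samp_var[i, g] * sh)
    }
    stab[i] <- acc / G
  }
  stab
}

# AUC by exhaustive pair counting: concordant pairs + half ties.
oracle_auc_pairs <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  acc <- 0
  for (s1 in cases) for (s0 in controls)
    acc <- acc + (s1 > s0) + 0.5 * (s1 == s0)
  acc / (length(cases) * length(controls))
}

# Two-sided exact Mann-Whitney p by full enumeration of group
# assignments (no ties assumed).
oracle_mw_exact <- function(x1, x2) {
  all_v <- c(x1, x2)
  n1 <- length(x1)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  obs <- u_stat(x1, x2)
  n <- length(all_v)
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, function(idx) u_stat(all_v[idx], all_v[-idx]))
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Small standard synthetic cohort shared by several tests.
default_test_cohort <- function(seed = 42) {
  generate_cohort(sim_config(seed = seed))
}
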