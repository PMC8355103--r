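#' TMM scaling factors for a count matrix
#'
#' Trimmed-mean-of-M-values normalization for between-sample scaling of
#' miRNA read counts. For each sample against the reference column
#' (the one whose counts-per-library 75th percentile is closest to the
#' mean 75th percentile), M (log2 expression ratio) and A (average log2
#' abundance) values are computed over features expressed in both,
#' doubly trimmed (`trim_m` of M tails, `trim_a` of A tails), and
#' averaged with inverse approximate-binomial-variance weights. Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param counts Features x samples matrix of non-negative counts.
#' @param trim_m,trim_a Two-sided trim fractions for M and A
#'   (defaults 0.30 and 0.05).
#' @param lib_sizes Optional library sizes (default: column sums).
#' @return Named per-sample scaling factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- lib_sizes %||% colSums(counts)
  if (any(lib == 0)) stop("all-zero sample (library size 0)")

  # reference: 75th percentile of scaled counts closest to the mean
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75, names = FALSE) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(obs, n_obs, refc, n_ref) {
    logR <- log2((obs / n_obs) / (refc / n_ref))
    absE <- (log2(obs / n_obs) + log2(refc / n_ref)) / 2
    v <- (n_obs - obs) / n_obs / obs + (n_ref - refc) / n_ref / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
            (rank(absE) >= loS & rank(absE) <= hiS)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one_factor(counts[, j], lib[j], counts[, ref], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Simplified negative-binomial exact test for two-group count data
#'
#' Per-feature two-sided test of differential abundance between two
#' groups. Counts are scaled to a common effective library size (library
#' size times TMM factor), a single common dispersion is estimated by
#' method of moments across features, and the conditional exact test on
#' the per-group sums of (rounded) scaled counts is evaluated: under the
#' null the two group sums are negative binomial with shared mean per
#' sample, and the two-sided p-value sums the probabilities of all
#' splits as or less likely than the observed one. When the
#' method-of-moments dispersion is zero the test falls back to the
#' Poisson (binomial-conditional) exact test, with a warning.
#'
#' This is a deliberately simplified variant: it keeps the structure of
#' the exact negative-binomial test but replaces the
#' conditional-maximum-likelihood dispersion machinery with a single
#' moment estimate.
#'
#' @param counts Features x samples non-negative integer matrix.
#' @param groups Two-level factor/vector over samples (case/control).
#' @param factors Optional TMM factors from [tmm_factors()]; computed
#'   when `NULL`.
#' @param pseudo Pseudo-count added to TMM-scaled group means for the
#'   log2 fold change (default 0.5).
#' @return Data.frame of class `de_result`: `feature`, `p`, `fdr` (BH),
#'   `log2fc` (first level vs second level of `groups`), `mean_tmm_case`,
#'   `mean_tmm_control`, `dispersion` (common value used).
#' @export
de_test <- function(counts, groups, factors = NULL, pseudo = 0.5) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) == 0)) stop("both groups must be non-empty")
  factors <- factors %||% tmm_factors(counts)
  eff_lib <- colSums(counts) * factors
  # scale to the geometric mean effective library size
  target <- exp(mean(log(eff_lib)))
  scaled <- sweep(counts, 2, target / eff_lib, "*")

  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(scaled[, g1, drop = FALSE])
  m2 <- rowMeans(scaled[, !g1, drop = FALSE])

  # common method-of-moments dispersion on scaled counts:
  # var = mu + phi * mu^2 within groups, pooled across features
  mom_phi <- function(sub) {
    mu <- rowMeans(sub); v <- apply(sub, 1, stats::var)
    ok <- mu > 0
    (v[ok] - mu[ok]) / mu[ok]^2
  }
  phis <- c(mom_phi(scaled[, g1, drop = FALSE]),
            mom_phi(scaled[, !g1, drop = FALSE]))
  phi <- max(0, stats::median(phis, na.rm = TRUE))
  if (phi == 0 && any(phis > 0, na.rm = TRUE))
    warning("method-of-moments dispersion is zero; using Poisson exact test")

  n1 <- sum(g1); n2 <- sum(!g1)
  s1 <- round(rowSums(scaled[, g1, drop = FALSE]))
  s2 <- round(rowSums(scaled[, !g1, drop = FALSE]))

  p <- vapply(seq_len(nrow(counts)), function(i) {
    t_i <- s1[i] + s2[i]
    if (t_i == 0) return(1)
    x <- 0:t_i
    if (phi > 0) {
      # group sums: NB(size = n_g/phi, mu = n_g * mu0)
      mu0 <- t_i / (n1 + n2)
      lp <- stats::dnbinom(x, size = n1 / phi, mu = n1 * mu0, log = TRUE) +
        stats::dnbinom(t_i - x, size = n2 / phi, mu = n2 * mu0, log = TRUE)
    } else {
      lp <- stats::dbinom(x, t_i, n1 / (n1 + n2), log = TRUE)
    }
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    obs <- pr[s1[i] + 1]
    sum(pr[pr <= obs * (1 + 1e-10)])
  }, numeric(1))

  out <- data.frame(
    feature = rownames(counts) %||% paste0("f", seq_len(nrow(counts))),
    p = p, fdr = bh_fdr(p),
    log2fc = log2((m1 + pseudo) / (m2 + pseudo)),
    mean_tmm_case = m1, mean_tmm_control = m2,
    dispersion = phi, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, via
#' [stats::p.adjust()].
#'
#' @param pvals Raw p-values in `[0, 1]`; NaN is an error.
#' @return Adjusted values (FDR).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-value")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Apply the published candidate-selection filters
#'
#' A feature is selected iff FDR < `fdr_max` AND its TMM-scaled mean
#' exceeds `tmm_min` in the case or the control group AND
#' |log2 fold change| > `abs_lfc_min`. All inequalities strict.
#'
#' @param de A `de_result` from [de_test()].
#' @param fdr_max,tmm_min,abs_lfc_min Thresholds (defaults 0.05, 10, 1).
#' @return Character vector of selected feature ids; the `de` data frame
#'   with a `selected` column is attached as attribute `"table"`.
#' @export
select_candidates <- function(de, fdr_max = 0.05, tmm_min = 10,
                              abs_lfc_min = 1) {
  stopifnot(all(c("fdr", "log2fc", "mean_tmm_case", "mean_tmm_control")
                %in% names(de)))
  sel <- de$fdr < fdr_max &
    (de$mean_tmm_case > tmm_min | de$mean_tmm_control > tmm_min) &
    abs(de$log2fc) > abs_lfc_min
  de$selected <- sel
  structure(de$feature[sel], table = de)
}

#' Simulate a miRNA NGS count matrix with planted fold changes
#'
#' Negative-binomial counts with feature-specific baseline abundances,
#' sample-specific library-depth factors, and a subset of features given
#' a true case/control fold change. Used by the discovery-stage analysis
#' and tests.
#'
#' @param n_features,n_case,n_control Dimensions.
#' @param base_mean_log_range log-scale range of baseline means.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param n_de Number of differentially abundant features.
#' @param log2fc Log2 fold change (case vs control) for those features
#'   (recycled; sign alternates if scalar).
#' @param depth_sd SD of log-normal per-sample depth factors.
#' @param seed Integer seed.
#' @return List: `counts` (features x samples), `groups`, `de_features`,
#'   `log2fc` (named truth).
#' @export
simulate_count_matrix <- function(n_features = 500, n_case = 10,
                                  n_control = 10,
                                  base_mean_log_range = c(log(5), log(500)),
                                  dispersion = 0.15, n_de = 25,
                                  log2fc = 2, depth_sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  groups <- factor(rep(c("case", "control"), c(n_case, n_control)),
                   levels = c("case", "control"))
  base <- exp(runif(n_features, base_mean_log_range[1],
                    base_mean_log_range[2]))
  depth <- exp(rnorm(n, 0, depth_sd))
  de_idx <- if (n_de > 0) sample.int(n_features, n_de) else integer(0)
  lfc <- numeric(n_features)
  if (n_de > 0)
    lfc[de_idx] <- rep_len(log2fc, n_de) *
      rep_len(c(1, -1), n_de)[order(order(de_idx))]
  mu <- outer(base, depth)
  mu[, groups == "case"] <- mu[, groups == "case"] * 2^lfc
  counts <- matrix(
    if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu),
    nrow = n_features,
    dimnames = list(sprintf("mir-%04d", seq_len(n_features)),
                    sprintf("%s_%02d", groups, seq_len(n))))
  list(counts = counts, groups = groups,
       de_features = rownames(counts)[de_idx],
       log2fc = stats::setNames(lfc[de_idx], rownames(counts)[de_idx]))
}
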