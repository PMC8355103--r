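#' NormFinder stability of candidate reference assays
#'
#' Ranks candidate reference miRNAs by the NormFinder model-based
#' stability value: a variance-components decomposition of log-scale
#' expression (Cq is already log2-like) into a systematic between-group
#' bias and a within-group variance per assay. Lower stability = more
#' stable.
#'
#' For groups \eqn{g} with \eqn{n_g} samples and \eqn{a} assays, each
#' group's matrix is double-centred (per-sample and per-assay means
#' removed); the raw per-assay residual variance \eqn{S_{ig}} is
#' corrected for the centring-induced coupling between assays,
#' \eqn{\hat\sigma^2_{ig} = \max(0, (S_{ig} - \bar S_g/(a-1))\,a/(a-2))}.
#' Group biases \eqn{d_{ig}} (deviation of the assay's group mean from
#' its across-group mean, after group-level centring) are shrunk towards
#' zero by the empirical-Bayes factor
#' \eqn{\hat\gamma^2 / (\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)}, where
#' \eqn{\hat\gamma^2} is the method-of-moments estimate of the true
#' bias variance. The stability of assay \eqn{i} is the across-group
#' mean of \eqn{|\tilde d_{ig}| + \sqrt{\mathrm{Var}(\tilde d_{ig})}}.
#'
#' @param x Samples x assays numeric matrix on the log (Cq) scale; no
#'   missing values.
#' @param groups Group labels (length `nrow(x)`; at least two groups,
#'   each with at least two samples).
#' @return A data.frame of class `stability_table` with columns
#'   `assay_id`, `stability`, `bias` (across-group mean absolute shrunk
#'   bias) and `variance` (across-group mean intragroup variance),
#'   sorted by assay order of `x`. Attributes `d_post`, `var_post`
#'   (assays x groups matrices) support combination search.
#' @references The two-group variance-components reference-gene model of
#'   Andersen, Jensen and Orntoft (model-based variance estimation for
#'   normalization candidate selection).
#' @export
normfinder_stability <- function(x, groups) {
  stopifnot(is.matrix(x), nrow(x) == length(groups))
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite with no NAs")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  ng <- table(groups)
  if (any(ng < 2)) stop("every group needs at least 2 samples")
  a <- ncol(x)
  if (a < 3) stop("need at least 3 candidate assays")
  if (stats::sd(as.numeric(x)) == 0)
    stop("degenerate input: all values identical")
  G <- nlevels(groups)

  sigma2 <- matrix(NA_real_, a, G)     # intragroup variance per assay/group
  z <- matrix(NA_real_, a, G)          # centred assay means per group
  for (g in seq_len(G)) {
    y <- t(x[groups == levels(groups)[g], , drop = FALSE])  # assays x samples
    n_g <- ncol(y)
    r <- y - rowMeans(y) - rep(colMeans(y), each = a) + mean(y)
    S <- rowSums(r^2) / (n_g - 1)
    sigma2[, g] <- pmax(0, (S - mean(S) / (a - 1)) * a / (a - 2))
    z[, g] <- rowMeans(y) - mean(y)
  }
  d <- z - rowMeans(z)                 # intergroup bias estimates
  samp_var <- sweep(sigma2, 2, as.numeric(ng), "/")
  gamma2 <- max(0, sum(d^2) / ((a - 1) * (G - 1)) - mean(samp_var))
  shrink <- if (gamma2 > 0) gamma2 / (gamma2 + samp_var)
            else matrix(0, a, G)
  d_post <- d * shrink
  var_post <- samp_var * shrink
  stability <- rowMeans(abs(d_post) + sqrt(var_post))

  out <- data.frame(assay_id = colnames(x) %||% paste0("assay", seq_len(a)),
                    stability = stability,
                    bias = rowMeans(abs(d_post)),
                    variance = rowMeans(sigma2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("stability_table", "data.frame"),
            d_post = d_post, var_post = var_post,
            group_sizes = as.numeric(ng), gamma2 = gamma2)
}

#' Combined NormFinder stability of an assay set
#'
#' The stability of using the average of `set` as normalizer: per group,
#' the absolute mean shrunk bias of the set plus the standard error of
#' the set average, averaged over groups. Not bounded by the member
#' stabilities: biases of opposite sign cancel, so a combination can be
#' more stable than each member.
#'
#' @param stab A `stability_table` from [normfinder_stability()].
#' @param set Assay ids (subset of `stab$assay_id`).
#' @return Combined stability value (scalar).
#' @export
combined_stability <- function(stab, set) {
  stopifnot(inherits(stab, "stability_table"))
  idx <- match(set, stab$assay_id)
  if (anyNA(idx)) stop("unknown assay id(s): ",
                       paste(set[is.na(idx)], collapse = ", "))
  d_post <- attr(stab, "d_post"); var_post <- attr(stab, "var_post")
  k <- length(idx)
  mean(abs(colSums(d_post[idx, , drop = FALSE])) / k +
         sqrt(colSums(var_post[idx, , drop = FALSE])) / k)
}

#' Select the most stable normalizer combination
#'
#' Exhaustive search over all size-`k` subsets of the candidates,
#' minimising [combined_stability()]. Ties are broken lexicographically
#' by sorted assay id.
#'
#' @param stab A `stability_table` from [normfinder_stability()].
#' @param k Combination size (default 3).
#' @return A list with `normalizers` (character, sorted), `stability`
#'   (combined value) and `k`.
#' @export
select_normalizers <- function(stab, k = 3) {
  stopifnot(inherits(stab, "stability_table"))
  ids <- stab$assay_id
  if (k < 1) stop("k must be >= 1")
  if (k > length(ids)) stop("k exceeds the number of candidate assays")
  d_post <- attr(stab, "d_post"); var_post <- attr(stab, "var_post")
  sets <- utils::combn(seq_along(ids), k)
  G <- ncol(d_post)
  vals <- numeric(ncol(sets))
  dsum <- matrix(0, ncol(sets), G); vsum <- matrix(0, ncol(sets), G)
  for (j in seq_len(k)) {
    dsum <- dsum + d_post[sets[j, ], , drop = FALSE]
    vsum <- vsum + var_post[sets[j, ], , drop = FALSE]
  }
  vals <- rowMeans(abs(dsum) / k + sqrt(vsum) / k)
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-15)
  keys <- vapply(cand, function(i)
    paste(sort(ids[sets[, i]]), collapse = "\r"), character(1))
  pick <- cand[order(keys)][1]
  list(normalizers = sort(ids[sets[, pick]]), stability = vals[pick], k = k)
}

#' Delta-Cq normalization against a normalizer set
#'
#' Normalized expression of target t in sample s is
#' `mean(Cq[s, normalizers]) - Cq[s, t]`: a log2-scale relative
#' expression in which higher values mean higher abundance, and
#' `2^expr` equals the relative quantity of the 2^-dCt method.
#' Invariant to per-sample additive Cq offsets (global efficiency
#' shifts).
#'
#' @param cq Samples x assays Cq matrix.
#' @param normalizers Normalizer assay names (values must be present for
#'   every sample; the error names the offending sample).
#' @param targets Target assay names.
#' @return Samples x targets expression matrix.
#' @examples
#' m <- rbind(S1 = c(n1 = 20, n2 = 22, n3 = 24, t = 19))
#' normalize_cq(m, c("n1", "n2", "n3"), "t")  # 22 - 19 = 3
#' @export
normalize_cq <- function(cq, normalizers, targets) {
  missing_cols <- setdiff(c(normalizers, targets), colnames(cq))
  if (length(missing_cols))
    stop("assay(s) absent from Cq matrix: ",
         paste(missing_cols, collapse = ", "))
  nm <- cq[, normalizers, drop = FALSE]
  bad <- which(rowSums(is.na(nm)) > 0)
  if (length(bad))
    stop("missing normalizer value for sample(s): ",
         paste(rownames(cq)[bad] %||% bad, collapse = ", "))
  tg <- cq[, targets, drop = FALSE]
  bad_t <- which(rowSums(is.na(tg)) > 0)
  if (length(bad_t))
    stop("missing target value for sample(s): ",
         paste(rownames(cq)[bad_t] %||% bad_t, collapse = ", "))
  rowMeans(nm) - tg
}

#' Linear-scale relative expression (2^-dCt)
#'
#' @param expr Expression matrix from [normalize_cq()] (log2 scale,
#'   defined as minus delta-Ct).
#' @return `2^expr`, elementwise.
#' @export
relative_expression <- function(expr) {
  if (any(!is.finite(expr))) stop("expr must be finite")
  2^expr
}
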