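#' Quintile assignment from control-derived thresholds
#'
#' Computes the 20/40/60/80 empirical percentiles of the CONTROL scores
#' (linear interpolation of order statistics, the default sample
#' quantile) and bins every sample (cases and controls) into the
#' half-open intervals (-Inf, q20], (q20, q40], (q40, q60], (q60, q80],
#' (q80, Inf): right-closed, so a score exactly at a threshold falls in
#' the lower bin.
#'
#' @param scores Numeric scores, one per sample.
#' @param labels Case indicator (see [fit_mir_score()]).
#' @param quantile_type Sample-quantile rule passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return List of class `quintile_assignment`: `thresholds` (q20, q40,
#'   q60, q80), `quintile` (factor Q1..Q5 per sample), `intervals`
#'   (printable bin notation).
#' @export
control_quintiles <- function(scores, labels, quantile_type = 7) {
  y <- as_case_indicator(labels)
  stopifnot(length(scores) == length(y))
  ctrl <- scores[y == 0]
  if (length(unique(ctrl)) < 5)
    stop("need at least 5 distinct control scores")
  thr <- stats::quantile(ctrl, c(0.2, 0.4, 0.6, 0.8), names = FALSE,
                         type = quantile_type)
  if (any(duplicated(thr)))
    stop("degenerate quintile bins: duplicated control thresholds (",
         paste(format(thr), collapse = ", "), ")")
  q <- cut(scores, breaks = c(-Inf, thr, Inf),
           labels = paste0("Q", 1:5), right = TRUE)
  intervals <- c(sprintf("(<%s]", format(thr[1], digits = 3)),
                 sprintf("(%s, %s]", format(thr[1:3], digits = 3),
                         format(thr[2:4], digits = 3)),
                 sprintf("(>%s)", format(thr[4], digits = 3)))
  structure(list(thresholds = stats::setNames(thr, c("q20", "q40", "q60",
                                                     "q80")),
                 quintile = q, intervals = intervals),
            class = "quintile_assignment")
}

#' Quintile-stratified odds ratios from logistic regression
#'
#' Logistic regression of case status on the quintile indicator with the
#' middle quintile (Q3) as reference; optionally adjusted for age
#' (continuous) and sex. Wald 95% CIs, `exp(b +/- 1.96 se)`, and
#' two-sided Wald p-values.
#'
#' @param assignment A [control_quintiles()] result.
#' @param labels Case indicator.
#' @param covariates Data frame with `age` and `sex` columns (required
#'   for the adjusted model).
#' @param adjusted `"none"` (model 1) or `"age_sex"` (model 2).
#' @return Data frame: quintile, cases, controls, or, ci_low, ci_high,
#'   p, model. The reference row has OR 1 and NA CI/p.
#' @export
quintile_or <- function(assignment, labels, covariates = NULL,
                        adjusted = c("none", "age_sex")) {
  adjusted <- match.arg(adjusted)
  stopifnot(inherits(assignment, "quintile_assignment"))
  y <- as_case_indicator(labels)
  q <- stats::relevel(assignment$quintile, ref = "Q3")
  tab <- table(assignment$quintile, factor(y, levels = 0:1))
  if (any(tab[, "1"] == 0 | tab[, "0"] == 0)) {
    bad <- rownames(tab)[tab[, "1"] == 0 | tab[, "0"] == 0]
    stop("empty quintile cell (infinite estimate) in: ",
         paste(bad, collapse = ", "), "; cell counts: ",
         paste(apply(tab, 1, paste, collapse = "/"), collapse = " "))
  }
  df <- data.frame(.y = y, .q = q)
  form <- .y ~ .q
  if (adjusted == "age_sex") {
    stopifnot(!is.null(covariates), all(c("age", "sex") %in%
                                        names(covariates)))
    df$age <- covariates$age
    df$sex <- covariates$sex
    form <- .y ~ .q + age + sex
  }
  fit <- stats::glm(form, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  cf <- summary(fit)$coefficients
  out <- data.frame(quintile = paste0("Q", 1:5),
                    cases = as.integer(tab[, "1"]),
                    controls = as.integer(tab[, "0"]),
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_,
                    model = if (adjusted == "none") "model1" else "model2",
                    stringsAsFactors = FALSE)
  for (qq in c("Q1", "Q2", "Q4", "Q5")) {
    row <- paste0(".q", qq)
    b <- cf[row, "Estimate"]; se <- cf[row, "Std. Error"]
    i <- match(qq, out$quintile)
    out$or[i] <- exp(b)
    out$ci_low[i] <- exp(b - 1.96 * se)
    out$ci_high[i] <- exp(b + 1.96 * se)
    out$p[i] <- cf[row, "Pr(>|z|)"]
  }
  out$or[out$quintile == "Q3"] <- 1
  out
}

#' Odds ratio and Wald CI from a 2x2 table
#'
#' Closed form for the contrast of an exposed bin against a reference
#' bin: `OR = (a d)/(b c)` with Wald 95% CI
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Equals the
#' unadjusted logistic-regression estimate for a binary contrast.
#'
#' @param a,b Cases and controls in the exposed bin.
#' @param c,d Cases and controls in the reference bin.
#' @param correction Add 0.5 to every cell (required if any cell is 0).
#' @return List: `or`, `ci_low`, `ci_high`.
#' @examples
#' or_from_2x2(126, 35, 17, 34)  # OR 7.20, CI 3.60-14.39
#' @export
or_from_2x2 <- function(a, b, c, d, correction = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0) && !correction)
    stop("zero cell; use correction = TRUE for the +0.5 adjustment")
  if (correction) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = exp(lor), ci_low = exp(lor - 1.96 * se),
       ci_high = exp(lor + 1.96 * se))
}

#' Area under the ROC curve with DeLong CI
#'
#' AUC computed from the Mann-Whitney U statistic via mid-ranks (ties
#' count one half); the 95% CI uses the DeLong variance method.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case indicator.
#' @param ci Compute the DeLong CI (default TRUE).
#' @return List of class `auc_result`: `auc`, `ci_low`, `ci_high`, `n_case`,
#'   `n_control`.
#' @export
auc <- function(scores, labels, ci = TRUE) {
  y <- as_case_indicator(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  a <- auc_value(scores, y)
  ci_lh <- c(NA_real_, NA_real_)
  if (ci && stats::sd(scores) > 0) {
    r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    ci_lh <- tryCatch(
      suppressWarnings(
        as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
      error = function(e) c(NA_real_, NA_real_))
  }
  structure(list(auc = a, ci_low = ci_lh[1], ci_high = ci_lh[2],
                 n_case = n1, n_control = n0), class = "auc_result")
}

# rank/U-statistic AUC; ties get half credit
auc_value <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_case, x$n_control))
  invisible(x)
}

#' Brier score
#'
#' Mean squared difference between predicted event probability and the
#' binary outcome.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Case indicator.
#' @return Scalar Brier score in `[0, 1]`.
#' @export
brier <- function(probabilities, labels) {
  y <- as_case_indicator(labels)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  mean((probabilities - y)^2)
}

#' Default refittable model: unpenalised logistic regression
#'
#' Model specification for [bootstrap_632plus()]: fits a logistic model
#' on the feature columns and returns a prediction closure.
#'
#' @param x Feature matrix. @param y 0/1 outcome.
#' @return `function(newx)` returning predicted probabilities.
#' @export
logistic_model_spec <- function(x, y) {
  x <- as.matrix(x)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  beta <- fit$coefficients
  function(newx) {
    newx <- as.matrix(newx)
    drop(stats::plogis(cbind(1, newx) %*% beta))
  }
}

#' Optimism-corrected performance by the .632+ bootstrap
#'
#' Estimates out-of-sample performance of a refittable model by the
#' .632+ rule: the apparent loss err_app (fit and evaluate on the full
#' data) is blended with the leave-one-out bootstrap loss err1 using the
#' relative-overfitting weight. For the Brier loss, each sample's
#' squared error is averaged over the resamples excluding it and then
#' across samples; for AUC (a rank statistic with no per-sample loss),
#' the out-of-bag AUC of each replicate is computed on its full
#' out-of-bag set and averaged. The no-information rate gamma is 0.5 for
#' AUC loss and the all-pairs mean squared error for Brier. Then
#' `R = clip((err1 - err_app) / (gamma - err_app), 0, 1)`,
#' `w = .632 / (1 - .368 R)`, and
#' `corrected = (1 - w) err_app + w min(err1, gamma)`.
#' AUC results are reported as `1 - loss`.
#'
#' @param features Samples x predictors matrix/data.frame.
#' @param labels Case indicator.
#' @param model_spec `function(x, y)` returning a `function(newx)` of
#'   predicted probabilities; refit inside every resample (default
#'   [logistic_model_spec()]).
#' @param B Bootstrap replicates (default 1000; below 50 warns).
#' @param seed Integer seed (resampling is fully reproducible).
#' @param loss `"auc"` or `"brier"`.
#' @param stratified Resample within case/control strata (default FALSE,
#'   simple resampling with replacement of n samples).
#' @return List of class `eval_report`: `loss`, `apparent` (AUC or Brier
#'   on the full-data fit; for AUC with DeLong CI), `corrected`
#'   (optimism-corrected value on the same scale), `err_app`, `err1`,
#'   `gamma`, `R`, `w`, `B`, `B_used`, `skipped`, `seed`.
#' @export
bootstrap_632plus <- function(features, labels,
                              model_spec = logistic_model_spec,
                              B = 1000, seed = 1,
                              loss = c("auc", "brier"),
                              stratified = FALSE) {
  loss <- match.arg(loss)
  features <- as.matrix(features)
  y <- as_case_indicator(labels)
  n <- nrow(features)
  stopifnot(length(y) == n)
  if (B < 50) warning("B < 50 gives unstable .632+ estimates")
  set.seed(seed)

  predict_full <- model_spec(features, y)
  p0 <- predict_full(features)
  app_auc <- if (loss == "auc") auc(p0, y) else NULL
  err_app <- if (loss == "auc") 1 - app_auc$auc else brier(p0, y)
  gamma <- if (loss == "auc") 0.5
           else mean(vapply(p0, function(p)
             mean(y) * (p - 1)^2 + (1 - mean(y)) * p^2, numeric(1)))

  skipped <- 0L
  oob_auc_loss <- numeric(0)
  sq_sum <- numeric(n); sq_cnt <- integer(n)
  for (b in seq_len(B)) {
    idx <- if (stratified)
      c(sample(which(y == 1), sum(y == 1), replace = TRUE),
        sample(which(y == 0), sum(y == 0), replace = TRUE))
    else sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(unique(y[idx])) < 2 || !length(oob) ||
        (loss == "auc" && length(unique(y[oob])) < 2)) {
      skipped <- skipped + 1L
      next
    }
    pred <- model_spec(features[idx, , drop = FALSE], y[idx])
    p_oob <- pred(features[oob, , drop = FALSE])
    if (loss == "auc") {
      oob_auc_loss <- c(oob_auc_loss, 1 - auc_value(p_oob, y[oob]))
    } else {
      sq_sum[oob] <- sq_sum[oob] + (p_oob - y[oob])^2
      sq_cnt[oob] <- sq_cnt[oob] + 1L
    }
  }
  if (skipped > 0.1 * B)
    stop("more than 10% of bootstrap resamples skipped (single-class ",
         "resamples); check class balance or use stratified = TRUE")
  err1 <- if (loss == "auc") mean(oob_auc_loss)
          else mean(sq_sum[sq_cnt > 0] / sq_cnt[sq_cnt > 0])
  R <- if (!is.finite(err1) || gamma <= err_app) 0
       else min(1, max(0, (err1 - err_app) / (gamma - err_app)))
  w <- 0.632 / (1 - 0.368 * R)
  corrected_loss <- (1 - w) * err_app + w * min(err1, gamma)
  structure(list(
    loss = loss,
    apparent = if (loss == "auc") app_auc else err_app,
    corrected = if (loss == "auc") 1 - corrected_loss else corrected_loss,
    err_app = err_app, err1 = err1, gamma = gamma, R = R, w = w,
    B = B, B_used = B - skipped, skipped = skipped, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$loss == "auc") {
    cat(sprintf("AUC  apparent %.3f (%.3f-%.3f)   .632+ %.3f   [B=%d, seed=%d]\n",
                x$apparent$auc, x$apparent$ci_low, x$apparent$ci_high,
                x$corrected, x$B, x$seed))
  } else {
    cat(sprintf("Brier  apparent %.3f   .632+ %.3f   [B=%d, seed=%d]\n",
                x$apparent, x$corrected, x$B, x$seed))
  }
  invisible(x)
}

#' Restrict cases to a follow-up window
#'
#' Retains cases whose time to diagnosis t satisfies
#' `t_min < t <= t_max` (years), and all controls.
#'
#' @param samples Data frame with `status` and `time_to_dx_years`
#'   (present for every case).
#' @param window Numeric length-2: `c(t_min, t_max)`; `t_max` may be Inf.
#' @return The filtered data frame.
#' @export
followup_subgroup <- function(samples, window) {
  stopifnot(all(c("status", "time_to_dx_years") %in% names(samples)))
  if (window[1] >= window[2]) stop("inverted follow-up window")
  is_case <- as_case_indicator(samples$status) == 1
  if (any(is_case & is.na(samples$time_to_dx_years)))
    stop("time to diagnosis missing for some cases")
  t <- samples$time_to_dx_years
  keep <- !is_case | (t > window[1] & t <= window[2])
  samples[keep, , drop = FALSE]
}

#' Per-miRNA deregulation statistics
#'
#' For each informative miRNA: the linear-scale fold change (mean
#' case relative expression over mean control relative expression,
#' with relative expression `2^expr`), the two-sided Mann-Whitney
#' p-value (exact when both groups have at most 25 samples and there
#' are no ties, normal approximation otherwise), the Holm-corrected
#' p-value across the panel, and the direction of deregulation.
#'
#' @param expr Samples x miRNAs normalized expression matrix.
#' @param labels Case indicator.
#' @param exact_max_n Per-group size limit for the exact test (default 25).
#' @return Data frame: mirna, fold_change, p, p_corrected, direction.
#' @export
deregulation_table <- function(expr, labels, exact_max_n = 25) {
  expr <- as.matrix(expr)
  y <- as_case_indicator(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) stop("both groups need at least 2 samples")
  rows <- lapply(seq_len(ncol(expr)), function(j) {
    v <- expr[, j]
    if (stats::sd(v) == 0)
      stop("degenerate all-equal expression for ",
           colnames(expr)[j] %||% j)
    rel <- 2^v
    fc <- mean(rel[y == 1]) / mean(rel[y == 0])
    use_exact <- n1 <= exact_max_n && n0 <= exact_max_n &&
      !any(duplicated(v))
    p <- suppressWarnings(
      stats::wilcox.test(v[y == 1], v[y == 0], exact = use_exact,
                         correct = !use_exact)$p.value)
    data.frame(mirna = colnames(expr)[j] %||% paste0("m", j),
               fold_change = fc, p = p,
               direction = if (fc >= 1) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- holm_correction(out$p)
  out[, c("mirna", "fold_change", "p", "p_corrected", "direction")]
}

#' Bonferroni-Holm step-down correction
#'
#' Step-down familywise-error control: the i-th smallest p multiplied by
#' (m - i + 1), with cumulative-maximum monotonicity and capping at 1.
#' Implemented via [stats::p.adjust()].
#'
#' @param pvals Raw p-values in `[0, 1]`; NaN is an error.
#' @return Corrected values.
#' @export
holm_correction <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-value")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Pairwise Spearman rank-correlation matrix
#'
#' Symmetric matrix of Spearman correlations (average-rank tie
#' handling) with unit diagonal. Constant columns yield NA entries and
#' are flagged in the `"undefined"` attribute rather than silently set
#' to zero.
#'
#' @param expr Samples x miRNAs matrix with at least 3 rows.
#' @return Correlation matrix with attribute `undefined` (names of
#'   constant columns, if any).
#' @export
spearman_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop("need at least 3 samples")
  const <- colnames(expr)[apply(expr, 2, stats::sd) == 0]
  m <- suppressWarnings(stats::cor(expr, method = "spearman"))
  diag(m) <- 1
  if (length(const))
    warning("constant column(s) give undefined correlations: ",
            paste(const, collapse = ", "))
  attr(m, "undefined") <- const
  m
}
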