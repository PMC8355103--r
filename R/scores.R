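#' Construct a linear risk-score model
#'
#' A `score_model` is an intercept plus named coefficients: the linear
#' predictor (log-odds scale) of a logistic model, usable for the
#' miR-score, score combinations, or any weighted predictor panel.
#'
#' @param intercept Intercept (log-odds).
#' @param coefficients Named numeric vector of predictor weights.
#' @param metadata Optional list (fit size, convergence, log-likelihood,
#'   standard errors, ...).
#' @return An object of class `score_model`.
#' @export
score_model <- function(intercept, coefficients, metadata = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (anyDuplicated(names(coefficients)))
    stop("predictor names must be unique")
  if (any(!is.finite(c(intercept, coefficients))))
    stop("weights must be finite")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients, metadata = metadata),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("Linear risk-score model (log-odds)\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-12s %+.4f\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

#' Load the frozen published 7-miRNA score model
#'
#' Reads the versioned JSON artifact shipped with the package: the
#' published serum miRNA panel's logistic linear predictor (intercept
#' 0.1899 and seven coefficients), applied to normalized expression
#' values under this package's sign convention (mean normalizer Cq minus
#' target Cq).
#'
#' @param path Path to the model JSON (default: the shipped artifact).
#' @return A [score_model()].
#' @export
load_mir_score_model <- function(path = system.file("extdata",
                                                    "mir_score_model.json",
                                                    package = "mirisk")) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_model(j$intercept, unlist(j$coefficients),
              metadata = j[setdiff(names(j), c("intercept", "coefficients"))])
}

#' Fit a logistic miRNA-panel risk score
#'
#' Unpenalised maximum-likelihood logistic regression of case status on
#' the normalized expression panel. Convergence uses a relative
#' log-likelihood change below 1e-10 with at most 100 iterations.
#' Complete or quasi-complete separation (diverging weights) is raised
#' as an error advising penalisation.
#'
#' @param expr Samples x miRNAs expression matrix (no missing values).
#' @param labels Case indicator: logical, 0/1, or `"case"`/`"control"`.
#' @return A [score_model()] with metadata `n`, `converged`, `logLik`,
#'   `se` (standard errors) and `fitted` (training linear predictors).
#' @export
fit_mir_score <- function(expr, labels) {
  expr <- as.matrix(expr)
  y <- as_case_indicator(labels)
  stopifnot(nrow(expr) == length(y))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (min(table(y)) < 10)
    stop("need at least 10 samples per class")
  df <- data.frame(.y = y, expr, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn && max(abs(stats::coef(fit))) > 10)
    stop("complete or quasi-complete separation detected (diverging ",
         "weights); consider a penalised fit")
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  names(se) <- c("(Intercept)", colnames(expr))  # undo backtick mangling
  score_model(cf[1], stats::setNames(cf[-1], colnames(expr)),
              metadata = list(n = nrow(expr), converged = fit$converged,
                              logLik = as.numeric(stats::logLik(fit)),
                              se = se,
                              fitted = unname(fit$linear.predictors)))
}

#' Evaluate a score model as a linear predictor
#'
#' Returns `intercept + sum(coef * expr)` per sample, on the log-odds
#' scale (no link transform: the score IS the linear predictor).
#'
#' @param model A [score_model()].
#' @param expr Samples x predictors matrix or data.frame containing
#'   every model predictor as a column (extra columns ignored).
#' @return Named numeric vector of scores.
#' @examples
#' m <- load_mir_score_model()
#' zero <- matrix(0, 1, 7, dimnames = list("s1", names(m$coefficients)))
#' apply_mir_score(m, zero)  # the published intercept, 0.1899
#' @export
apply_mir_score <- function(model, expr) {
  stopifnot(inherits(model, "score_model"))
  expr <- as.matrix(expr)
  missing_cols <- setdiff(names(model$coefficients), colnames(expr))
  if (length(missing_cols))
    stop("missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  drop(model$intercept +
         expr[, names(model$coefficients), drop = FALSE] %*%
         model$coefficients)
}

#' Environmental risk score (point-based)
#'
#' Integer points summed over five risk factors: age (0 for <55, 1 for
#' 55 to <60, 2 for 60 to <65, 3 for 65 to <70, 4 for >=70 years), sex
#' (1 for male, 0 for female), first-degree relative with CRC (1 for
#' >=1 relative), body mass index (0 for <25, 1 for 25 to <30, 2 for
#' >=30 kg/m^2), and cigarette smoking (0 for 0 pack-years, 2 for >0 to
#' <30, 4 for >=30 pack-years). Range 0-12.
#'
#' @param x Data frame with columns `age`, `sex` (`"M"`/`"F"`),
#'   `family_history` (0/1), `bmi`, `pack_years`. No missing values:
#'   impute first with [impute_ers_missing()].
#' @return Integer vector of scores.
#' @export
compute_ers <- function(x) {
  req <- c("age", "sex", "family_history", "bmi", "pack_years")
  stopifnot(all(req %in% names(x)))
  if (anyNA(x[req]))
    stop("missing values in ERS inputs; impute first ",
         "(see impute_ers_missing)")
  stopifnot(all(x$age > 0), all(x$bmi > 0), all(x$pack_years >= 0),
            all(x$sex %in% c("M", "F")), all(x$family_history %in% 0:1))
  age_pts <- findInterval(x$age, c(55, 60, 65, 70))
  bmi_pts <- findInterval(x$bmi, c(25, 30))
  smoke_pts <- ifelse(x$pack_years == 0, 0L,
                      ifelse(x$pack_years < 30, 2L, 4L))
  as.integer(age_pts + (x$sex == "M") + (x$family_history >= 1) +
               bmi_pts + smoke_pts)
}

#' Chained-equation imputation of ERS covariates
#'
#' Fills missing `family_history` (binary; logistic conditional model)
#' and `pack_years` (non-negative continuous; linear conditional model)
#' by cycling the two conditional models for a fixed number of
#' iterations, drawing each missing value from the fitted predictive
#' distribution (Bernoulli for the binary variable; a normal draw
#' truncated at zero for pack-years). `age`, `sex` and `bmi` must be
#' complete. Fully seed-reproducible.
#'
#' @param x Data frame with `age`, `sex`, `family_history`, `bmi`,
#'   `pack_years` (missing allowed only in the last-named two).
#' @param m Number of imputed datasets (default 1).
#' @param iterations Chained-equation cycles per dataset (default 10).
#' @param seed Integer seed.
#' @return A list of `m` completed data frames; element 1 is the default
#'   analysis dataset.
#' @export
impute_ers_missing <- function(x, m = 1, iterations = 10, seed = 1) {
  req <- c("age", "sex", "family_history", "bmi", "pack_years")
  stopifnot(all(req %in% names(x)))
  if (anyNA(x[c("age", "sex", "bmi")]))
    stop("age, sex and bmi must be complete")
  for (v in c("family_history", "pack_years"))
    if (all(is.na(x[[v]]))) stop(v, " is 100% missing; cannot impute")
  miss_fh <- is.na(x$family_history)
  miss_py <- is.na(x$pack_years)
  if (!any(miss_fh) && !any(miss_py)) return(replicate(m, x, simplify = FALSE))
  set.seed(seed)
  male <- as.numeric(x$sex == "M")
  lapply(seq_len(m), function(chain) {
    d <- x
    # initialise by sampling observed values
    if (any(miss_fh))
      d$family_history[miss_fh] <- sample(x$family_history[!miss_fh],
                                          sum(miss_fh), replace = TRUE)
    if (any(miss_py))
      d$pack_years[miss_py] <- sample(x$pack_years[!miss_py],
                                      sum(miss_py), replace = TRUE)
    for (it in seq_len(iterations)) {
      if (any(miss_fh)) {
        fit <- suppressWarnings(
          stats::glm(x$family_history[!miss_fh] ~ d$age[!miss_fh] +
                       male[!miss_fh] + d$bmi[!miss_fh] +
                       d$pack_years[!miss_fh],
                     family = stats::binomial()))
        eta <- cbind(1, d$age, male, d$bmi, d$pack_years)[miss_fh, ,
                                                          drop = FALSE] %*%
          stats::coef(fit)
        d$family_history[miss_fh] <- stats::rbinom(sum(miss_fh), 1L,
                                                   stats::plogis(drop(eta)))
      }
      if (any(miss_py)) {
        fit <- stats::lm(x$pack_years[!miss_py] ~ d$age[!miss_py] +
                           male[!miss_py] + d$bmi[!miss_py] +
                           d$family_history[!miss_py])
        mu <- cbind(1, d$age, male, d$bmi,
                    d$family_history)[miss_py, , drop = FALSE] %*%
          stats::coef(fit)
        sigma <- summary(fit)$sigma
        d$pack_years[miss_py] <- pmax(0, stats::rnorm(sum(miss_py),
                                                      drop(mu), sigma))
      }
    }
    d
  })
}

#' Polygenic risk score as a weighted allele sum
#'
#' @param dosages Samples x SNPs matrix of allele dosages in `[0, 2]`.
#' @param weights Named numeric vector (or data.frame with `snp_id`,
#'   `weight`) of per-SNP log-odds weights; ids must match the dosage
#'   columns exactly.
#' @return Named numeric vector: `sum(weight * dosage)` per sample.
#' @export
compute_prs <- function(dosages, weights) {
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$weight, weights$snp_id)
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)) || is.null(names(weights)))
    stop("dosage columns and weights must be named by SNP id")
  if (!setequal(colnames(dosages), names(weights)))
    stop("SNP id mismatch between dosages and weights")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (anyNA(dosages) || any(dosages < 0 | dosages > 2))
    stop("dosages must lie in [0, 2]")
  drop(dosages[, names(weights), drop = FALSE] %*% weights)
}

#' Combine component risk scores by logistic refit
#'
#' Fits a logistic regression of case status on the component scores
#' (miR-score, ERS, PRS, ...) and returns the combined model; its linear
#' predictor is the combined score. Collinear components are rejected.
#'
#' @param scores Samples x components matrix or data.frame of scores.
#' @param labels Case indicator (as in [fit_mir_score()]).
#' @param kappa_max Condition-number guard on the standardised design
#'   (default 1e8).
#' @return A [score_model()] over the components, with metadata `fitted`
#'   holding the combined linear predictor for the training samples.
#' @export
combine_scores <- function(scores, labels, kappa_max = 1e8) {
  scores <- as.matrix(scores)
  y <- as_case_indicator(labels)
  stopifnot(nrow(scores) == length(y))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("score", seq_len(ncol(scores)))
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0)) stop("constant score component: ",
                          paste(colnames(scores)[sds == 0], collapse = ", "))
  std <- scale(scores)
  if (ncol(scores) > 1 && kappa(crossprod(std), exact = TRUE) > kappa_max)
    stop("collinear score components (condition number guard)")
  df <- data.frame(.y = y, scores, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  cf <- stats::coef(fit)
  score_model(cf[1], stats::setNames(cf[-1], colnames(scores)),
              metadata = list(n = nrow(scores),
                              converged = fit$converged,
                              logLik = as.numeric(stats::logLik(fit)),
                              fitted = unname(fit$linear.predictors)))
}

#' Normalise a case/control label vector to a 0/1 indicator
#' @keywords internal
as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% 0:1)) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  l <- tolower(as.character(labels))
  if (!all(l %in% c("case", "control")))
    stop("labels must be logical, 0/1, or 'case'/'control'")
  as.integer(l == "case")
}
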