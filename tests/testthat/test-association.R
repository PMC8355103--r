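test_that("control quintile thresholds and half-open binning", {
  scores <- c(1:10, 8.5, 2.8)           # 10 controls, 2 cases
  labels <- c(rep("control", 10), "case", "case")
  qa <- control_quintiles(scores, labels)
  # type-7 percentiles of 1..10
  expect_equal(unname(qa$thresholds),
               unname(quantile(1:10, c(.2, .4, .6, .8))))
  expect_equal(as.character(qa$quintile[11]), "Q5")  # 8.5 > q80 = 8.2
  # a score exactly at q40 falls in Q2 (right-closed)
  expect_equal(unname(qa$thresholds["q20"]), 2.8)
  expect_equal(as.character(qa$quintile[12]), "Q1")

  # n divisible by 5, all distinct: 20% of controls per bin
  set.seed(4)
  ctrl <- rnorm(100)
  qa2 <- control_quintiles(ctrl, rep("control", 100))
  expect_true(all(table(qa2$quintile) == 20))

  expect_error(control_quintiles(rep(1, 10), rep("control", 10)),
               "distinct")
})

test_that("quintile odds ratios equal the closed-form 2x2 estimate", {
  set.seed(12)
  n <- 600
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * score))
  qa <- control_quintiles(score, y)
  or1 <- quintile_or(qa, y)
  for (qq in c("Q1", "Q2", "Q4", "Q5")) {
    i <- match(qq, or1$quintile)
    ref <- match("Q3", or1$quintile)
    cf <- or_from_2x2(or1$cases[i], or1$controls[i],
                      or1$cases[ref], or1$controls[ref])
    expect_equal(or1$or[i], cf$or, tolerance = 1e-8)
    expect_equal(or1$ci_low[i], cf$ci_low, tolerance = 1e-6)
    expect_equal(or1$ci_high[i], cf$ci_high, tolerance = 1e-6)
  }
  expect_equal(or1$or[or1$quintile == "Q3"], 1)
  # adjusted model runs and keeps the reference at 1
  cov <- data.frame(age = rnorm(n, 65, 7),
                    sex = sample(c("M", "F"), n, TRUE))
  or2 <- quintile_or(qa, y, covariates = cov, adjusted = "age_sex")
  expect_equal(or2$or[or2$quintile == "Q3"], 1)
  expect_true(all(or2$ci_low <= or2$or & or2$or <= or2$ci_high,
                  na.rm = TRUE))
})

test_that("equal case/control composition in two bins gives OR 1", {
  r <- or_from_2x2(1, 1, 1, 1)
  expect_equal(r$or, 1.0)
  r2 <- or_from_2x2(20, 10, 40, 20)
  expect_equal(r2$or, 1.0)
  expect_error(or_from_2x2(0, 5, 5, 5), "zero cell")
  expect_silent(or_from_2x2(0, 5, 5, 5, correction = TRUE))
})

test_that("AUC equals exhaustive pair counting on small datasets", {
  # perfect separation and all-ties limits
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1.0)
  expect_equal(auc(rep(5, 8), rep(0:1, each = 4), ci = FALSE)$auc, 0.5)

  set.seed(8)
  for (r in 1:60) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:6, n, replace = TRUE)   # induces ties
    expect_equal(auc(s, y, ci = FALSE)$auc, oracle_auc_pairs(s, y))
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC point estimate and DeLong CI agree with pROC", {
  set.seed(10)
  s <- rnorm(80)
  y <- rbinom(80, 1, plogis(s))
  a <- auc(s, y)
  r <- pROC::roc(y, s, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(a$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(c(a$ci_low, a$ci_high), ci[c(1, 3)], tolerance = 1e-12)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 10), rep(0:1, 5)), 0.25)
  expect_equal(brier(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_error(brier(c(0.5, 1.2), c(1, 0)), "\\[0, 1\\]")
})

test_that(".632+ bootstrap removes optimism on null data and is reproducible", {
  set.seed(1)
  n <- 200
  x <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("m", 1:7)))
  y <- sample(rep(0:1, each = n / 2))   # permuted labels: null association
  r1 <- bootstrap_632plus(x, y, B = 150, seed = 5)
  r2 <- bootstrap_632plus(x, y, B = 150, seed = 5)
  expect_identical(r1[c("corrected", "err1", "R", "w")],
                   r2[c("corrected", "err1", "R", "w")])
  expect_gt(r1$apparent$auc, 0.5)          # apparent overfits
  expect_lt(abs(r1$corrected - 0.5), 0.05) # corrected does not
  # corrected loss is a convex combination of err_app and min(err1, gamma)
  lo <- min(r1$err_app, min(r1$err1, r1$gamma))
  hi <- max(r1$err_app, min(r1$err1, r1$gamma))
  expect_gte(1 - r1$corrected, lo - 1e-12)
  expect_lte(1 - r1$corrected, hi + 1e-12)
})

test_that(".632+ correction is small for strongly separable data", {
  set.seed(32)
  n <- 500
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(4 * x[, "a"]))
  r <- bootstrap_632plus(x, y, B = 120, seed = 9)
  expect_lt(abs(r$corrected - r$apparent$auc), 0.02)
  expect_warning(bootstrap_632plus(x[1:100, ], y[1:100], B = 40, seed = 1),
                 "B < 50")
})

test_that(".632+ Brier loss uses per-sample out-of-bag averaging", {
  set.seed(33)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("m", 1:3)))
  y <- rbinom(n, 1, plogis(x[, 1]))
  r <- bootstrap_632plus(x, y, B = 150, seed = 2, loss = "brier")
  expect_gte(r$corrected, r$err_app)  # optimism correction inflates loss
  expect_lte(r$corrected, 0.3)
  expect_true(is.finite(r$gamma) && r$gamma > r$err_app)
})

test_that("follow-up windows filter cases only and partition", {
  samples <- data.frame(
    sample_id = paste0("S", 1:6),
    status = c("case", "case", "case", "control", "control", "case"),
    time_to_dx_years = c(1.0, 5.0, 3.0, NA, NA, 14.0))
  full <- followup_subgroup(samples, c(0, Inf))
  expect_identical(full, samples)
  early <- followup_subgroup(samples, c(0, 3))
  expect_setequal(early$sample_id, c("S1", "S3", "S4", "S5"))  # 3.0 <= 3
  late <- followup_subgroup(samples, c(3, Inf))
  # partition: every case in exactly one window, controls in both
  cases <- samples$sample_id[samples$status == "case"]
  expect_setequal(c(intersect(early$sample_id, cases),
                    intersect(late$sample_id, cases)), cases)
  expect_length(intersect(intersect(early$sample_id, cases),
                          intersect(late$sample_id, cases)), 0)
  expect_error(followup_subgroup(samples, c(3, 1)), "inverted")
})

test_that("deregulation table: fold changes, exact Mann-Whitney, Holm", {
  # identical groups: fold change 1, p 1
  e <- cbind(m1 = c(1, 2, 3, 1, 2, 3))
  y <- rep(c("case", "control"), each = 3)
  d <- deregulation_table(e, y)
  expect_equal(d$fold_change, 1.0)
  expect_equal(d$p, 1.0)

  # 3-vs-3 exact p equals full 20-arrangement enumeration
  set.seed(14)
  for (r in 1:10) {
    v <- sample(seq(0.1, 9.9, by = 0.37), 6)
    e2 <- cbind(m = v)
    d2 <- deregulation_table(e2, y)
    expect_equal(d2$p, oracle_mw_exact(v[1:3], v[4:6]), tolerance = 1e-12)
  }

  # direction is consistent with the fold change
  set.seed(15)
  e3 <- cbind(up = c(rnorm(20, 2), rnorm(20, 0)),
              down = c(rnorm(20, -2), rnorm(20, 0)))
  d3 <- deregulation_table(e3, rep(c("case", "control"), each = 20))
  expect_equal(d3$direction, c("up", "down"))
  expect_true(all(d3$p_corrected >= d3$p))
  expect_error(deregulation_table(cbind(m = rep(1, 6)), y), "degenerate")
})

test_that("Holm correction reproduces the published seven-miRNA panel column", {
  raw <- c(5.04e-06, 2.01e-14, 1.26e-05, 2.72e-02, 7.88e-08, 2.94e-10,
           3.74e-05)
  printed <- c(2.02e-05, 1.41e-13, 3.77e-05, 2.72e-02, 3.94e-07, 1.76e-09,
               7.48e-05)
  # printed values carry rounded raw inputs; compare at printed precision
  expect_equal(holm_correction(raw), printed, tolerance = 5e-3)
  expect_equal(holm_correction(0.02), 0.02)
  expect_equal(holm_correction(c(0.04, 0.04)), c(0.08, 0.08))
  # order preservation and permutation invariance
  set.seed(16)
  p <- runif(30)
  h <- holm_correction(p)
  expect_true(all(diff(h[order(p)]) >= -1e-12))
  perm <- sample(30)
  expect_equal(holm_correction(p[perm]), h[perm])
  expect_error(holm_correction(c(0.1, NaN)), "NaN")
})

test_that("Spearman matrix handles ties and flags constant columns", {
  x <- 1:10
  m <- cbind(x = x, inc = x^3, dec = -x + 0.5)
  r <- spearman_matrix(m)
  expect_equal(unname(r["x", "inc"]), 1.0)
  expect_equal(unname(r["x", "dec"]), -1.0)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  # one tie: equals Pearson of average ranks
  v1 <- c(1, 2, 2, 4, 5); v2 <- c(2, 1, 4, 3, 5)
  r2 <- spearman_matrix(cbind(a = v1, b = v2))
  expect_equal(unname(r2["a", "b"]), cor(rank(v1), rank(v2)),
               tolerance = 1e-12)

  expect_warning(r3 <- spearman_matrix(cbind(a = 1:5, k = rep(2, 5))),
                 "constant")
  expect_true(is.na(r3["a", "k"]))
  expect_equal(attr(r3, "undefined"), "k")
})
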