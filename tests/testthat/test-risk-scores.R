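frozen_model <- load_mir_score_model()

test_that("the frozen published model evaluates exactly", {
  nm <- names(frozen_model$coefficients)
  zero <- matrix(0, 1, 7, dimnames = list("s", nm))
  expect_identical(unname(apply_mir_score(frozen_model, zero)), 0.1899)
  ones <- zero + 1
  expect_equal(unname(apply_mir_score(frozen_model, ones)), 0.9859,
               tolerance = 1e-12)
  # linearity: doubling one expression moves the score by its coefficient
  x <- ones; x[, "miR-23a-3p"] <- 2
  expect_equal(unname(apply_mir_score(frozen_model, x)) -
                 unname(apply_mir_score(frozen_model, ones)),
               unname(frozen_model$coefficients["miR-23a-3p"]),
               tolerance = 1e-12)
  expect_error(apply_mir_score(frozen_model, zero[, -3, drop = FALSE]),
               "miR-23a-3p")
})

test_that("logistic panel fit recovers generating coefficients within 3 SE", {
  set.seed(41)
  n <- 5000
  nm <- names(frozen_model$coefficients)
  x <- matrix(rnorm(n * 7, 0, 1), n, 7, dimnames = list(NULL, nm))
  eta <- apply_mir_score(frozen_model, x)
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_mir_score(x, y)
  se <- fit$metadata$se
  expect_lt(abs(fit$intercept - frozen_model$intercept), 3 * se[1])
  for (k in nm)
    expect_lt(abs(fit$coefficients[[k]] - frozen_model$coefficients[[k]]),
              3 * se[[k]])
  # stored linear predictors reproduce apply_mir_score on training data
  expect_equal(unname(apply_mir_score(fit, x)), fit$metadata$fitted,
               tolerance = 1e-10)
})

test_that("a label-independent predictor gets a near-zero coefficient", {
  set.seed(7)
  n <- 400
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * x[, "signal"]))
  fit <- fit_mir_score(x, y)
  expect_lt(abs(fit$coefficients[["noise"]]),
            3 * fit$metadata$se[["noise"]])
})

test_that("separation and tiny classes are rejected", {
  x <- matrix(c(seq(-2, -0.1, length.out = 12),
                seq(0.1, 2, length.out = 12)), ncol = 1,
              dimnames = list(NULL, "m"))
  y <- rep(0:1, each = 12)
  expect_error(fit_mir_score(x, y), "separation")
  expect_error(fit_mir_score(x[1:15, , drop = FALSE],
                             c(rep(0, 12), rep(1, 3))),
               "10 samples")
})

test_that("ERS point table reproduces the published brackets", {
  ers1 <- data.frame(age = 52, sex = "F", family_history = 0, bmi = 24,
                     pack_years = 0)
  expect_identical(compute_ers(ers1), 0L)
  ers2 <- data.frame(age = 72, sex = "M", family_history = 1, bmi = 31,
                     pack_years = 35)
  expect_identical(compute_ers(ers2), 12L)  # 4+1+1+2+4
  ers3 <- data.frame(age = 55, sex = "F", family_history = 0, bmi = 25,
                     pack_years = 0.5)
  expect_identical(compute_ers(ers3), 4L)   # 1+0+0+1+2
  expect_error(compute_ers(data.frame(age = 60, sex = "M",
                                      family_history = NA, bmi = 25,
                                      pack_years = 3)), "impute")
})

test_that("ERS is piecewise constant with breakpoints exactly at the brackets", {
  eps <- 1e-9
  ages <- c(40, 55 - eps, 55, 60 - eps, 60, 65 - eps, 65, 70 - eps, 70, 90)
  age_expected <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  bmis <- c(18, 25 - eps, 25, 30 - eps, 30, 45)
  bmi_expected <- c(0, 0, 1, 1, 2, 2)
  pys <- c(0, eps, 30 - eps, 30, 80)
  py_expected <- c(0, 2, 2, 4, 4)
  grid <- expand.grid(a = seq_along(ages), b = seq_along(bmis),
                      p = seq_along(pys), s = c("M", "F"), fh = 0:1)
  x <- data.frame(age = ages[grid$a], sex = as.character(grid$s),
                  family_history = grid$fh, bmi = bmis[grid$b],
                  pack_years = pys[grid$p])
  expected <- age_expected[grid$a] + (grid$s == "M") + grid$fh +
    bmi_expected[grid$b] + py_expected[grid$p]
  expect_identical(compute_ers(x), as.integer(expected))
})

test_that("chained-equation imputation is reproducible and unbiased under MCAR", {
  full <- data.frame(age = runif(200, 50, 75),
                     sex = sample(c("M", "F"), 200, TRUE),
                     family_history = rbinom(200, 1, 0.15),
                     bmi = rnorm(200, 27, 4),
                     pack_years = pmax(0, rnorm(200, 12, 10)))
  expect_identical(impute_ers_missing(full, seed = 1)[[1]], full)

  mask <- full
  mask$pack_years[1:20] <- NA
  mask$family_history[21:30] <- NA
  i1 <- impute_ers_missing(mask, m = 2, seed = 99)
  i2 <- impute_ers_missing(mask, m = 2, seed = 99)
  expect_identical(i1, i2)
  expect_false(anyNA(i1[[1]]))
  expect_false(identical(i1[[1]]$pack_years[1:20], i1[[2]]$pack_years[1:20]))

  # MCAR 10% missing pack-years: imputed-data mean unbiased over replicates
  set.seed(3)
  diffs <- replicate(100, {
    n <- 200
    d <- data.frame(age = runif(n, 50, 75),
                    sex = sample(c("M", "F"), n, TRUE),
                    family_history = rbinom(n, 1, 0.15),
                    bmi = rnorm(n, 27, 4),
                    pack_years = pmax(0, rnorm(n, 12, 10)))
    dm <- d
    dm$pack_years[sample(n, n / 10)] <- NA
    imp <- impute_ers_missing(dm, seed = sample.int(1e6, 1))[[1]]
    mean(imp$pack_years) - mean(d$pack_years)
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))

  bad <- full; bad$pack_years <- NA_real_
  expect_error(impute_ers_missing(bad), "100% missing")
})

test_that("PRS is the weighted allele sum with strict input validation", {
  d <- rbind(s1 = c(snpA = 0, snpB = 0), s2 = c(snpA = 2, snpB = 1))
  w <- c(snpA = 0.1, snpB = -0.2)
  prs <- compute_prs(d, w)
  expect_equal(unname(prs["s1"]), 0)
  expect_equal(unname(prs["s2"]), 0)  # 0.2 - 0.2
  # zero-weight SNP leaves scores unchanged
  d2 <- cbind(d, snpC = c(1, 2))
  expect_equal(unname(compute_prs(d2, c(w, snpC = 0))), unname(prs))
  expect_error(compute_prs(d, c(snpA = 0.1, snpX = 1)), "mismatch")
  expect_error(compute_prs(rbind(c(snpA = 3, snpB = 0)), w), "\\[0, 2\\]")
})

test_that("combining scores preserves and never degrades apparent AUC", {
  set.seed(11)
  n <- 300
  s1 <- rnorm(n); s2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * s1 + 0.8 * s2))
  single <- combine_scores(cbind(a = s1), y)
  # one component: a monotone transform, AUC unchanged
  expect_equal(auc(single$metadata$fitted, y)$auc, auc(s1, y)$auc,
               tolerance = 1e-12)
  both <- combine_scores(cbind(a = s1, b = s2), y)
  expect_gte(auc(both$metadata$fitted, y)$auc,
             auc(s1, y)$auc - 1e-9)
  expect_gte(auc(both$metadata$fitted, y)$auc,
             auc(s2, y)$auc - 1e-9)
  expect_error(combine_scores(cbind(a = s1, b = s1), y), "collinear")
})
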