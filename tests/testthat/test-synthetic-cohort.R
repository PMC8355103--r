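test_that("cohort generation is deterministic and structurally sound", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_snps = 20, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cq, b$cq)
  expect_identical(a$samples, b$samples)
  expect_identical(a$dosages, b$dosages)

  expect_equal(nrow(a$cq), 80)
  expect_setequal(c("UniSp2", "UniSp4", "UniSp6", "miR-23a", "miR-451a"),
                  intersect(colnames(a$cq),
                            c("UniSp2", "UniSp4", "UniSp6", "miR-23a",
                              "miR-451a")))
  expect_equal(sum(a$samples$status == "case"), 40)
  expect_true(all(a$roles$assay_id %in% colnames(a$cq)))
  expect_true(all(a$truth$hemolyzed %in% a$samples$sample_id))
  # hemolysed samples actually violate the delta-Cq rule
  hem <- a$truth$hemolyzed
  expect_true(all(a$cq[hem, "miR-23a"] - a$cq[hem, "miR-451a"] > 7))
  expect_true(all(a$dosages %in% 0:2))
  expect_true(all(is.na(a$samples$time_to_dx_years[
    a$samples$status == "control"])))
})

test_that("hemolysis_fraction = 0 yields no downstream hemolysis exclusions", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_snps = 10,
                    hemolysis_fraction = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_length(co$truth$hemolyzed, 0)
  qc <- run_qc(co$cq, co$roles, normalizers = cfg$normalizer_names)
  expect_equal(unname(qc$counts["hemolysis"]), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(n_informative = 50), "exceed")
  expect_error(sim_config(effect_sizes = c(1, NaN, 1, 1, 1, 1, 1)),
               "finite")
  expect_error(sim_config(hemolysis_fraction = 1.2), "fractions")
  expect_error(sim_config(n_informative = 2, effect_sizes = 1), "length")
})

test_that("injected shift is detected and null assays reject at ~1%", {
  # one informative miRNA with a 1.5-cycle shift among many null fillers
  cfg <- sim_config(n_cases = 1000, n_controls = 1000,
                    n_candidate_mirnas = 254, n_informative = 1,
                    effect_sizes = 1.5, informative_names = "shifted",
                    n_snps = 5, hemolysis_fraction = 0,
                    missing_fraction = 0, seed = 101)
  co <- generate_cohort(cfg)
  case <- co$samples$status == "case"
  tt <- t.test(co$cq[case, "shifted"], co$cq[!case, "shifted"])
  expect_lt(tt$p.value, 1e-10)
  # mean Cq difference recovers the injected shift within 3 SE
  diff <- mean(co$cq[!case, "shifted"]) - mean(co$cq[case, "shifted"])
  se <- sqrt(var(co$cq[case, "shifted"]) / sum(case) +
               var(co$cq[!case, "shifted"]) / sum(!case))
  expect_lt(abs(diff - 1.5), 3 * se)

  # 500 null columns (250 per cohort over two seeds): type-I rate ~ alpha
  cfg2 <- sim_config(n_cases = 1000, n_controls = 1000,
                     n_candidate_mirnas = 254, n_informative = 1,
                     effect_sizes = 1.5, informative_names = "shifted",
                     n_snps = 5, hemolysis_fraction = 0,
                     missing_fraction = 0, seed = 102)
  co2 <- generate_cohort(cfg2)
  nulls <- grep("^cand-", colnames(co$cq), value = TRUE)
  pvals <- c(
    vapply(nulls, function(a)
      t.test(co$cq[case, a], co$cq[!case, a])$p.value, numeric(1)),
    vapply(nulls, function(a) {
      cs <- co2$samples$status == "case"
      t.test(co2$cq[cs, a], co2$cq[!cs, a])$p.value
    }, numeric(1)))
  n_rej <- sum(pvals < 0.01)
  # Binomial(500, 0.01): accept up to ~3 SD above/below the mean
  expect_gte(n_rej, qbinom(0.001, length(pvals), 0.01))
  expect_lte(n_rej, qbinom(0.999, length(pvals), 0.01))
})

test_that("realised case fraction matches the logistic-model-implied rate", {
  cfg <- sim_config(seed = 5)
  set.seed(77)
  snp_freqs <- runif(cfg$n_snps, 0.05, 0.5)
  snp_lor <- setNames(rnorm(cfg$n_snps, 0, 0.08),
                      sprintf("snp_%03d", seq_len(cfg$n_snps)))
  pop <- mirisk:::simulate_population(cfg, 20000, snp_freqs, snp_lor)
  implied <- mean(pop$prob)
  se <- sqrt(implied * (1 - implied) / length(pop$status))
  expect_lt(abs(mean(pop$status) - implied), 3 * se)
})

test_that("null-effect cohorts give unbiased miR-score coefficients (CI coverage)", {
  n_rep <- 200
  covered <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_cases = 100, n_controls = 100,
                      n_candidate_mirnas = 12, n_informative = 7,
                      effect_sizes = rep(0, 7), n_snps = 4,
                      hemolysis_fraction = 0, missing_fraction = 0,
                      seed = 9000 + r)
    co <- generate_cohort(cfg)
    expr <- normalize_cq(co$cq, cfg$normalizer_names,
                         cfg$informative_names)
    fit <- fit_mir_score(expr, co$samples$status)
    se <- fit$metadata$se[-1]
    covered <- covered + sum(abs(fit$coefficients) <= 1.96 * se)
    total <- total + length(fit$coefficients)
  }
  coverage <- covered / total
  expect_gt(coverage, 0.92)
  expect_lt(coverage, 0.98)
})

test_that("cohorts round-trip through TSV fixtures and regenerate from seed", {
  cfg <- sim_config(n_cases = 8, n_controls = 8, n_candidate_mirnas = 10,
                    n_informative = 2, effect_sizes = c(0.5, -0.5),
                    informative_names = c("up", "down"), n_snps = 6,
                    seed = 314)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(co$cq, back$cq)
  expect_equal(co$dosages, back$dosages)
  expect_equal(co$samples$status, back$samples$status)
  expect_equal(co$samples$age, back$samples$age)
  expect_equal(co$snp_weights$weight, back$snp_weights$weight)
  expect_equal(co$truth$effects, back$truth$effects)
  # the recorded config regenerates the identical cohort
  again <- generate_cohort(back$config)
  expect_identical(co$cq, again$cq)
})

test_that("the shipped 10-sample fixture regenerates from its recorded seed", {
  dir <- system.file("extdata", "synthetic_cohort_10", package = "mirisk")
  fix <- read_cohort(dir)
  regen <- generate_cohort(fix$config)
  expect_equal(fix$cq, regen$cq, tolerance = 1e-12)
  expect_equal(fix$samples$status, regen$samples$status)
  expect_equal(fix$truth$hemolyzed, regen$truth$hemolyzed)
})
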