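#' Simulate a raw population with case status from the additive model
#'
#' Draws covariates and SNP dosages and assigns case status from an
#' additive logistic model (covariate effects plus per-SNP log odds on
#' centred dosages). Used internally by [generate_cohort()] and directly
#' in calibration checks: the realised case fraction converges to the
#' mean of the model-implied probabilities.
#'
#' @param config A [sim_config()] object.
#' @param n Number of individuals to draw.
#' @param snp_freqs,snp_log_or Allele frequencies and per-SNP log odds
#'   (already resolved from the config).
#' @return A list with `covariates` (data.frame), `dosages` (matrix),
#'   `prob` (model-implied case probability) and `status` (0/1).
#' @keywords internal
simulate_population <- function(config, n, snp_freqs, snp_log_or) {
  ce <- config$covariate_effects
  age <- rnorm(n, 65, 7)
  while (any(bad <- age < 50 | age > 75)) age[bad] <- rnorm(sum(bad), 65, 7)
  sex <- ifelse(runif(n) < 0.55, "M", "F")
  family_history <- as.integer(runif(n) < 0.12)
  bmi <- pmax(16, rnorm(n, 27.5, 4))
  smoker <- runif(n) < 0.55
  pack_years <- ifelse(smoker, rgamma(n, shape = 1.5, scale = 12), 0)

  dosages <- matrix(rbinom(n * config$n_snps, 2L,
                           rep(snp_freqs, each = n)),
                    nrow = n, ncol = config$n_snps)
  colnames(dosages) <- names(snp_log_or)

  # centred linear predictor: implied marginal case rate ~ 1/2
  eta <- ce[["age"]] * (age - 65) +
    ce[["sex"]] * ((sex == "M") - 0.55) +
    ce[["family_history"]] * (family_history - 0.12) +
    ce[["bmi"]] * (bmi - 27.5) +
    ce[["pack_years"]] * (pack_years - 9.9) +
    drop(sweep(dosages, 2, 2 * snp_freqs) %*% snp_log_or)
  prob <- stats::plogis(eta)
  status <- stats::rbinom(n, 1L, prob)
  list(covariates = data.frame(age = age, sex = sex,
                               family_history = family_history,
                               bmi = bmi, pack_years = pack_years,
                               stringsAsFactors = FALSE),
       dosages = dosages, prob = prob, status = status)
}

#' Generate a synthetic serum-miRNA case-cohort study
#'
#' Produces a raw Cq matrix (spike-ins, hemolysis markers, candidate
#' miRNAs), a per-sample covariate table, a SNP dosage matrix with the
#' true additive weights, and a ground-truth record. Case status is
#' drawn from the additive logistic model of [simulate_population()] and
#' rejection-sampled to hit the configured case/control margins, as in a
#' case-cohort design. Informative miRNAs then receive their configured
#' case/control Cq shift; hemolytic samples have miR-451a lowered until
#' Cq(miR-23a) - Cq(miR-451a) exceeds 7 cycles.
#'
#' All randomness is fixed by `config$seed`: the same configuration
#' always reproduces the identical cohort.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `mirisk_cohort`: a list with elements
#'   `cq` (samples x assays Cq matrix, NA = undetected), `roles`
#'   (data.frame assay_id/role), `samples` (covariate table with
#'   `status`, `time_to_dx_years`), `dosages`, `snp_weights`
#'   (data.frame snp_id/weight, the true log odds), and `truth`
#'   (informative set, injected shifts, SNP effects, hemolysed ids).
#' @examples
#' cohort <- generate_cohort(sim_config(n_cases = 30, n_controls = 30,
#'                                      n_snps = 10, seed = 7))
#' dim(cohort$cq)
#' table(cohort$samples$status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  filler_n <- config$n_candidate_mirnas - length(config$normalizer_names) -
    config$n_informative
  candidate_names <- c(config$normalizer_names, config$informative_names,
                       if (filler_n > 0) sprintf("cand-%02d", seq_len(filler_n)))
  assay_names <- c("UniSp2", "UniSp4", "UniSp6", "miR-23a", "miR-451a",
                   candidate_names)
  roles <- data.frame(
    assay_id = assay_names,
    role = c("spike_in_extraction", "spike_in_extraction", "spike_in_rt",
             "hemolysis", "hemolysis", rep("candidate", length(candidate_names))),
    stringsAsFactors = FALSE)

  # per-assay baseline Cq in the qPCR detectable range
  base_cq <- stats::setNames(runif(length(candidate_names), 22, 34),
                             candidate_names)
  snp_ids <- sprintf("snp_%03d", seq_len(config$n_snps))
  snp_freqs <- config$snp_freqs %||% runif(config$n_snps, 0.05, 0.5)
  snp_log_or <- stats::setNames(
    config$snp_log_or %||% rnorm(config$n_snps, 0, 0.08), snp_ids)

  # rejection-sample to the configured case/control margins
  need_cases <- config$n_cases; need_controls <- config$n_controls
  kept <- list()
  while (need_cases > 0 || need_controls > 0) {
    batch <- simulate_population(config,
                                 max(512L, 2L * (need_cases + need_controls)),
                                 snp_freqs, snp_log_or)
    take <- c(which(batch$status == 1L)[seq_len(min(need_cases,
                                                    sum(batch$status == 1L)))],
              which(batch$status == 0L)[seq_len(min(need_controls,
                                                    sum(batch$status == 0L)))])
    kept[[length(kept) + 1L]] <- list(
      covariates = batch$covariates[take, , drop = FALSE],
      dosages = batch$dosages[take, , drop = FALSE],
      status = batch$status[take])
    need_cases <- config$n_cases -
      sum(vapply(kept, function(k) sum(k$status == 1L), integer(1)))
    need_controls <- config$n_controls -
      sum(vapply(kept, function(k) sum(k$status == 0L), integer(1)))
  }
  covariates <- do.call(rbind, lapply(kept, `[[`, "covariates"))
  dosages <- do.call(rbind, lapply(kept, `[[`, "dosages"))
  status <- unlist(lapply(kept, `[[`, "status"))
  # cases first, then controls, then shuffle deterministically
  ord <- c(which(status == 1L), which(status == 0L))
  ord <- ord[sample.int(length(ord))]
  covariates <- covariates[ord, , drop = FALSE]
  dosages <- dosages[ord, , drop = FALSE]
  status <- status[ord]
  n <- length(status)
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(covariates) <- NULL
  rownames(dosages) <- sample_ids

  # Cq matrix
  cq <- matrix(NA_real_, nrow = n, ncol = length(assay_names),
               dimnames = list(sample_ids, assay_names))
  for (sp in names(config$spikein_means))
    cq[, sp] <- rnorm(n, config$spikein_means[[sp]], config$spikein_sds[[sp]])
  cq[, "miR-23a"] <- rnorm(n, 26, 0.8)
  cq[, "miR-451a"] <- rnorm(n, 24, 0.8)
  for (a in candidate_names) {
    sd_a <- if (a %in% config$normalizer_names) config$normalizer_sd
            else config$assay_noise_sd
    cq[, a] <- rnorm(n, base_cq[[a]], sd_a)
  }
  # injected case/control shifts: positive effect = up in cases = lower Cq
  if (config$n_informative > 0) {
    eff <- stats::setNames(config$effect_sizes, config$informative_names)
    for (a in config$informative_names)
      cq[status == 1L, a] <- cq[status == 1L, a] - eff[[a]]
  } else eff <- stats::setNames(numeric(0), character(0))

  # hemolysis: drop miR-451a Cq until the marker difference exceeds 7
  n_hem <- round(config$hemolysis_fraction * n)
  hemolyzed <- if (n_hem > 0) sort(sample(sample_ids, n_hem)) else character(0)
  if (n_hem > 0)
    cq[hemolyzed, "miR-451a"] <- cq[hemolyzed, "miR-23a"] - 7 -
      runif(n_hem, 0.5, 3)

  # undetected measurements: dropout concentrates in the filler candidates
  # (low-abundance assays near the limit of detection); planted
  # normalizers and informative miRNAs stay complete so the detectability
  # contract (>= 99% detected) is reproducible
  filler_names <- setdiff(candidate_names,
                          c(config$normalizer_names,
                            config$informative_names))
  if (config$missing_fraction > 0 && length(filler_names)) {
    sub <- cq[, filler_names, drop = FALSE]
    if (config$missing_mechanism == "mcar") {
      p_miss <- matrix(config$missing_fraction, nrow(sub), ncol(sub))
    } else {
      w <- stats::plogis((sub - 34) / 1.5)
      p_miss <- pmin(1, config$missing_fraction * w / mean(w))
    }
    sub[matrix(runif(length(sub)), nrow(sub)) < p_miss] <- NA_real_
    cq[, filler_names] <- sub
  }

  time_to_dx <- ifelse(status == 1L, runif(n, 0, 14), NA_real_)

  samples <- data.frame(
    sample_id = sample_ids,
    status = ifelse(status == 1L, "case", "control"),
    covariates,
    time_to_dx_years = time_to_dx,
    stringsAsFactors = FALSE)

  structure(list(
    cq = cq, roles = roles, samples = samples, dosages = dosages,
    snp_weights = data.frame(snp_id = snp_ids, weight = unname(snp_log_or),
                             stringsAsFactors = FALSE),
    truth = list(informative = config$informative_names,
                 effects = eff, snp_log_or = snp_log_or,
                 snp_freqs = stats::setNames(snp_freqs, snp_ids),
                 hemolyzed = hemolyzed,
                 time_to_dx_years = stats::setNames(time_to_dx, sample_ids),
                 seed = config$seed),
    config = config), class = "mirisk_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mirisk_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d cases), %d assays, %d SNPs\n",
              nrow(x$cq), sum(x$samples$status == "case"), ncol(x$cq),
              ncol(x$dosages)))
  cat(sprintf("  informative miRNAs: %s\n",
              paste(x$truth$informative, collapse = ", ")))
  cat(sprintf("  hemolysed samples: %d\n", length(x$truth$hemolyzed)))
  invisible(x)
}

#' Write a synthetic cohort to delimited-text fixtures
#'
#' Writes `cq_matrix.tsv`, `assay_roles.tsv`, `samples.tsv`,
#' `dosages.tsv`, `snp_weights.tsv` and `truth.json` into `dir`. The
#' files round-trip losslessly through [read_cohort()] (numeric values
#' are serialised at full double precision).
#'
#' @param cohort A `mirisk_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mirisk_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  p <- function(f) file.path(dir, f)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

  write_mat <- function(m, path, id_col) {
    df <- data.frame(rownames(m), apply(m, 2, num), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(id_col, colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(cohort$cq, p("cq_matrix.tsv"), "sample_id")
  write_mat(cohort$dosages, p("dosages.tsv"), "sample_id")
  utils::write.table(cohort$roles, p("assay_roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  samples <- cohort$samples
  for (v in c("age", "bmi", "pack_years", "time_to_dx_years"))
    samples[[v]] <- num(samples[[v]])
  utils::write.table(samples, p("samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sw <- cohort$snp_weights
  sw$weight <- num(sw$weight)
  utils::write.table(sw, p("snp_weights.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- unclass(cohort$config)
  tru <- cohort$truth
  # jsonlite drops names of atomic vectors; serialise them as objects
  for (v in c("spikein_means", "spikein_sds", "covariate_effects"))
    cfg[[v]] <- as.list(cfg[[v]])
  for (v in c("effects", "snp_log_or", "snp_freqs", "time_to_dx_years"))
    tru[[v]] <- as.list(tru[[v]])
  jsonlite::write_json(
    list(truth = tru, config = cfg),
    p("truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(cq = p("cq_matrix.tsv"), roles = p("assay_roles.tsv"),
              samples = p("samples.tsv"), dosages = p("dosages.tsv"),
              snp_weights = p("snp_weights.tsv"), truth = p("truth.json")))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the fixture files.
#' @return A `mirisk_cohort` list (with `truth` and `config` restored
#'   from `truth.json`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  read_mat <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    m
  }
  tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  cfg <- tr$config
  config <- sim_config(
    n_cases = cfg$n_cases, n_controls = cfg$n_controls,
    n_candidate_mirnas = cfg$n_candidate_mirnas,
    n_informative = cfg$n_informative, effect_sizes = cfg$effect_sizes,
    informative_names = cfg$informative_names,
    assay_noise_sd = cfg$assay_noise_sd,
    normalizer_names = cfg$normalizer_names,
    normalizer_sd = cfg$normalizer_sd,
    spikein_means = unlist(cfg$spikein_means),
    spikein_sds = unlist(cfg$spikein_sds),
    hemolysis_fraction = cfg$hemolysis_fraction,
    missing_fraction = cfg$missing_fraction,
    missing_mechanism = cfg$missing_mechanism,
    n_snps = cfg$n_snps, snp_freqs = cfg$snp_freqs,
    snp_log_or = cfg$snp_log_or,
    covariate_effects = unlist(cfg$covariate_effects),
    seed = cfg$seed)
  truth <- tr$truth
  truth$effects <- unlist(truth$effects)
  truth$snp_log_or <- unlist(truth$snp_log_or)
  truth$snp_freqs <- unlist(truth$snp_freqs)
  truth$time_to_dx_years <- unlist(truth$time_to_dx_years)
  truth$hemolyzed <- as.character(unlist(truth$hemolyzed))
  structure(list(
    cq = read_mat(p("cq_matrix.tsv")),
    roles = utils::read.delim(p("assay_roles.tsv"), stringsAsFactors = FALSE),
    samples = utils::read.delim(p("samples.tsv"), stringsAsFactors = FALSE),
    dosages = read_mat(p("dosages.tsv")),
    snp_weights = utils::read.delim(p("snp_weights.tsv"),
                                    stringsAsFactors = FALSE),
    truth = truth, config = config), class = "mirisk_cohort")
}
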