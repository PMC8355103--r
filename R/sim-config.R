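#' Configuration for synthetic serum-miRNA cohorts
#'
#' Builds a validated configuration object for [generate_cohort()]. The
#' defaults emulate a prospective case-cohort qPCR study: 198 incident
#' cases and 178 randomly selected controls assayed on a 41-miRNA custom
#' panel with UniSp2/UniSp4/UniSp6 spike-ins and the miR-23a/miR-451a
#' hemolysis marker pair, plus 140 SNP dosages with additive log-odds
#' effects and the covariates entering the environmental risk score.
#'
#' Seven candidate miRNAs carry true case/control shifts on the Cq scale
#' (units: cycles, equal to log2 fold change of relative expression);
#' default magnitudes span roughly log2(0.6) to log2(1.5), typical of
#' serum miRNA case-control deregulation. Three low-variance,
#' shift-free candidates act as planted normalizers.
#'
#' @param n_cases,n_controls Number of cases / controls to generate.
#' @param n_candidate_mirnas Number of candidate miRNA assays on the panel
#'   (includes the planted normalizers and informative miRNAs).
#' @param n_informative Number of candidates given true case/control shifts.
#' @param effect_sizes Numeric vector of length `n_informative`; mean shift
#'   in expression units (cycles of Cq, log2 scale). Positive values mean
#'   up-regulation in cases (lower Cq).
#' @param informative_names Optional names for the informative assays.
#' @param assay_noise_sd Within-group SD of candidate Cq values (cycles).
#' @param normalizer_names Names of the planted stable normalizer assays.
#' @param normalizer_sd SD of the normalizer Cq values (cycles); low.
#' @param spikein_means,spikein_sds Named Cq means/SDs for UniSp2, UniSp4,
#'   UniSp6.
#' @param hemolysis_fraction Proportion of samples made hemolytic
#'   (miR-451a Cq lowered until Cq(miR-23a) - Cq(miR-451a) > 7).
#' @param missing_fraction Proportion of filler-candidate measurements
#'   (candidates that are neither planted normalizers nor informative)
#'   set to undetected (NA); emulates near-limit-of-detection dropout in
#'   low-abundance assays, which keeps the 99%-detectability contract of
#'   the informative set reproducible.
#' @param missing_mechanism `"mcar"` (default) or `"cq"` for
#'   near-limit-of-detection dropout (higher Cq more likely undetected).
#' @param n_snps Number of SNPs for the polygenic score.
#' @param snp_freqs Optional allele frequencies (length `n_snps`); drawn
#'   Uniform(0.05, 0.5) from the seed when `NULL`.
#' @param snp_log_or Optional per-SNP additive log odds ratios; drawn
#'   Normal(0, 0.08) when `NULL`.
#' @param covariate_effects Named log-odds effects of age (per year), sex
#'   (male vs female), family history, BMI (per kg/m^2) and smoking
#'   (per pack-year) on case status.
#' @param seed Integer seed fixing all randomness.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_cases = 198L,
                       n_controls = 178L,
                       n_candidate_mirnas = 41L,
                       n_informative = 7L,
                       effect_sizes = c(0.33, -0.71, 0.28, 0.15,
                                        0.61, -0.54, -0.29),
                       informative_names = NULL,
                       assay_noise_sd = 1.0,
                       normalizer_names = c("miR-93-5p", "miR-1246",
                                            "miR-223-3p"),
                       normalizer_sd = 0.15,
                       spikein_means = c(UniSp2 = 21.26, UniSp4 = 28.42,
                                         UniSp6 = 18.15),
                       spikein_sds = c(UniSp2 = 1.93, UniSp4 = 2.82,
                                       UniSp6 = 0.11),
                       hemolysis_fraction = 10 / 376,
                       missing_fraction = 0.05,
                       missing_mechanism = c("mcar", "cq"),
                       n_snps = 140L,
                       snp_freqs = NULL,
                       snp_log_or = NULL,
                       covariate_effects = c(age = 0.02, sex = 0.35,
                                             family_history = 0.45,
                                             bmi = 0.02, pack_years = 0.01),
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_cases >= 1, n_controls >= 1, n_candidate_mirnas >= 1,
            n_informative >= 0, n_snps >= 1)
  if (n_informative > n_candidate_mirnas)
    stop("n_informative must not exceed n_candidate_mirnas")
  if (length(effect_sizes) != n_informative)
    stop("effect_sizes must have length n_informative")
  if (any(!is.finite(effect_sizes)))
    stop("effect_sizes must be finite")
  for (f in c(hemolysis_fraction, missing_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (!is.null(snp_freqs) && length(snp_freqs) != n_snps)
    stop("snp_freqs must have length n_snps")
  if (!is.null(snp_log_or) && length(snp_log_or) != n_snps)
    stop("snp_log_or must have length n_snps")
  if (!all(c("age", "sex", "family_history", "bmi", "pack_years") %in%
           names(covariate_effects)))
    stop("covariate_effects must name age, sex, family_history, bmi, pack_years")

  if (is.null(informative_names)) {
    defaults <- c("let-7g-5p", "miR-19a-3p", "miR-23a-3p", "miR-92a-3p",
                  "miR-144-5p", "miR-21-5p", "miR-27a-3p")
    informative_names <-
      if (n_informative <= length(defaults)) defaults[seq_len(n_informative)]
      else c(defaults, sprintf("inf-%02d", seq_len(n_informative -
                                                   length(defaults))))
  }
  if (length(informative_names) != n_informative)
    stop("informative_names must have length n_informative")
  n_named <- length(normalizer_names) + n_informative
  if (n_named > n_candidate_mirnas)
    stop("normalizers + informative miRNAs exceed n_candidate_mirnas")

  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_candidate_mirnas = as.integer(n_candidate_mirnas),
    n_informative = as.integer(n_informative),
    effect_sizes = as.numeric(effect_sizes),
    informative_names = informative_names,
    assay_noise_sd = assay_noise_sd,
    normalizer_names = normalizer_names, normalizer_sd = normalizer_sd,
    spikein_means = spikein_means, spikein_sds = spikein_sds,
    hemolysis_fraction = hemolysis_fraction,
    missing_fraction = missing_fraction,
    missing_mechanism = missing_mechanism,
    n_snps = as.integer(n_snps),
    snp_freqs = snp_freqs, snp_log_or = snp_log_or,
    covariate_effects = covariate_effects,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d cases / %d controls; %d candidate miRNAs (%d informative)\n",
              x$n_cases, x$n_controls, x$n_candidate_mirnas, x$n_informative))
  cat(sprintf("  %d SNPs; hemolysis %.1f%%; missing %.1f%% (%s); seed %d\n",
              x$n_snps, 100 * x$hemolysis_fraction,
              100 * x$missing_fraction, x$missing_mechanism, x$seed))
  invisible(x)
}
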