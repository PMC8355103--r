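#' Spike-in control summary
#'
#' Summarises the RNA-extraction (UniSp2/UniSp4) and reverse-transcription
#' (UniSp6) spike-in controls: mean and sample SD of the Cq values per
#' spike-in, with per-sample outlier flags for samples whose spike-in Cq
#' deviates from the mean by more than `z` SDs. Spike-in outliers are
#' warnings, not exclusions: they indicate extraction or RT problems that
#' warrant inspection.
#'
#' @param cq Samples x assays numeric Cq matrix (NA = undetected).
#' @param spikeins Character vector of spike-in assay names that must be
#'   present as columns.
#' @param z Outlier threshold in SD units (default 3).
#' @return A list with `summary` (data.frame assay/mean/sd/n) and
#'   `flagged` (data.frame sample_id/assay/cq/z).
#' @examples
#' m <- cbind(UniSp6 = c(18.1, 18.2, 18.15))
#' rownames(m) <- paste0("S", 1:3)
#' spike_in_report(m, "UniSp6")$summary
#' @export
spike_in_report <- function(cq, spikeins = c("UniSp2", "UniSp4", "UniSp6"),
                            z = 3) {
  missing_cols <- setdiff(spikeins, colnames(cq))
  if (length(missing_cols))
    stop("spike-in column(s) absent from Cq matrix: ",
         paste(missing_cols, collapse = ", "))
  summ <- do.call(rbind, lapply(spikeins, function(a) {
    v <- cq[, a]
    data.frame(assay = a, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)),
               stringsAsFactors = FALSE)
  }))
  flagged <- do.call(rbind, lapply(spikeins, function(a) {
    v <- cq[, a]
    s <- summ$sd[summ$assay == a]
    if (is.na(s) || s == 0) return(NULL)
    zz <- (v - summ$mean[summ$assay == a]) / s
    idx <- which(!is.na(zz) & abs(zz) > z)
    if (!length(idx)) return(NULL)
    data.frame(sample_id = rownames(cq)[idx], assay = a, cq = v[idx],
               z = zz[idx], stringsAsFactors = FALSE)
  }))
  list(summary = summ,
       flagged = flagged %||% data.frame(sample_id = character(0),
                                         assay = character(0),
                                         cq = numeric(0), z = numeric(0)))
}

#' Hemolysis flag from the miR-23a / miR-451a marker pair
#'
#' miR-451a is enriched in red blood cells while miR-23a is stable in
#' serum; red-cell lysis inflates miR-451a (lowers its Cq). A sample is
#' flagged as hemolysed when Cq(miR-23a) - Cq(miR-451a) strictly exceeds
#' `delta` cycles (default 7).
#'
#' @param cq23a,cq451a Cq values of miR-23a and miR-451a (vectorised).
#' @param delta Threshold in cycles; the comparison is strict (`>`).
#' @return Logical vector; NA where either marker is undetected (such
#'   samples are unevaluable and handled separately by [run_qc()]).
#' @export
hemolysis_flag <- function(cq23a, cq451a, delta = 7) {
  (cq23a - cq451a) > delta
}

#' Single-measurement assay validity
#'
#' A measurement is valid iff its Cq does not exceed `max_cq` and it is
#' separated from the no-template negative control by more than
#' `negctrl_margin` cycles. An undetected negative control (NA) is
#' treated as +Inf, i.e. no contamination evidence. An undetected
#' measurement is invalid.
#'
#' @param cq Measurement Cq (vectorised; NA = undetected).
#' @param negctrl_cq Negative-control Cq for the same assay (NA = undetected).
#' @param max_cq Maximum acceptable Cq (default 37).
#' @param negctrl_margin Required separation from the negative control
#'   (default 5 cycles, strict).
#' @return Logical vector.
#' @export
assay_validity <- function(cq, negctrl_cq = NA_real_, max_cq = 37,
                           negctrl_margin = 5) {
  neg <- ifelse(is.na(negctrl_cq), Inf, negctrl_cq)
  !is.na(cq) & cq <= max_cq & (neg - cq) > negctrl_margin
}

#' Detectability filter for candidate miRNAs
#'
#' Retains the candidates whose Cq is detected (present and strictly
#' below `detect_cq`) in at least `min_frac` of the samples. Run after
#' hemolysed samples have been removed.
#'
#' @param cq Samples x assays Cq matrix.
#' @param candidates Candidate assay names (non-empty).
#' @param detect_cq Detection limit in cycles (default 40, strict `<`).
#' @param min_frac Minimum detected fraction (default 0.99, inclusive).
#' @return Character vector: the informative miRNA set.
#' @export
detectability_filter <- function(cq, candidates, detect_cq = 40,
                                 min_frac = 0.99) {
  if (!length(candidates)) stop("empty candidate list")
  missing_cols <- setdiff(candidates, colnames(cq))
  if (length(missing_cols))
    stop("candidate(s) absent from Cq matrix: ",
         paste(missing_cols, collapse = ", "))
  frac <- colMeans(!is.na(cq[, candidates, drop = FALSE]) &
                     cq[, candidates, drop = FALSE] < detect_cq)
  candidates[frac >= min_frac]
}

#' Exclude samples with missing values in required assays
#'
#' @param cq Samples x assays Cq matrix.
#' @param required Assay names every retained sample must have detected
#'   (non-NA). An empty list retains everything, with a warning.
#' @return A list with `retained` (sample ids), `excluded` (data.frame
#'   sample_id/reason) and `counts` (exclusions per missing assay).
#' @export
exclude_incomplete_samples <- function(cq, required) {
  if (!length(required)) {
    warning("empty required-assay list; no samples excluded")
    return(list(retained = rownames(cq),
                excluded = data.frame(sample_id = character(0),
                                      reason = character(0)),
                counts = integer(0)))
  }
  missing_cols <- setdiff(required, colnames(cq))
  if (length(missing_cols))
    stop("required assay(s) absent: ", paste(missing_cols, collapse = ", "))
  sub <- cq[, required, drop = FALSE]
  bad <- rowSums(is.na(sub)) > 0
  if (all(bad)) stop("all samples excluded: every sample misses a required assay")
  excluded <- data.frame(
    sample_id = rownames(cq)[bad],
    reason = vapply(which(bad), function(i) {
      paste0("missing:", paste(required[is.na(sub[i, ])], collapse = ","))
    }, character(1)),
    stringsAsFactors = FALSE)
  list(retained = rownames(cq)[!bad], excluded = excluded,
       counts = colSums(is.na(sub[bad, , drop = FALSE])))
}

#' Full qPCR quality-control pass
#'
#' Applies the QC stages in order: spike-in outlier flags (warn only),
#' hemolysis exclusion (miR-23a/miR-451a delta-Cq rule; samples with an
#' undetected marker are excluded as unevaluable), per-measurement assay
#' validity (invalid measurements set to undetected), detectability over
#' the retained samples, and completeness exclusion on the normalizers
#' plus informative miRNAs.
#'
#' @param cq Samples x assays Cq matrix (NA = undetected).
#' @param roles Data frame with columns `assay_id`, `role`; roles are
#'   `spike_in_extraction`, `spike_in_rt`, `hemolysis`, `candidate`,
#'   `negative_control`. Every assay column must be covered.
#' @param hemolysis_markers Length-2 character vector: the serum-stable
#'   marker and the red-cell marker, in that order.
#' @param hemolysis_delta,detect_cq,min_frac,max_cq,negctrl_margin,spike_z
#'   Stage thresholds; see the stage functions.
#' @param negctrl_cq Optional named vector of per-assay negative-control
#'   Cq values (default: all undetected).
#' @param required Assays that retained samples must have complete; the
#'   default `"informative"` uses the detectability result plus
#'   `normalizers` (if given).
#' @param normalizers Optional normalizer assay names to require complete.
#' @return An object of class `qc_report`: list with `cq` (retained
#'   samples, all columns, invalid candidate measurements set NA; a
#'   second full QC pass on it is a no-op), `cq_candidates` (candidate
#'   columns only), `spike_in`, `hemolysis` (sample_id/delta/flag),
#'   `informative`, `excluded` (sample_id/reason, one primary reason
#'   each), `retained`, and `counts` (per-reason exclusion tallies
#'   partitioning the input).
#' @export
run_qc <- function(cq, roles,
                   hemolysis_markers = c("miR-23a", "miR-451a"),
                   hemolysis_delta = 7, detect_cq = 40, min_frac = 0.99,
                   max_cq = 37, negctrl_margin = 5, spike_z = 3,
                   negctrl_cq = NULL, required = "informative",
                   normalizers = NULL) {
  stopifnot(is.matrix(cq), !is.null(rownames(cq)), !is.null(colnames(cq)))
  if (anyDuplicated(rownames(cq))) stop("sample ids must be unique")
  uncovered <- setdiff(colnames(cq), roles$assay_id)
  if (length(uncovered))
    stop("assay(s) missing from role map: ", paste(uncovered, collapse = ", "))
  role_of <- stats::setNames(roles$role, roles$assay_id)
  spikeins <- intersect(colnames(cq),
                        roles$assay_id[roles$role %in%
                                       c("spike_in_extraction", "spike_in_rt")])
  candidates <- intersect(colnames(cq), roles$assay_id[roles$role == "candidate"])

  spike <- if (length(spikeins)) spike_in_report(cq, spikeins, z = spike_z)
           else list(summary = NULL, flagged = NULL)

  # hemolysis
  m_stable <- hemolysis_markers[1]; m_rbc <- hemolysis_markers[2]
  if (!all(hemolysis_markers %in% colnames(cq)))
    stop("hemolysis marker column(s) absent: ",
         paste(setdiff(hemolysis_markers, colnames(cq)), collapse = ", "))
  delta <- cq[, m_stable] - cq[, m_rbc]
  hem_flag <- hemolysis_flag(cq[, m_stable], cq[, m_rbc], hemolysis_delta)
  hemolysis <- data.frame(sample_id = rownames(cq), delta = delta,
                          flag = hem_flag, stringsAsFactors = FALSE)
  hem_ids <- rownames(cq)[!is.na(hem_flag) & hem_flag]
  uneval_ids <- rownames(cq)[is.na(hem_flag)]
  keep1 <- setdiff(rownames(cq), c(hem_ids, uneval_ids))
  if (!length(keep1)) stop("all samples excluded at the hemolysis stage")

  # per-measurement validity on candidate assays
  sub <- cq[keep1, candidates, drop = FALSE]
  neg <- if (is.null(negctrl_cq)) stats::setNames(rep(NA_real_,
                                                      length(candidates)),
                                                  candidates)
         else negctrl_cq
  for (a in candidates) {
    ok <- assay_validity(sub[, a], neg[[a]] %||% NA_real_, max_cq,
                         negctrl_margin)
    sub[!ok, a] <- NA_real_
  }

  informative <- detectability_filter(sub, candidates, detect_cq, min_frac)

  req <- if (identical(required, "informative"))
    unique(c(normalizers, informative)) else required
  comp <- exclude_incomplete_samples(sub, req)

  excluded <- rbind(
    if (length(hem_ids)) data.frame(sample_id = hem_ids,
                                    reason = "hemolysis",
                                    stringsAsFactors = FALSE),
    if (length(uneval_ids)) data.frame(sample_id = uneval_ids,
                                       reason = "hemolysis_unevaluable",
                                       stringsAsFactors = FALSE),
    if (nrow(comp$excluded)) data.frame(sample_id = comp$excluded$sample_id,
                                        reason = "incomplete",
                                        stringsAsFactors = FALSE))
  excluded <- excluded %||% data.frame(sample_id = character(0),
                                       reason = character(0))
  retained <- comp$retained
  counts <- c(input = nrow(cq), retained = length(retained),
              hemolysis = length(hem_ids),
              hemolysis_unevaluable = length(uneval_ids),
              incomplete = nrow(comp$excluded))
  cq_out <- cq[retained, , drop = FALSE]
  cq_out[, candidates] <- sub[retained, , drop = FALSE]
  structure(list(cq = cq_out,
                 cq_candidates = sub[retained, , drop = FALSE],
                 spike_in = spike,
                 hemolysis = hemolysis, informative = informative,
                 excluded = excluded, retained = retained, counts = counts,
                 role_of = role_of,
                 params = list(hemolysis_delta = hemolysis_delta,
                               detect_cq = detect_cq, min_frac = min_frac,
                               max_cq = max_cq,
                               negctrl_margin = negctrl_margin)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qPCR quality-control report\n")
  cat(sprintf("  %d samples in, %d retained (%d hemolysed, %d unevaluable, %d incomplete)\n",
              x$counts[["input"]], x$counts[["retained"]],
              x$counts[["hemolysis"]], x$counts[["hemolysis_unevaluable"]],
              x$counts[["incomplete"]]))
  cat(sprintf("  informative miRNAs (%d): %s\n", length(x$informative),
              paste(x$informative, collapse = ", ")))
  if (!is.null(x$spike_in$summary)) {
    s <- x$spike_in$summary
    cat(sprintf("  spike-ins: %s\n",
                paste(sprintf("%s %.2f +/- %.2f", s$assay, s$mean, s$sd),
                      collapse = "; ")))
  }
  invisible(x)
}
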