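#!/usr/bin/env Rscript
# Association and predictive-performance evaluation: control-quintile
# odds ratios (unadjusted and age/sex-adjusted), apparent and
# .632+-corrected AUC and Brier for the individual scores and their
# combinations, follow-up-time subgroups, per-miRNA deregulation
# statistics, and the miRNA correlation structure.

library(mirisk)

cohort <- read_cohort("results/cohort")
scores <- read.delim("results/scores.tsv")
expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$sample_id
samples <- cohort$samples[match(scores$sample_id,
                                cohort$samples$sample_id), ]
labels <- scores$status
B <- 200  # bootstrap replicates per evaluation

# --- quintile-stratified association ----------------------------------
assoc <- do.call(rbind, lapply(c("mir_score", "ers", "prs"), function(s) {
  qa <- control_quintiles(scores[[s]], labels)
  rbind(cbind(score = s, quintile_interval = qa$intervals,
              quintile_or(qa, labels)),
        cbind(score = s, quintile_interval = qa$intervals,
              quintile_or(qa, labels, covariates = samples,
                          adjusted = "age_sex")))
}))
write.table(assoc, "results/association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("unadjusted quintile ORs (miR-score):\n")
print(assoc[assoc$score == "mir_score" & assoc$model == "model1",
            c("quintile", "cases", "controls", "or", "ci_low", "ci_high")],
      row.names = FALSE, digits = 3)

# --- predictive performance -------------------------------------------
evals <- list()
evals$mir_score <- bootstrap_632plus(expr, labels, B = B, seed = 17)
evals$mir_score_brier <- bootstrap_632plus(expr, labels, B = B, seed = 17,
                                           loss = "brier")
for (s in c("ers", "prs")) {
  a <- auc(scores[[s]], labels)
  evals[[s]] <- list(auc = a$auc, ci = c(a$ci_low, a$ci_high))
}
combos <- list(ers_prs = c("ers", "prs"),
               ers_mir = c("ers", "mir_score"),
               prs_mir = c("prs", "mir_score"),
               ers_prs_mir = c("ers", "prs", "mir_score"))
for (nm in names(combos)) {
  evals[[nm]] <- bootstrap_632plus(as.matrix(scores[combos[[nm]]]),
                                   labels, B = B, seed = 17)
}
cat("\npredictive performance (apparent / .632+ corrected AUC):\n")
for (nm in c("mir_score", names(combos)))
  cat(sprintf("  %-12s %.3f / %.3f\n", nm, evals[[nm]]$apparent$auc,
              evals[[nm]]$corrected))
cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", "ers", evals$ers$auc,
            evals$ers$ci[1], evals$ers$ci[2]))
cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", "prs", evals$prs$auc,
            evals$prs$ci[1], evals$prs$ci[2]))

# follow-up subgroups: early (<= 3 years to diagnosis) vs later cases
for (win in list(early = c(0, 3), late = c(3, Inf))) {
  sub <- followup_subgroup(cbind(samples, .s = scores$mir_score), win)
  a <- auc(sub$.s, sub$status, ci = FALSE)
  cat(sprintf("  miR-score, cases diagnosed (%g, %g] years: AUC %.3f (n=%d)\n",
              win[1], win[2], a$auc, nrow(sub)))
}

jsonlite::write_json(
  lapply(evals, function(e)
    if (inherits(e, "eval_report"))
      e[c("loss", "corrected", "err_app", "err1", "gamma", "B", "seed")]
    else e),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA, force = TRUE)

# --- per-miRNA deregulation and correlation ---------------------------
dereg <- deregulation_table(expr, labels)
write.table(dereg, "results/deregulation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nper-miRNA deregulation (fold change, Holm-corrected p):\n")
print(dereg, row.names = FALSE, digits = 3)

rho <- spearman_matrix(expr)
write.table(data.frame(mirna = rownames(rho), round(rho, 3),
                       check.names = FALSE),
            "results/spearman.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# ROC points of the miR-score for plotting
sc <- scores$mir_score
thr <- sort(unique(sc), decreasing = TRUE)
y <- as.integer(labels == "case")
roc_pts <- data.frame(
  threshold = thr,
  fpr = vapply(thr, function(t) mean(sc[y == 0] >= t), numeric(1)),
  tpr = vapply(thr, function(t) mean(sc[y == 1] >= t), numeric(1)))
write.table(roc_pts, "results/roc_points.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote association.tsv, evaluation.json, deregulation.tsv,",
    "spearman.tsv, roc_points.tsv\n")
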