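#!/usr/bin/env Rscript
# Risk-score construction: the cohort-fitted logistic miR-score, the
# frozen published 7-miRNA panel applied to the same expression values,
# the point-based environmental risk score (with chained-equation
# imputation if covariates are missing), and the weighted-allele-sum
# polygenic risk score.

library(mirisk)

cohort <- read_cohort("results/cohort")
expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1])
rownames(expr) <- expr_df$sample_id
samples <- cohort$samples[match(rownames(expr), cohort$samples$sample_id), ]

# cohort-fitted miR-score
fit <- fit_mir_score(expr, samples$status)
print(fit)
mir_score <- apply_mir_score(fit, expr)

# frozen published panel, where its predictors were measured
frozen <- load_mir_score_model()
mir_score_published <- if (all(names(frozen$coefficients) %in%
                               colnames(expr)))
  apply_mir_score(frozen, expr) else rep(NA_real_, nrow(expr))

# environmental risk score
covars <- samples[, c("age", "sex", "family_history", "bmi", "pack_years")]
if (anyNA(covars[c("family_history", "pack_years")]))
  covars <- impute_ers_missing(covars, seed = 17)[[1]]
ers <- compute_ers(covars)

# polygenic risk score
prs <- compute_prs(cohort$dosages[rownames(expr), ], cohort$snp_weights)

scores <- data.frame(sample_id = rownames(expr), status = samples$status,
                     mir_score = mir_score,
                     mir_score_published = mir_score_published,
                     ers = ers, prs = prs)
dir.create("results", showWarnings = FALSE)
write.table(scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("scores for %d samples written to results/scores.tsv\n",
            nrow(scores)))
for (s in c("mir_score", "ers", "prs"))
  cat(sprintf("  apparent AUC %-9s %.3f\n", s,
              auc(scores[[s]], scores$status, ci = FALSE)$auc))
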