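#!/usr/bin/env Rscript
# Quality control and normalization: spike-in monitoring, hemolysis
# exclusion (delta-Cq > 7), assay validity, 99% detectability, and
# NormFinder selection of a 3-miRNA normalizer combination, then
# delta-Cq normalization of the informative panel.

library(mirisk)

cohort <- read_cohort("results/cohort")
qc <- run_qc(cohort$cq, cohort$roles,
             normalizers = cohort$config$normalizer_names)
print(qc)

labels <- cohort$samples$status[match(qc$retained,
                                      cohort$samples$sample_id)]

# NormFinder over candidates complete in all retained samples
complete <- colnames(qc$cq_candidates)[
  colSums(is.na(qc$cq_candidates)) == 0]
stab <- normfinder_stability(qc$cq_candidates[, complete], labels)
sel <- select_normalizers(stab, k = 3)
cat(sprintf("selected normalizers: %s (combined stability %.4g)\n",
            paste(sel$normalizers, collapse = ", "), sel$stability))

dir.create("results", showWarnings = FALSE)
write.table(stab[order(stab$stability), ], "results/stability.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

targets <- setdiff(qc$informative, sel$normalizers)
expr <- normalize_cq(qc$cq_candidates, sel$normalizers, targets)
write.table(data.frame(sample_id = rownames(expr), expr,
                       check.names = FALSE),
            "results/expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("normalized expression: %d samples x %d informative miRNAs\n",
            nrow(expr), ncol(expr)))
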