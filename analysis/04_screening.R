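#!/usr/bin/env Rscript
# Screening over the bout-locked coherence changes: per-pair stimulus bias
# (preferred minus less-preferred), the mean +/- 1.5 SD selection, region
# over-representation among selected pairs (exact binomial), octant
# classification of per-task bias signs, and cross-task correlations of the
# bout coherence changes with FDR.

suppressPackageStartupMessages(library(sblfp))

bt <- read.csv("results/coherence_bout_theta.csv", stringsAsFactors = FALSE)
biases <- bias_table(bt, unit_col = "pair")
write.csv(biases, "results/pair_biases_theta.csv", row.names = FALSE)

universe <- sort(unique(bt$pair))
selected_all <- character(0)
for (tk in task_vocabulary()) {
  b <- biases[biases$task == tk & is.finite(biases$bias), ]
  sel <- threshold_bias(setNames(b$bias, b$unit))
  cat(sprintf("%s: %d of %d pairs cross mean +/- 1.5 SD [%.3f, %.3f]\n",
              tk, length(sel$selected), nrow(b), sel$lower, sel$upper))
  selected_all <- union(selected_all, sel$selected)
}
over <- region_overrepresentation(selected_all, universe)
write.csv(over, "results/region_overrepresentation.csv", row.names = FALSE)
cat("\nMost over-represented regions among selected pairs:\n")
print(head(over, 5))

oc <- octant_classification(biases)
cat(sprintf("\nOctant classification: max octant count %d of %d regions/pairs, P(X >= %d | 1/8) = %.4g\n",
            oc$max_count, nrow(oc$octants), oc$max_count, oc$p_arrangement))
write.csv(oc$octants, "results/octants.csv", row.names = FALSE)

# cross-task correlation of per-pair biases, BH-corrected
wide <- reshape(biases, idvar = "unit", timevar = "task", direction = "wide")
combos <- combn(task_vocabulary(), 2)
ps <- numeric(ncol(combos)); rs <- numeric(ncol(combos))
for (k in seq_len(ncol(combos))) {
  a <- wide[[paste0("bias.", combos[1, k])]]
  b <- wide[[paste0("bias.", combos[2, k])]]
  ct <- correlate(a, b, "spearman")
  rs[k] <- ct$r; ps[k] <- ct$p
}
adj <- bh_fdr(ps)
cat("\nCross-task bias correlations (Spearman, BH-adjusted):\n")
print(data.frame(pair = apply(combos, 2, paste, collapse = " vs "),
                 rho = round(rs, 3), p_adj = signif(adj$p_adj, 3)))
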