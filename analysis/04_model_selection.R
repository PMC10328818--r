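#!/usr/bin/env Rscript
# AICc backward selection under known truth: 100 replicate cohorts with three
# true medium-tier covariates and seven null multi-level covariates; scores
# how often the final model keeps every true term and how many null terms
# survive the two-unit improvement rule.

suppressMessages(library(microvarpart))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

sel <- bench_selection(n_rep = 100, seed = 20260923)
write.table(sel$table, "results/tables/selection_replicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("replicates keeping all 3 true terms: %.0f%%\n",
            100 * sel$true_recovery))
cat(sprintf("null terms retained: median %d, mean %.2f\n",
            sel$median_null_retained, sel$mean_null_retained))
print(table(null_retained = sel$table$null_kept))
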