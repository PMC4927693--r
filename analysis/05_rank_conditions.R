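#!/usr/bin/env Rscript
# Stage 5: condition ranking and the human-readable digest.
#
# Lexicographic objective: narrower median base width, then higher sum of
# resolution, then more even peak distribution (higher NRP).

suppressPackageStartupMessages(library(sfcscreen))
dir.create("results", showWarnings = FALSE)
seed <- 20260

design <- sfc_method_development_design()
dataset <- generate_screen(design, default_test_panel(), seed = seed)
report <- run_screen_evaluation(dataset)

utils::write.table(report$ranking, "results/condition_ranking.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_report_digest(report, "results/screen_digest.txt")

print(report)
top_ms <- report$ranking[report$ranking$detection == "MS", ][1, ]
cat(sprintf("\nBest MS-compatible condition: %s\n", top_ms$condition_id))
cat(sprintf("  median width %.1f s, sum Rs %.2f, NRP %.2f\n",
            top_ms$median_width, top_ms$sum_rs, top_ms$nrp))
cat("\nDigest written to results/screen_digest.txt\n")
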