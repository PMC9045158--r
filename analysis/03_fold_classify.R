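#!/usr/bin/env Rscript
# Fold every long intergenic region, keep stem-loops below -10 kcal/mol,
# and classify the candidate internal terminators into Types I-IV.

suppressMessages(library(termstoich))

irs <- read_table_tsv("results/intergenic_regions.tsv")
scan <- scan_ir_table(irs, dG_threshold = -10)
calls <- lapply(scan$structures, terminator_call)

write_table(scan$table, "results/stemloops.tsv")
write_table(calls_table(calls), "results/terminator_calls.tsv")

logo <- tail_logo_counts(calls)
write_table(data.frame(base = rownames(logo$counts), logo$counts),
            "results/tail_logo_counts.tsv")

cat("Stem-loops below -10 kcal/mol:", nrow(scan$table), "of",
    sum(irs$is_long), "long IRs\n")
cat("dG range:", sprintf("%.1f .. %.1f kcal/mol",
                         min(scan$table$dG), max(scan$table$dG)), "\n")
cat("Type calls:\n")
print(table(vapply(calls, function(x) x$type_label, "")))
cat("3' window information content (bits/position):\n")
print(round(logo$information, 2))
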