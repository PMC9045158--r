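#!/usr/bin/env Rscript
# Quantify termination efficiency from simulated Northern band-intensity
# and qPCR tables for a panel of reporter constructs with known true TE,
# then check the two assays against each other and the TE ~ poly(U)-length
# relationship.

suppressMessages(library(termstoich))
set.seed(556)

# a 12-construct panel spanning the observed TE range (about 20 - 96 %)
true_te <- setNames(seq(20.7, 96.1, length.out = 12),
                    sprintf("SL%02d", 1:12))

bands <- gen_band_table(true_te, noise_sd = 3, replicates = 3)
qpcr <- gen_qpcr_table(true_te, noise_sd = 0.2, replicates = 3)
te_n <- aggregate_te(bands, "northern")
te_q <- aggregate_te(qpcr_relative_table(qpcr), "qpcr")

write_table(bands, "results/band_intensities.tsv")
write_table(te_n, "results/te_northern.tsv")
write_table(te_q, "results/te_qpcr.tsv")

m <- merge(te_n, te_q, by = "construct_id", suffixes = c("_n", "_q"))
xcor <- correlate(m$te_percent_n, m$te_percent_q)
cat("Northern vs qPCR TE across", nrow(m), "constructs: r2 =",
    round(xcor$r2, 3), "\n")

d <- gen_te_polyU_dataset(200, target_r2 = 0.69)
pu <- correlate(d$polyU_len, d$te_percent)
write_table(d, "results/te_vs_polyU.tsv")
cat("TE ~ poly(U) length calibration: r2 =", round(pu$r2, 3),
    "(slope", round(pu$slope, 2), "% per U)\n")
write_table(data.frame(comparison = c("northern_vs_qpcr", "te_vs_polyU"),
                       r2 = c(xcor$r2, pu$r2),
                       slope = c(xcor$slope, pu$slope),
                       n = c(xcor$n, pu$n)),
            "results/correlations.tsv")
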