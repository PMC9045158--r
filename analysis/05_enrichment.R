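#!/usr/bin/env Rscript
# Positional enrichment of stem-loops: on the simulated survey, and as a
# recomputation from the published survey counts (306 long IRs, 213 with
# stem-loops; 221 in 5'-SBP clusters with 193 hits; promoters 46 vs 45).

suppressMessages(library(termstoich))

clusters <- read_table_tsv("results/clusters.tsv")
irs <- read_table_tsv("results/intergenic_regions.tsv")
hits <- read_table_tsv("results/stemloops.tsv")

long <- irs[irs$is_long, ]
side <- clusters$sbp_position[match(long$cluster_id, clusters$cluster_id)]
hit <- long$ir_id %in% hits$ir_id
n5 <- sum(side == "five_prime"); n3 <- sum(side == "three_prime")
sim <- enrichment_test(n5, n3,
                       sum(hit & side == "five_prime"),
                       sum(hit & side == "three_prime"), "stemloop")
cat("Simulated genome:\n"); print(sim)

paper_sl <- enrichment_test(221, 85, 193, 20, "stemloop")
paper_pr <- enrichment_test(221, 85, 46, 45, "promoter")
cat("Published survey counts:\n"); print(paper_sl); print(paper_pr)

write_table(do.call(rbind, lapply(
  list(simulated_stemloop = sim, survey_stemloop = paper_sl,
       survey_promoter = paper_pr),
  function(e) data.frame(feature = e$feature, n_5p = e$n_5p_IRs,
                         n_3p = e$n_3p_IRs, k_5p = e$k_5p_hits,
                         k_3p = e$k_3p_hits, pct_5p = e$pct_5p,
                         pct_3p = e$pct_3p, direction = e$direction,
                         p_value = e$p_value))),
  "results/enrichment.tsv")
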