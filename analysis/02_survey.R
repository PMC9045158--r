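#!/usr/bin/env Rscript
# Survey the simulated genome for importer clusters, classify them by SBP
# position, and extract strand-aware intergenic regions.

suppressMessages(library(termstoich))

bundle <- read_annotation("results/simulated/genes.gff3",
                          "results/simulated/genome.fasta")
clusters <- find_importer_clusters(bundle)
irs <- extract_all_intergenic_regions(clusters, bundle)
arch <- summarize_architecture(clusters)

dir.create("results", showWarnings = FALSE)
write_table(clusters_table(clusters), "results/clusters.tsv")
write_table(irs, "results/intergenic_regions.tsv")
write_fasta(setNames(irs$sequence, irs$ir_id),
            "results/intergenic_regions.fasta")
write_table(data.frame(bin = names(arch$gap_histogram),
                       count = as.integer(arch$gap_histogram)),
            "results/gap_histogram.tsv")

cat(arch$n_clusters, "clusters;", nrow(irs), "intergenic regions (",
    sum(irs$is_long), "longer than 50 bp)\n")
cat("Cluster positions:", paste(names(arch$position_counts),
                                arch$position_counts, collapse = ", "),
    "\n")
cat("Gap histogram (bimodal: tightly linked pairs vs separated SBPs):\n")
print(arch$gap_histogram)
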