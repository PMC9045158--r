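test_that("generators are deterministic under a fixed seed", {
  set.seed(101); a <- gen_terminator("II")
  set.seed(101); b <- gen_terminator("II")
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$dG, b$dG)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 5, n_clusters = 4)
  g1 <- gen_genome(cfg, out_dir = d1)
  g2 <- gen_genome(cfg, out_dir = d2)
  expect_identical(g1$bundle$contigs, g2$bundle$contigs)
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
  expect_identical(unname(tools::md5sum(file.path(d1, "genome.fasta"))),
                   unname(tools::md5sum(file.path(d2, "genome.fasta"))))
})

test_that("terminator targets land near the requested free energy", {
  set.seed(103)
  gI <- gen_terminator("I", dG_target = -18)
  expect_identical(gI$type, "I")
  expect_lte(abs(gI$dG - (-18)), 2)
  gIV <- gen_terminator("IV", dG_target = -28)
  expect_identical(gIV$type, "IV")
  expect_lte(abs(gIV$dG - (-28)), 2)
  # the emitted structure always passes its own classification check
  expect_identical(classify_type(gI$features), "I")
  expect_identical(classify_type(gIV$features), "IV")
})

test_that("generated genomes round-trip through files and the survey", {
  d <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 13, n_clusters = 8)
  gg <- gen_genome(cfg, out_dir = d)
  # file round-trip reproduces the in-memory bundle
  b2 <- read_annotation(file.path(d, "genes.gff3"),
                        file.path(d, "genome.fasta"))
  expect_identical(b2$contigs, gg$bundle$contigs)
  expect_identical(b2$genes[, c("gene_id", "start", "end", "strand",
                                "role")],
                   gg$bundle$genes[, c("gene_id", "start", "end", "strand",
                                       "role")])
  # the survey recovers the embedded clusters exactly
  cl <- find_importer_clusters(b2)
  ct <- clusters_table(cl)
  expect_identical(nrow(ct), nrow(gg$truth))
  expect_identical(ct$arrangement, gg$truth$arrangement)
  expect_identical(ct$sbp_position, gg$truth$sbp_position)
  expect_identical(ct$strand, gg$truth$strand)
})

test_that("an empty genome config is valid", {
  gg <- gen_genome(synthetic_config(seed = 3, n_clusters = 0))
  expect_identical(nrow(gg$bundle$genes), 0L)
  expect_length(find_importer_clusters(gg$bundle), 0)
})

test_that("embedded terminator IRs are long and carry the terminator", {
  cfg <- synthetic_config(seed = 17, n_clusters = 12)
  gg <- gen_genome(cfg)
  with_term <- gg$truth[gg$truth$terminator_type != "none", ]
  expect_gt(nrow(with_term), 0)
  expect_true(all(with_term$ir_len > 50))
  cl <- find_importer_clusters(gg$bundle)
  irs <- extract_all_intergenic_regions(cl, gg$bundle)
  sbp_irs <- irs[irs$context == "SBP_X", ]
  for (q in seq_len(nrow(with_term))) {
    cid <- sprintf("cluster_%04d", with_term$cluster_index[q])
    seqs <- sbp_irs$sequence[sbp_irs$cluster_id == cid]
    expect_true(any(grepl(with_term$terminator_seq[q], seqs, fixed = TRUE)))
  }
})

test_that("band tables with zero noise return the exact true TE", {
  set.seed(107)
  tab <- gen_band_table(c(a = 20.7, b = 96.1), noise_sd = 0,
                        replicates = 2)
  agg <- aggregate_te(tab, "northern")
  expect_equal(agg$te_percent[agg$construct_id == "a"], 20.7)
  expect_equal(agg$te_percent[agg$construct_id == "b"], 96.1)
  expect_equal(agg$sd_percent, c(0, 0))
})

test_that("poly(U)-length dataset calibration is exact by construction", {
  set.seed(109)
  d <- gen_te_polyU_dataset(200, target_r2 = 0.69)
  expect_identical(nrow(d), 200L)
  expect_true(all(d$polyU_len %in% 0:8))
  r <- correlate(d$polyU_len, d$te_percent)
  expect_equal(r$r2, 0.69, tolerance = 1e-10)

  d1 <- gen_te_polyU_dataset(60, target_r2 = 1)
  expect_equal(correlate(d1$polyU_len, d1$te_percent)$r2, 1)
  d0 <- gen_te_polyU_dataset(60, target_r2 = 0)
  expect_lt(correlate(d0$polyU_len, d0$te_percent)$r2, 1e-20)
})
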