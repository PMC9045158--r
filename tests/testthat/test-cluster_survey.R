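make_bundle <- function(roles, strand = "+", gaps = 30L,
                        glen = 100L, contig_pad = 200L) {
  n <- length(roles)
  gaps <- rep_len(gaps, n - 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- contig_pad
  for (q in seq_len(n)) {
    starts[q] <- pos + 1L
    ends[q] <- pos + glen
    pos <- ends[q] + if (q < n) gaps[q] else 0L
  }
  ctg <- paste(sample(c("A", "C", "G", "T"), pos + contig_pad, TRUE),
               collapse = "")
  ids <- sprintf("t%02d", seq_len(n))
  if (strand == "-") { # transcriptional order = descending coordinates
    roles <- rev(roles)
  }
  genes <- data.frame(gene_id = ids, contig = "c1", start = starts,
                      end = ends, strand = strand, role = roles)
  genome_bundle(c(c1 = ctg), genes)
}

test_that("canonical SBP-TMD-TMD run is one five_prime cluster", {
  set.seed(1)
  b <- make_bundle(c("SBP", "TMD", "TMD"))
  cl <- find_importer_clusters(b)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$arrangement, "SBP-TMD-TMD")
  expect_identical(cl[[1]]$sbp_position, "five_prime")
})

test_that("minus-strand SBP at highest coordinate is still five_prime", {
  set.seed(1)
  b <- make_bundle(c("SBP", "TMD", "TMD"), strand = "-")
  cl <- find_importer_clusters(b)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$sbp_position, "five_prime")
  expect_identical(cl[[1]]$arrangement, "SBP-TMD-TMD")
  # transcriptional order = descending genomic start
  expect_true(all(diff(cl[[1]]$genes$start) < 0))
})

test_that("runs without an SBP, or split by other/gap, are handled", {
  set.seed(1)
  expect_length(find_importer_clusters(make_bundle(c("TMD", "NBD"))), 0)
  # an intervening other-role gene splits the run
  b <- make_bundle(c("SBP", "TMD", "other", "SBP", "NBD"))
  cl <- find_importer_clusters(b)
  expect_length(cl, 2)
  expect_identical(vapply(cl, function(x) x$arrangement, ""),
                   c("SBP-TMD", "SBP-NBD"))
  # a > max_intergene_gap gap splits the run
  b2 <- make_bundle(c("SBP", "TMD", "TMD"), gaps = c(30L, 400L))
  cl2 <- find_importer_clusters(b2)
  expect_length(cl2, 1)
  expect_identical(cl2[[1]]$arrangement, "SBP-TMD")
  # middle and multiple SBP labels
  expect_identical(find_importer_clusters(
    make_bundle(c("TMD", "SBP", "NBD")))[[1]]$sbp_position, "middle")
  expect_identical(find_importer_clusters(
    make_bundle(c("SBP", "TMD", "SBP")))[[1]]$sbp_position, "multiple")
})

test_that("genes belong to at most one cluster and clusters are maximal", {
  set.seed(5)
  cfg <- synthetic_config(seed = 11, n_clusters = 12)
  b <- gen_genome(cfg)$bundle
  cl <- find_importer_clusters(b)
  ids <- unlist(lapply(cl, function(x) x$genes$gene_id))
  expect_false(anyDuplicated(ids) > 0)
  # maximality: the genes adjacent to each cluster (genomically) are not
  # eligible extensions
  g <- b$genes
  for (x in cl) {
    gi <- sort(match(x$genes$gene_id, g$gene_id))
    for (nb in c(min(gi) - 1L, max(gi) + 1L)) {
      if (nb < 1 || nb > nrow(g)) next
      inner <- g[if (nb < min(gi)) min(gi) else max(gi), ]
      outer <- g[nb, ]
      eligible <- outer$role %in% c("SBP", "TMD", "NBD") &&
        outer$strand == inner$strand &&
        abs(ifelse(nb < min(gi), inner$start - outer$end,
                   outer$start - inner$end)) - 1L <= 300L
      expect_false(eligible)
    }
  }
})

test_that("intergenic_gap follows the exclusive-bp sign convention", {
  up <- list(contig = "c", start = 1L, end = 1000L, strand = "+")
  down <- list(contig = "c", start = 1025L, end = 2000L, strand = "+")
  expect_identical(intergenic_gap(up, down), 24L)
  down0 <- list(contig = "c", start = 1001L, end = 2000L, strand = "+")
  expect_identical(intergenic_gap(up, down0), 0L)
  downo <- list(contig = "c", start = 997L, end = 2000L, strand = "+")
  expect_identical(intergenic_gap(up, downo), -4L)
  bad <- list(contig = "c", start = 1025L, end = 2000L, strand = "-")
  expect_error(intergenic_gap(up, bad), "strand")
})

test_that("intergenic regions carry the sense-strand RNA of the gap", {
  set.seed(3)
  b <- make_bundle(c("SBP", "TMD"), gaps = 106L)
  cl <- find_importer_clusters(b)
  irs <- extract_intergenic_regions(cl[[1]], b)
  expect_identical(nrow(irs), 1L)
  expect_identical(irs$gap_bp, 106L)
  expect_identical(nchar(irs$sequence), 106L)
  expect_true(irs$is_long)
  expect_identical(irs$context, "SBP_X")
  g <- cl[[1]]$genes
  plus_slice <- substr(b$contigs[["c1"]], g$end[1] + 1L, g$start[2] - 1L)
  expect_identical(irs$sequence, chartr("T", "U", plus_slice))

  # folding input length equals gap_bp; boundary: exactly 50 is not long
  b50 <- make_bundle(c("SBP", "TMD"), gaps = 50L)
  ir50 <- extract_intergenic_regions(find_importer_clusters(b50)[[1]], b50)
  expect_false(ir50$is_long)

  # minus strand: sequence is the reverse complement of the plus slice
  set.seed(3)
  bm <- make_bundle(c("SBP", "TMD"), gaps = 80L, strand = "-")
  clm <- find_importer_clusters(bm)
  irm <- extract_intergenic_regions(clm[[1]], bm)
  gm <- bm$genes
  slice <- substr(bm$contigs[["c1"]], gm$end[1] + 1L, gm$start[2] - 1L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(slice)))
  expect_identical(irm$sequence, chartr("T", "U", rc))
  expect_identical(irm$context, "SBP_X")
})

test_that("architecture summary counts, bins and handles empty input", {
  set.seed(9)
  cls <- c(find_importer_clusters(make_bundle(c("SBP", "TMD"), gaps = 5L)),
           find_importer_clusters(make_bundle(c("SBP", "TMD"), gaps = 75L)),
           find_importer_clusters(make_bundle(c("TMD", "SBP"), gaps = 70L)))
  s <- summarize_architecture(cls)
  expect_identical(sum(s$position_counts), 3L)
  expect_identical(unname(s$position_counts["five_prime"]), 2L)
  expect_identical(unname(s$position_counts["three_prime"]), 1L)
  expect_identical(sum(s$gap_histogram), 3L)
  expect_identical(unname(s$gap_histogram[["[0,20)"]]), 1L)
  expect_identical(unname(s$gap_histogram[["[60,80)"]]), 2L)
  s0 <- summarize_architecture(list())
  expect_identical(s0$n_clusters, 0L)
  expect_identical(sum(s0$position_counts), 0L)
})

test_that("synthetic genome with bimodal gaps yields a bimodal histogram", {
  cfg <- synthetic_config(seed = 23, n_clusters = 40)
  gg <- gen_genome(cfg)
  cl <- find_importer_clusters(gg$bundle)
  s <- summarize_architecture(cl)
  h <- s$gap_histogram
  # modes in the generator's two components: [0,20) and 60-100
  expect_gt(h[["[0,20)"]], 0)
  long_mass <- sum(h[c("[60,80)", "[80,100)")])
  mid_mass <- sum(h[c("[20,40)", "[40,60)")])
  expect_gt(h[["[0,20)"]], mid_mass)
  expect_gt(long_mass, mid_mass)
})
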