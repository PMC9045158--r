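# shared fixture builders: a tiny two-gene genome written as GFF3 + FASTA
# and as an equivalent GenBank flat file, plus random-sequence helpers

fixture_contig <- function() {
  set.seed(2024)
  paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
}

fixture_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2"), contig = "ctg1",
    start = c(10L, 70L), end = c(39L, 120L),
    strand = c("+", "+"), role = c("SBP", "TMD"),
    stringsAsFactors = FALSE)
}

write_gff3_fixture <- function(dir) {
  ctg <- fixture_contig()
  g <- fixture_genes()
  gff <- file.path(dir, "fix.gff3")
  fa <- file.path(dir, "fix.fasta")
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region ctg1 1 %d", nchar(ctg)),
    sprintf("ctg1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;role=%s",
            g$start, g$end, g$strand, g$gene_id, g$role)), gff)
  writeLines(c(">ctg1", ctg), fa)
  list(gff = gff, fasta = fa, contig = ctg, genes = g)
}

write_genbank_fixture <- function(dir) {
  ctg <- fixture_contig()
  g <- fixture_genes()
  gb <- file.path(dir, "fix.gbk")
  feat <- character()
  for (q in seq_len(nrow(g))) {
    loc <- sprintf("%d..%d", g$start[q], g$end[q])
    if (g$strand[q] == "-") loc <- sprintf("complement(%s)", loc)
    feat <- c(feat,
              sprintf("     gene            %s", loc),
              sprintf('                     /locus_tag="%s"', g$gene_id[q]),
              sprintf('                     /role="%s"', g$role[q]))
  }
  chunks <- substring(tolower(ctg), seq(1, nchar(ctg), 60),
                      pmin(nchar(ctg), seq(60, nchar(ctg) + 59, 60)))
  origin <- sprintf("%9d %s", seq(1, nchar(ctg), 60), chunks)
  writeLines(c(
    sprintf("LOCUS       ctg1 %d bp DNA linear 01-JAN-2024", nchar(ctg)),
    "DEFINITION  synthetic fixture.",
    "FEATURES             Location/Qualifiers",
    feat, "ORIGIN", origin, "//"), gb)
  gb
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
}

# a plain GC hairpin with an appended custom tail, built with pinned pairs
# (no refolding), for feature-extraction tests
gc_hairpin_with_tail <- function(tail, stem = 5L, loop = "AAAA") {
  seq <- paste0(strrep("G", stem), loop, strrep("C", stem), tail)
  pairs <- cbind(1:stem, (stem + nchar(loop) + stem):(stem + nchar(loop) + 1L))
  hairpin_structure(seq, pairs)
}
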