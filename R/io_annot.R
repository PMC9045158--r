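GENE_ROLES <- c("SBP", "TMD", "NBD", "other")

#' Construct a genome bundle
#'
#' A genome bundle holds contig sequences and an annotated gene table with
#' per-gene functional roles. All coordinates are 1-based and inclusive
#' (GFF3 convention) on both strands.
#'
#' @param contigs named character vector of uppercase DNA sequences
#'   (alphabet ACGTN).
#' @param genes data frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand` (`+`/`-`), `role` (one of SBP, TMD, NBD, other).
#' @return A `genome_bundle`: list with `contigs` and `genes`, the gene
#'   table sorted by (contig, start).
#' @export
genome_bundle <- function(contigs, genes) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig ", names(contigs)[bad][1], " contains non-ACGTN characters")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "role")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 1L) || any(genes$end < genes$start))
    stop("gene coordinates must satisfy 1 <= start <= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(genes$role %in% GENE_ROLES))
    stop("role must be one of ", paste(GENE_ROLES, collapse = ", "))
  missing_contig <- setdiff(genes$contig, names(contigs))
  if (length(missing_contig))
    stop("no sequence for annotated contig: ", missing_contig[1])
  too_far <- genes$end > nchar(contigs)[genes$contig]
  if (any(too_far))
    stop("gene ", genes$gene_id[too_far][1], " extends beyond its contig")
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(contigs = contigs, genes = genes), class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle: ", length(x$contigs), " contig(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  print(table(x$genes$role))
  invisible(x)
}

#' Read genome annotation plus sequence into a genome bundle
#'
#' Reads either GFF3 (with a separate FASTA) or a GenBank flat file
#' (sequence embedded). Functional roles are taken, in order of precedence,
#' from `role_table`, from a `role` attribute/qualifier in the annotation,
#' or (if `keyword_fallback = TRUE`) from the product description
#' ("substrate-binding" -> SBP, "permease" -> TMD, "ATP-binding" -> NBD);
#' genes without any mapping get role `other`.
#'
#' @param annotation_path path to a GFF3 or GenBank file (format detected
#'   from content/extension).
#' @param fasta_path path to the genome FASTA (required for GFF3 input).
#' @param role_table optional path to a two-column TSV `gene_id`, `role`.
#' @param feature_type annotation feature type to treat as a gene.
#' @param keyword_fallback assign roles from product keywords when no
#'   explicit role is available (off by default).
#' @return A [genome_bundle()].
#' @export
read_annotation <- function(annotation_path, fasta_path = NULL,
                            role_table = NULL, feature_type = "gene",
                            keyword_fallback = FALSE) {
  if (!file.exists(annotation_path)) stop("no such file: ", annotation_path)
  head1 <- readLines(annotation_path, n = 1L)
  is_genbank <- grepl("^LOCUS", head1)
  if (is_genbank) {
    parsed <- parse_genbank(annotation_path, feature_type = feature_type)
  } else {
    if (is.null(fasta_path))
      stop("fasta_path is required for GFF3 input")
    parsed <- parse_gff3(annotation_path, fasta_path,
                         feature_type = feature_type)
  }
  genes <- parsed$genes
  role <- rep(NA_character_, nrow(genes))
  if (keyword_fallback && !is.null(genes$product)) {
    prod <- tolower(ifelse(is.na(genes$product), "", genes$product))
    role[grepl("atp-binding", prod)] <- "NBD"
    role[grepl("permease", prod)] <- "TMD"
    role[grepl("substrate-binding", prod)] <- "SBP"
  }
  if (!is.null(genes$role_attr))
    role[!is.na(genes$role_attr)] <- genes$role_attr[!is.na(genes$role_attr)]
  if (!is.null(role_table)) {
    rt <- utils::read.delim(role_table, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "role") %in% names(rt)))
      stop("role table needs columns gene_id, role")
    m <- match(genes$gene_id, rt$gene_id)
    role[!is.na(m)] <- rt$role[m[!is.na(m)]]
  }
  role[is.na(role)] <- "other"
  bad <- !role %in% GENE_ROLES
  if (any(bad))
    stop("unknown role '", role[bad][1], "' for gene ",
         genes$gene_id[bad][1])
  genes$role <- role
  genes$role_attr <- NULL
  genes$product <- NULL
  genome_bundle(parsed$contigs, genes)
}

parse_gff3 <- function(gff_path, fasta_path, feature_type = "gene") {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (!length(gr)) stop("no '", feature_type, "' features in ", gff_path)
  mc <- S4Vectors::mcols(gr)
  pick <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]])
         else rep(NA_character_, length(gr))
  gene_id <- pick("ID")
  for (alt in c("locus_tag", "Name", "gene_id"))
    gene_id <- ifelse(is.na(gene_id), pick(alt), gene_id)
  if (anyNA(gene_id)) stop("GFF3 feature without ID/locus_tag/Name")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genes <- data.frame(
    gene_id = gene_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    role_attr = pick("role"),
    product = pick("product"),
    stringsAsFactors = FALSE)
  if (any(genes$strand == "*"))
    stop("GFF3 gene without strand: ",
         genes$gene_id[genes$strand == "*"][1])
  list(contigs = stats::setNames(as.character(seqs), names(seqs)),
       genes = genes)
}

# Minimal GenBank flat-file reader: LOCUS name, gene/CDS features with
# simple or complement() spans, /locus_tag, /gene, /role and /product
# qualifiers, and the ORIGIN sequence block. Coordinates are converted to
# the same 1-based inclusive convention used for GFF3. Multi-record files
# (separated by //) are supported; join() locations are not.
parse_genbank <- function(path, feature_type = "gene") {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  contigs <- character()
  genes_list <- list()
  for (rec in recs) {
    locus <- strsplit(sub("^LOCUS\\s+", "", rec[1]), "\\s+")[[1]][1]
    o <- grep("^ORIGIN", rec)
    if (!length(o)) stop("GenBank record ", locus, " has no ORIGIN block")
    seq_lines <- rec[(o + 1):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seqstr <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[locus] <- seqstr
    f0 <- grep("^FEATURES", rec)
    if (!length(f0)) next
    feat <- rec[(f0 + 1):(o - 1)]
    starts <- grep("^ {5}\\S", feat)
    if (!length(starts)) next
    ends <- c(starts[-1] - 1L, length(feat))
    for (q in seq_along(starts)) {
      block <- feat[starts[q]:ends[q]]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (!key %in% feature_type) next
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))
      if (!length(span)) stop("unsupported GenBank location: ", loc)
      se <- as.integer(strsplit(span, "..", fixed = TRUE)[[1]])
      qual <- function(nm) {
        hit <- grep(paste0("^\\s+/", nm, "="), block, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^\\s+/[a-z_]+="?|"$', "", hit[1])
      }
      gid <- qual("locus_tag")
      if (is.na(gid)) gid <- qual("gene")
      if (is.na(gid)) stop("GenBank feature without locus_tag/gene in ",
                           locus)
      genes_list[[length(genes_list) + 1L]] <- data.frame(
        gene_id = gid, contig = locus, start = se[1], end = se[2],
        strand = strand, role_attr = qual("role"), product = qual("product"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(genes_list)) stop("no gene features found in ", path)
  list(contigs = contigs, genes = do.call(rbind, genes_list))
}

#' Fetch the genomic (sense-strand) sequence of one gene
#'
#' @param bundle a [genome_bundle()].
#' @param gene_id gene identifier.
#' @return DNA string; for `-` strand genes the reverse complement of the
#'   plus-strand slice, i.e. the coding-orientation sequence.
#' @export
gene_sequence <- function(bundle, gene_id) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id)
  s <- substr(bundle$contigs[[g$contig]], g$start, g$end)
  if (g$strand == "-") s <- revcomp_dna(s)
  s
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

dna_to_rna <- function(s) chartr("T", "U", s)

#' Reverse-complement every contig of a bundle, remapping gene coordinates
#'
#' Utility for strand-symmetry testing: the survey of the mirrored genome
#' must recover identical clusters, arrangements and intergenic sequences.
#'
#' @param bundle a [genome_bundle()].
#' @return A new [genome_bundle()] on the mirrored coordinates.
#' @export
reverse_complement_bundle <- function(bundle) {
  L <- nchar(bundle$contigs)
  contigs <- vapply(bundle$contigs, revcomp_dna, character(1))
  genes <- bundle$genes
  len <- L[genes$contig]
  new_start <- len - genes$end + 1L
  new_end <- len - genes$start + 1L
  genes$start <- as.integer(new_start)
  genes$end <- as.integer(new_end)
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  genome_bundle(contigs, genes)
}

#' Write a tabular result as TSV
#'
#' TSV with a header row, stable column order, no quoting or row names.
#' Numeric columns keep full precision (at least 4 significant digits). An
#' empty table writes a header-only file.
#'
#' @param records data frame (possibly zero rows).
#' @param path output path.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to missing directory: ", dir)
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write intergenic-region (or any) sequences as FASTA
#' @param seqs named character vector of sequences (DNA or RNA letters).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs))
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  invisible(path)
}
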