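#' Detect ABC-importer gene clusters around substrate-binding proteins
#'
#' Scans the sorted gene table for maximal runs of adjacent, same-strand
#' genes whose roles are all transporter components (SBP, TMD, NBD), with
#' no intervening `other`-role gene and no intergenic gap larger than
#' `max_intergene_gap`. Runs with at least two genes and at least one SBP
#' are emitted as clusters; gene order within a cluster is transcriptional
#' (descending genomic coordinates on the `-` strand). Each cluster is
#' labelled by the position of its SBP: `five_prime`, `middle`,
#' `three_prime`, or `multiple` when it carries more than one SBP.
#'
#' @param bundle a [genome_bundle()].
#' @param max_intergene_gap largest allowed gap (exclusive bp) between
#'   consecutive cluster genes (default 300).
#' @param max_genes largest cluster size emitted (default 6); longer runs
#'   are discarded with a warning.
#' @return List of `gene_cluster` objects; each has `cluster_id`, `contig`,
#'   `strand`, `genes` (data frame in transcriptional order), `arrangement`
#'   (e.g. "SBP-TMD-TMD") and `sbp_position`.
#' @export
find_importer_clusters <- function(bundle, max_intergene_gap = 300L,
                                   max_genes = 6L) {
  g <- bundle$genes
  clusters <- list()
  if (!nrow(g)) return(clusters)
  transporter <- g$role %in% c("SBP", "TMD", "NBD")
  brk <- c(TRUE, g$contig[-1] != g$contig[-nrow(g)] |
                 g$strand[-1] != g$strand[-nrow(g)] |
                 (g$start[-1] - g$end[-nrow(g)] - 1L) > max_intergene_gap)
  brk <- brk | !transporter
  run_id <- cumsum(brk)
  run_id[!transporter] <- NA
  idx <- which(!is.na(run_id))
  n_emit <- 0L
  for (r in unique(run_id[idx])) {
    members <- which(run_id %in% r)
    if (length(members) < 2L) next
    genes <- g[members, , drop = FALSE]
    if (!any(genes$role == "SBP")) next
    if (length(members) > max_genes) {
      warning("run of ", length(members), " transporter genes at ",
              genes$gene_id[1], " exceeds max_genes = ", max_genes,
              "; not emitted")
      next
    }
    strand <- genes$strand[1]
    if (strand == "-") genes <- genes[rev(seq_len(nrow(genes))), ,
                                      drop = FALSE]
    rownames(genes) <- NULL
    n_sbp <- sum(genes$role == "SBP")
    sbp_position <- if (n_sbp > 1L) "multiple"
      else if (genes$role[1] == "SBP") "five_prime"
      else if (genes$role[nrow(genes)] == "SBP") "three_prime"
      else "middle"
    n_emit <- n_emit + 1L
    clusters[[n_emit]] <- structure(list(
      cluster_id = sprintf("cluster_%04d", n_emit),
      contig = genes$contig[1], strand = strand, genes = genes,
      arrangement = paste(genes$role, collapse = "-"),
      sbp_position = sbp_position), class = "gene_cluster")
  }
  clusters
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(x$cluster_id, " [", x$contig, x$strand, "] ", x$arrangement,
      " (SBP: ", x$sbp_position, ")\n", sep = "")
  invisible(x)
}

#' Flatten a cluster list to one row per cluster
#' @param clusters list from [find_importer_clusters()].
#' @return data frame: cluster_id, contig, strand, n_genes, arrangement,
#'   sbp_position, gene_ids (comma-separated, transcriptional order).
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster_id = character(), contig = character(),
                      strand = character(), n_genes = integer(),
                      arrangement = character(), sbp_position = character(),
                      gene_ids = character()))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, contig = cl$contig, strand = cl$strand,
    n_genes = nrow(cl$genes), arrangement = cl$arrangement,
    sbp_position = cl$sbp_position,
    gene_ids = paste(cl$genes$gene_id, collapse = ","))))
}

#' Transcription-oriented gap between two adjacent genes
#'
#' Gap in exclusive bp between an upstream and a downstream gene in
#' transcriptional order: `start(downstream) - end(upstream) - 1` in
#' transcription-oriented coordinates. Abutting genes give 0; overlapping
#' genes give a negative value.
#'
#' @param upstream,downstream one-row data frames (or lists) with `contig`,
#'   `start`, `end`, `strand`.
#' @return Integer gap in bp (possibly negative).
#' @export
intergenic_gap <- function(upstream, downstream) {
  if (!identical(as.character(upstream$contig),
                 as.character(downstream$contig)))
    stop("genes on different contigs")
  if (!identical(as.character(upstream$strand),
                 as.character(downstream$strand)))
    stop("genes on different strands")
  if (upstream$strand == "+")
    as.integer(downstream$start - upstream$end - 1L)
  else
    as.integer(upstream$start - downstream$end - 1L)
}

#' Extract intergenic regions of a cluster as sense-strand RNA
#'
#' One region per adjacent gene pair with a positive gap. The sequence is
#' the transcribed (sense) strand of the gap as RNA: the plus-strand slice
#' with T->U for `+` clusters, its reverse complement for `-` clusters.
#' `is_long` flags regions longer than 50 bp (strict), the gate used when
#' scanning for stem-loops. The `context` records which flanking gene is
#' the SBP: `SBP_X` (upstream SBP), `X_SBP` (downstream SBP), `TMD_NBD`
#' (both flanks translocator components), else `other`.
#'
#' @param cluster a `gene_cluster`.
#' @param bundle the [genome_bundle()] the cluster came from.
#' @return data frame: ir_id, cluster_id, upstream_gene, downstream_gene,
#'   upstream_role, downstream_role, gap_bp, sequence, is_long, context.
#' @export
extract_intergenic_regions <- function(cluster, bundle) {
  genes <- cluster$genes
  out <- list()
  for (q in seq_len(nrow(genes) - 1L)) {
    up <- genes[q, ]; down <- genes[q + 1L, ]
    gap <- intergenic_gap(up, down)
    if (gap < 1L) next
    if (cluster$strand == "+") {
      dna <- substr(bundle$contigs[[cluster$contig]], up$end + 1L,
                    down$start - 1L)
    } else {
      dna <- substr(bundle$contigs[[cluster$contig]], down$end + 1L,
                    up$start - 1L)
      dna <- revcomp_dna(dna)
    }
    context <- if (up$role == "SBP") "SBP_X"
      else if (down$role == "SBP") "X_SBP"
      else if (all(c(up$role, down$role) %in% c("TMD", "NBD"))) "TMD_NBD"
      else "other"
    out[[length(out) + 1L]] <- data.frame(
      ir_id = paste0(cluster$cluster_id, ":", up$gene_id, "-",
                     down$gene_id),
      cluster_id = cluster$cluster_id,
      upstream_gene = up$gene_id, downstream_gene = down$gene_id,
      upstream_role = up$role, downstream_role = down$role,
      gap_bp = gap, sequence = dna_to_rna(dna), is_long = gap > 50L,
      context = context, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ir_id = character(), cluster_id = character(),
                      upstream_gene = character(),
                      downstream_gene = character(),
                      upstream_role = character(),
                      downstream_role = character(), gap_bp = integer(),
                      sequence = character(), is_long = logical(),
                      context = character()))
  do.call(rbind, out)
}

#' Intergenic regions for a whole cluster list
#' @param clusters list from [find_importer_clusters()].
#' @param bundle the source [genome_bundle()].
#' @return data frame, rbind of [extract_intergenic_regions()] per cluster.
#' @export
extract_all_intergenic_regions <- function(clusters, bundle) {
  do.call(rbind, c(lapply(clusters, extract_intergenic_regions,
                          bundle = bundle),
                   make.row.names = FALSE))
}

#' Summarize cluster architecture
#'
#' Counts of clusters per SBP position and per arrangement, a histogram of
#' all within-cluster adjacent-gene gaps in 20-bp bins (plus a `<0` bin for
#' overlaps), and the mean gap per flanking-gene context.
#'
#' @param clusters list from [find_importer_clusters()].
#' @return list with `n_clusters`, `position_counts`, `arrangement_counts`,
#'   `gap_histogram` (named integer vector), `mean_gap_by_context`.
#' @export
summarize_architecture <- function(clusters) {
  positions <- c("five_prime", "middle", "three_prime", "multiple")
  pos <- vapply(clusters, function(cl) cl$sbp_position, character(1))
  arr <- vapply(clusters, function(cl) cl$arrangement, character(1))
  gaps <- integer(); ctx <- character()
  for (cl in clusters) {
    genes <- cl$genes
    for (q in seq_len(nrow(genes) - 1L)) {
      up <- genes[q, ]; down <- genes[q + 1L, ]
      gaps <- c(gaps, intergenic_gap(up, down))
      ctx <- c(ctx, if (up$role == "SBP") "SBP_X"
               else if (down$role == "SBP") "X_SBP"
               else if (all(c(up$role, down$role) %in% c("TMD", "NBD")))
                 "TMD_NBD" else "other")
    }
  }
  hi <- if (length(gaps)) max(20L, 20L * ceiling((max(gaps) + 1L) / 20L))
        else 20L
  edges <- seq(0L, hi, by = 20L)
  labs <- c("<0", paste0("[", edges[-length(edges)], ",",
                         edges[-1], ")"))
  bin <- ifelse(gaps < 0L, 0L, pmin(gaps %/% 20L, length(edges) - 2L) + 1L)
  histo <- stats::setNames(tabulate(bin + 1L, nbins = length(labs)), labs)
  list(
    n_clusters = length(clusters),
    position_counts = stats::setNames(
      as.integer(table(factor(pos, levels = positions))), positions),
    arrangement_counts = if (length(arr)) sort(table(arr),
                                               decreasing = TRUE)
                         else table(character()),
    gap_histogram = histo,
    mean_gap_by_context = if (length(gaps))
      tapply(gaps, ctx, mean) else stats::setNames(numeric(), character())
  )
}
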