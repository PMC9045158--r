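#' Run the full survey -> fold -> classify -> enrichment pipeline
#'
#' Thin orchestrator over the module functions: reads (or receives) an
#' annotated genome, surveys importer clusters, extracts intergenic
#' regions, scans the long ones for stem-loops, classifies terminator
#' types, optionally computes the positional enrichment of stem-loops and
#' promoters, and writes every stage table plus a run manifest with file
#' checksums. Reruns with the same inputs and config are byte-identical.
#'
#' @param config list with elements: either `bundle` (a [genome_bundle()])
#'   or `gff3` + `fasta` (+ optional `roles` TSV) paths; `out_dir`
#'   (required); optional `promoter_scores` (TSV ir_id, score), `seed`
#'   (recorded in the manifest; default 1), `dG_threshold` (default -10),
#'   `max_intergene_gap` (300), `promoter_cutoff` (0.9), and
#'   `classify` (a [classify_config()]).
#' @return Invisibly, a list with `clusters`, `irs`, `calls`, `enrichment`
#'   (possibly NULL), and `manifest` (data frame file, md5).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  params <- if (is.null(config$params)) energy_params() else config$params
  ccfg <- if (is.null(config$classify)) classify_config() else
    config$classify
  dG_threshold <- if (is.null(config$dG_threshold)) -10 else
    config$dG_threshold
  max_gap <- if (is.null(config$max_intergene_gap)) 300L else
    config$max_intergene_gap

  bundle <- if (!is.null(config$bundle)) config$bundle else {
    if (is.null(config$gff3) || is.null(config$fasta))
      stop("config needs either a bundle or gff3 + fasta paths")
    read_annotation(config$gff3, config$fasta, role_table = config$roles)
  }

  clusters <- find_importer_clusters(bundle, max_intergene_gap = max_gap)
  irs <- extract_all_intergenic_regions(clusters, bundle)
  scan <- scan_ir_table(irs, params = params, dG_threshold = dG_threshold)
  calls <- lapply(scan$structures, terminator_call, config = ccfg)

  files <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    files <<- c(files, p)
  }
  emit(clusters_table(clusters), "clusters.tsv")
  ir_out <- irs
  emit(ir_out, "intergenic_regions.tsv")
  if (nrow(irs)) {
    fa <- file.path(out_dir, "intergenic_regions.fasta")
    write_fasta(stats::setNames(irs$sequence, irs$ir_id), fa)
    files <- c(files, fa)
  }
  arch <- summarize_architecture(clusters)
  emit(data.frame(metric = c(
         paste0("n_clusters"),
         paste0("sbp_", names(arch$position_counts)),
         paste0("gap_", names(arch$gap_histogram))),
       value = c(arch$n_clusters, arch$position_counts,
                 arch$gap_histogram)),
       "architecture_summary.tsv")
  emit(scan$table, "stemloops.tsv")
  emit(calls_table(calls), "terminator_calls.tsv")

  enrichment <- NULL
  if (nrow(irs)) {
    pos <- vapply(clusters, function(cl) cl$sbp_position, character(1))
    names(pos) <- vapply(clusters, function(cl) cl$cluster_id, character(1))
    long <- irs[irs$is_long, , drop = FALSE]
    side <- pos[long$cluster_id]
    hit <- long$ir_id %in% names(scan$structures)
    n5 <- sum(side == "five_prime"); n3 <- sum(side == "three_prime")
    k5 <- sum(hit & side == "five_prime")
    k3 <- sum(hit & side == "three_prime")
    if (n5 > 0 && n3 > 0) {
      enrichment <- list(stemloop = enrichment_test(n5, n3, k5, k3,
                                                    "stemloop"))
      if (!is.null(config$promoter_scores)) {
        sc <- read_table_tsv(config$promoter_scores)
        cutoff <- if (is.null(config$promoter_cutoff)) 0.9 else
          config$promoter_cutoff
        prom <- long$ir_id %in% promoter_positive_irs(sc, cutoff)
        enrichment$promoter <- enrichment_test(
          n5, n3, sum(prom & side == "five_prime"),
          sum(prom & side == "three_prime"), "promoter")
      }
      enr_df <- do.call(rbind, lapply(enrichment, function(e) data.frame(
        feature = e$feature, n_5p = e$n_5p_IRs, n_3p = e$n_3p_IRs,
        k_5p = e$k_5p_hits, k_3p = e$k_3p_hits, pct_5p = e$pct_5p,
        pct_3p = e$pct_3p, direction = e$direction, p_value = e$p_value)))
      emit(enr_df, "enrichment.tsv")
    }
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  attr(manifest, "seed") <- seed
  man_df <- rbind(manifest,
                  data.frame(file = "__seed__", md5 = as.character(seed)),
                  data.frame(file = "__params__",
                             md5 = params$version_tag))
  write_table(man_df, file.path(out_dir, "manifest.tsv"))
  invisible(list(clusters = clusters, irs = irs, calls = calls,
                 enrichment = enrichment, manifest = manifest))
}
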