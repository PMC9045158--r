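#' Configuration for the synthetic genome / measurement generator
#'
#' Defaults emulate the study conditions of the operon survey: most
#' clusters carry the SBP gene at the 5' end, the commonest arrangement is
#' SBP followed by two permease (TMD) genes, within-cluster gaps follow a
#' bimodal mixture with peaks at 0-20 bp (tightly linked genes) and
#' 60-100 bp (separated SBPs), terminator folding energies fall in the
#' observed -38 .. -10 kcal/mol range, and measurement tables are generated
#' in triplicate with modest noise.
#'
#' @param seed integer RNG seed recorded with the config.
#' @param n_clusters number of importer clusters to embed.
#' @param sbp_position_mix probabilities over
#'   `c(five_prime, middle, three_prime)`.
#' @param arrangement_mix probabilities over translocator-body layouts
#'   (the SBP is then placed according to the position draw).
#' @param gap_model list `short` (range bp), `long` (range bp), `w_long`
#'   (weight of the long mode) for SBP-flanking gaps.
#' @param terminator_type_mix probabilities over `c(I, II, III, IV, none)`
#'   for the element embedded downstream of the SBP.
#' @param dG_window allowed terminator folding-energy window, kcal/mol.
#' @param dG_means per-type mean target free energies, kcal/mol.
#' @param te_noise_sd additive intensity noise, percent scale.
#' @param qpcr_noise_sd Ct noise, cycles.
#' @param background_gc GC content of intergenic background sequence.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_clusters = 30L,
    sbp_position_mix = c(five_prime = 0.70, middle = 0.03,
                         three_prime = 0.27),
    arrangement_mix = c("TMD-TMD" = 0.50, "TMD-NBD" = 0.20,
                        "TMD-TMD-NBD" = 0.20, "TMD-TMD-NBD-NBD" = 0.10),
    gap_model = list(short = c(0L, 20L), long = c(61L, 100L),
                     w_long = 0.5),
    terminator_type_mix = c(I = 0.11, II = 0.41, III = 0.29, IV = 0.08,
                            none = 0.11),
    dG_window = c(-38, -10),
    dG_means = c(I = -18, II = -22, III = -25, IV = -28),
    te_noise_sd = 3,
    qpcr_noise_sd = 0.2,
    background_gc = 0.35) {
  stopifnot(abs(sum(sbp_position_mix) - 1) < 1e-8,
            abs(sum(arrangement_mix) - 1) < 1e-8,
            abs(sum(terminator_type_mix) - 1) < 1e-8,
            dG_window[1] >= -40, dG_window[2] <= -10,
            all(dG_means >= dG_window[1] & dG_means <= dG_window[2]))
  structure(as.list(environment()), class = "synthetic_config")
}

rand_dna <- function(n, gc = 0.35) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rand_rna <- function(n, gc = 0.35) chartr("T", "U", rand_dna(n, gc))

revcomp_rna <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# one candidate terminator sequence for a given type and inner-stem size;
# returns the RNA string (design only; acceptance is by refold + classify)
terminator_template <- function(type, stem_bp) {
  gc_arm <- function(n) paste(sample(c("G", "C", "A", "U"), n, TRUE,
                                     prob = c(.45, .35, .1, .1)),
                              collapse = "")
  nonU <- function(n) paste(sample(c("A", "G", "C"), n, TRUE), collapse = "")
  loop <- paste(sample(c("A", "G", "C", "U"), 4, TRUE,
                       prob = c(.5, .2, .2, .1)), collapse = "")
  arm5 <- gc_arm(stem_bp)
  core <- paste0(arm5, loop, revcomp_rna(arm5))
  if (type == "I") {
    return(paste0(core, strrep("U", sample(6:8, 1)), nonU(3)))
  }
  if (type == "II") {
    # 8 nt tail, 3-4 scattered U in the first 7, no run > 2
    repeat {
      u <- sample(3:4, 1)
      pos <- sort(sample(1:7, u))
      tail <- strsplit(nonU(8), "", fixed = TRUE)[[1]]
      tail[pos] <- "U"
      r <- rle(tail == "U")
      if (max(r$lengths[r$values]) <= 2) break
    }
    return(paste0(core, paste(tail, collapse = "")))
  }
  # Types III / IV: outer helix (distal arm) - small unpaired region -
  # inner GC-rich stem; the 3' strand of the outer helix is the putative
  # U-rich tract (U-rich for III, U-poor for IV)
  if (type == "III") {
    d <- sample(2:3, 1)
    o5 <- c(sample(c("A", "G"), 1, prob = c(.4, .6)), rep("A", d - 1))
  } else {
    d <- sample(6:7, 1)
    o5 <- sample(c("G", "C"), d, TRUE)          # no A -> no U in tract
  }
  o5 <- paste(o5, collapse = "")
  o3 <- revcomp_rna(o5)
  defect <- sample(c("int11", "bulge5", "bulge3"), 1,
                   prob = c(.6, .2, .2))
  x5 <- switch(defect, int11 = "A", bulge5 = "A", bulge3 = "")
  x3 <- switch(defect, int11 = "C", bulge5 = "", bulge3 = "A")
  tail <- if (type == "III") paste0("U", nonU(7)) else nonU(8)
  paste0(o5, x5, arm5, loop, revcomp_rna(arm5), x3, o3, tail)
}

#' Generate one terminator of a requested structural type
#'
#' Constructive templates (GC-rich stem; type-specific 3' tract and stem
#' defect) tuned so the refolded minimum-free-energy structure lands within
#' +/- `dG_tol` kcal/mol of `dG_target`, then rejection-sampled against the
#' real folding and classification stack: the emitted sequence always
#' refolds to a structure classified as the requested type. Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param type `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param dG_target target folding energy, kcal/mol (defaults to the
#'   type's mean in [synthetic_config()]).
#' @param params an [energy_params()] object.
#' @param config a [classify_config()].
#' @param dG_tol acceptance half-width around `dG_target`, kcal/mol.
#' @param max_attempts templates tried before giving up (error).
#' @return list: `sequence` (RNA), `structure` (refolded
#'   `hairpin_structure`), `features`, `type`, `dG`, `dG_target`.
#' @export
gen_terminator <- function(type = c("I", "II", "III", "IV"),
                           dG_target = NULL, params = energy_params(),
                           config = classify_config(), dG_tol = 2,
                           max_attempts = 100L) {
  type <- match.arg(type)
  if (is.null(dG_target))
    dG_target <- synthetic_config()$dG_means[[type]]
  for (attempt in seq_len(max_attempts)) {
    best <- NULL
    for (s in 4:16) {
      cand <- terminator_template(type, s)
      st <- min_hairpin(cand, params = params)
      if (is.null(st)) next
      if (is.null(best) || abs(st$dG - dG_target) < abs(best$dG - dG_target))
        best <- list(seq = cand, st = st, dG = st$dG)
      if (abs(st$dG - dG_target) <= dG_tol) break
    }
    if (is.null(best) || abs(best$dG - dG_target) > dG_tol) next
    feats <- extract_features(best$st, config)
    if (classify_type(feats, config) == type)
      return(list(sequence = best$seq, structure = best$st,
                  features = feats, type = type, dG = best$dG,
                  dG_target = dG_target))
  }
  stop("could not generate a type ", type, " terminator at dG ", dG_target,
       " +/- ", dG_tol, " kcal/mol in ", max_attempts, " attempts")
}

draw_gap <- function(gap_model) {
  rng <- if (stats::runif(1) < gap_model$w_long) gap_model$long
         else gap_model$short
  sample(rng[1]:rng[2], 1)
}

#' Generate a synthetic annotated genome with embedded importer clusters
#'
#' Builds one contig carrying `n_clusters` ABC-importer gene clusters on
#' random strands, separated by long spacers and occasional non-transporter
#' genes. Each cluster's SBP position and gene arrangement follow the
#' configured mixes; when a terminator type is drawn, a [gen_terminator()]
#' sequence is embedded (with AT-rich flanks) in the intergenic region
#' downstream of the SBP, which is then always longer than 50 bp.
#' Ground truth for every cluster is returned for recovery testing.
#'
#' @param config a [synthetic_config()]; `config$seed` seeds the RNG, so
#'   identical configs give byte-identical output.
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `genes.gff3` and `ground_truth.tsv`.
#' @param params an [energy_params()] object for terminator generation.
#' @return list: `bundle` (a [genome_bundle()]), `truth` (data frame, one
#'   row per cluster), `paths` (named character, if written).
#' @export
gen_genome <- function(config = synthetic_config(), out_dir = NULL,
                       params = energy_params()) {
  set.seed(config$seed)
  contig_name <- "synth_contig_1"
  parts <- character()           # sequence blocks, 5'->3' on plus strand
  offset <- 0L
  genes <- list(); truth <- list()
  gene_n <- 0L; other_n <- 0L
  add_part <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  add_part(rand_dna(sample(400:800, 1), config$background_gc))
  for (ci in seq_len(config$n_clusters)) {
    sbp_pos <- sample(names(config$sbp_position_mix), 1,
                      prob = config$sbp_position_mix)
    body <- strsplit(sample(names(config$arrangement_mix), 1,
                            prob = config$arrangement_mix), "-")[[1]]
    roles <- switch(sbp_pos,
      five_prime = c("SBP", body),
      three_prime = c(body, "SBP"),
      middle = append(body, "SBP", after = 1L))
    strand <- sample(c("+", "-"), 1)
    sbp_idx <- which(roles == "SBP")
    term_type <- if (sbp_idx < length(roles))
      sample(names(config$terminator_type_mix), 1,
             prob = config$terminator_type_mix) else "none"
    term <- NULL
    if (term_type != "none") {
      dG_target <- max(config$dG_window[1],
                       min(config$dG_window[2],
                           stats::rnorm(1, config$dG_means[[term_type]], 2)))
      term <- gen_terminator(term_type, dG_target, params = params)
    }
    # assemble the cluster in transcription orientation
    block <- ""
    starts <- integer(length(roles)); ends <- integer(length(roles))
    ir_len <- NA_integer_
    for (q in seq_along(roles)) {
      if (q > 1) {
        if (q == sbp_idx + 1L && !is.null(term)) {
          left <- rand_dna(sample(8:15, 1), 0.2)
          term_dna <- chartr("U", "T", term$sequence)
          min_len <- nchar(left) + nchar(term_dna) + 5L
          gap_len <- max(61L, min_len,
                         sample(config$gap_model$long[1]:
                                config$gap_model$long[2], 1))
          right <- rand_dna(gap_len - nchar(left) - nchar(term_dna), 0.2)
          gap_seq <- paste0(left, term_dna, right)
          ir_len <- nchar(gap_seq)
        } else if (roles[q - 1] != "SBP" && roles[q] != "SBP" ) {
          gap_seq <- rand_dna(sample(config$gap_model$short[1]:
                                     config$gap_model$short[2], 1),
                              config$background_gc)
        } else {
          gap_seq <- rand_dna(draw_gap(config$gap_model),
                              config$background_gc)
        }
        block <- paste0(block, gap_seq)
      }
      glen <- sample(600:1500, 1)
      starts[q] <- nchar(block) + 1L
      block <- paste0(block, rand_dna(glen, 0.45))
      ends[q] <- nchar(block)
    }
    # place on the contig; map coordinates for minus-strand clusters
    if (strand == "-") {
      blen <- nchar(block)
      new_starts <- blen - ends + 1L
      new_ends <- blen - starts + 1L
      starts <- new_starts; ends <- new_ends
      block <- chartr("ACGT",
                      "TGCA",
                      paste(rev(strsplit(block, "", fixed = TRUE)[[1]]),
                            collapse = ""))
    }
    for (q in seq_along(roles)) {
      gene_n <- gene_n + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("sg%04d", gene_n), contig = contig_name,
        start = offset + starts[q], end = offset + ends[q],
        strand = strand, role = roles[q], stringsAsFactors = FALSE)
    }
    truth[[ci]] <- data.frame(
      cluster_index = ci, strand = strand, sbp_position = sbp_pos,
      arrangement = paste(roles, collapse = "-"),
      terminator_type = term_type,
      terminator_seq = if (is.null(term)) NA_character_ else term$sequence,
      terminator_dG = if (is.null(term)) NA_real_ else term$dG,
      ir_len = ir_len, stringsAsFactors = FALSE)
    add_part(block)
    # spacer (> 300 bp so clusters never chain), sometimes with a
    # non-transporter gene in the middle
    add_part(rand_dna(sample(400:800, 1), config$background_gc))
    if (stats::runif(1) < 0.3) {
      other_n <- other_n + 1L
      glen <- sample(600:1200, 1)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("so%04d", other_n), contig = contig_name,
        start = offset + 1L, end = offset + glen,
        strand = sample(c("+", "-"), 1), role = "other",
        stringsAsFactors = FALSE)
      add_part(rand_dna(glen, 0.45))
      add_part(rand_dna(sample(400:800, 1), config$background_gc))
    }
  }
  contig <- paste(parts, collapse = "")
  gene_df <- if (length(genes)) do.call(rbind, genes)
    else data.frame(gene_id = character(), contig = character(),
                    start = integer(), end = integer(),
                    strand = character(), role = character())
  bundle <- genome_bundle(stats::setNames(contig, contig_name), gene_df)
  truth_df <- if (length(truth)) do.call(rbind, truth)
    else data.frame(cluster_index = integer())
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(fasta = file.path(out_dir, "genome.fasta"),
               gff3 = file.path(out_dir, "genes.gff3"),
               truth = file.path(out_dir, "ground_truth.tsv"))
    write_fasta(stats::setNames(contig, contig_name), paths[["fasta"]])
    write_gff3(bundle, paths[["gff3"]])
    write_table(truth_df, paths[["truth"]])
  }
  list(bundle = bundle, truth = truth_df, paths = paths)
}

#' Write a bundle's gene table as GFF3
#' @param bundle a [genome_bundle()].
#' @param path output path.
#' @export
write_gff3 <- function(bundle, path) {
  g <- bundle$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in unique(g$contig))
    writeLines(sprintf("##sequence-region %s 1 %d", ct,
                       nchar(bundle$contigs[[ct]])), con)
  if (nrow(g))
    writeLines(sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;role=%s",
                       g$contig, g$start, g$end, g$strand, g$gene_id,
                       g$role), con)
  invisible(path)
}

#' Synthetic Northern-blot band-intensity table with known true TE
#'
#' Per construct and replicate, `I_mono = TE + e1` and
#' `I_bi = (100 - TE) + e2` with independent Gaussian noise (sd
#' `noise_sd`), truncated at 0, on an arbitrary intensity scale; with zero
#' noise [te_from_bands()] returns the true TE exactly.
#'
#' @param true_te named numeric vector, construct -> true TE percent.
#' @param noise_sd additive noise sd (percent-scale intensity units).
#' @param replicates replicates per construct.
#' @return data frame: construct_id, probe, I_mono, I_bi, replicate.
#' @export
gen_band_table <- function(true_te, noise_sd = 3, replicates = 3L) {
  out <- list()
  for (id in names(true_te)) {
    te <- true_te[[id]]
    for (r in seq_len(replicates)) {
      out[[length(out) + 1L]] <- data.frame(
        construct_id = id, probe = "fbfp",
        I_mono = max(0, te + stats::rnorm(1, 0, noise_sd)),
        I_bi = max(0, (100 - te) + stats::rnorm(1, 0, noise_sd)),
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Synthetic qPCR Ct table for the dual-reporter system
#'
#' Models the upstream reporter at a fixed relative level of 1 and the
#' downstream reporter at `1 - TE/100` (floored at 0.001), converts levels
#' to Ct against a reference gene at `ref_Ct`, and adds Gaussian Ct noise.
#'
#' @param true_te named numeric vector, construct -> true TE percent.
#' @param noise_sd Ct noise, cycles.
#' @param replicates replicates per construct.
#' @param ref_Ct reference-gene Ct.
#' @param efficiency amplification factor per cycle.
#' @return data frame: construct_id, gene (fbfp/mcherry/reference), Ct,
#'   replicate.
#' @export
gen_qpcr_table <- function(true_te, noise_sd = 0.2, replicates = 3L,
                           ref_Ct = 18, efficiency = 2.0) {
  out <- list()
  for (id in names(true_te)) {
    lf <- 1
    lm <- max(0.001, 1 - true_te[[id]] / 100)
    for (r in seq_len(replicates)) {
      cts <- c(reference = ref_Ct + stats::rnorm(1, 0, noise_sd),
               fbfp = ref_Ct - log(lf, efficiency) +
                 stats::rnorm(1, 0, noise_sd),
               mcherry = ref_Ct - log(lm, efficiency) +
                 stats::rnorm(1, 0, noise_sd))
      out[[length(out) + 1L]] <- data.frame(
        construct_id = id, gene = names(cts), Ct = unname(cts),
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reshape a long qPCR Ct table to per-replicate relative levels
#'
#' Normalizes fbfp and mcherry Cts against the reference gene within each
#' construct x replicate and returns the table expected by
#' [aggregate_te()]'s qPCR mode.
#'
#' @param qpcr data frame from [gen_qpcr_table()] (or equivalent).
#' @param efficiency amplification factor per cycle.
#' @return data frame: construct_id, replicate, rel_fbfp, rel_mcherry.
#' @export
qpcr_relative_table <- function(qpcr, efficiency = 2.0) {
  sp <- split(qpcr, list(qpcr$construct_id, qpcr$replicate), drop = TRUE)
  out <- lapply(sp, function(d) {
    ref <- d$Ct[d$gene == "reference"]
    if (length(ref) != 1L) stop("need exactly one reference Ct per ",
                                "construct x replicate")
    data.frame(
      construct_id = d$construct_id[1], replicate = d$replicate[1],
      rel_fbfp = relative_level(d$Ct[d$gene == "fbfp"], ref, efficiency),
      rel_mcherry = relative_level(d$Ct[d$gene == "mcherry"], ref,
                                   efficiency))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$construct_id, res$replicate), , drop = FALSE]
}

#' Synthetic TE versus poly(U)-length dataset with calibrated correlation
#'
#' Generates `TE = a + b * polyU + e` over poly(U) lengths 0-8. The
#' residual scale is solved in closed form from the coefficient of
#' determination: for residuals empirically orthogonal to the predictor,
#' \deqn{r^2 = b^2 s_x^2 / (b^2 s_x^2 + \sigma^2)} so
#' \deqn{\sigma^2 = b^2 s_x^2 (1 - r^2) / r^2.}
#' The Gaussian residuals are centered, decorrelated from x, and rescaled
#' to exactly that sample variance, making the realized sample r-squared
#' equal the target by construction (`target_r2 = 1` gives zero noise;
#' `target_r2 = 0` sets b = 0). TE values are left unclipped so the
#' calibration is exact; extreme draws may leave `[0, 100]`.
#'
#' @param n number of observations.
#' @param target_r2 desired coefficient of determination in `[0, 1]`.
#' @param a,b intercept and slope of the true line (percent per U).
#' @return data frame `polyU_len`, `te_percent`, with attributes `a`, `b`,
#'   `sigma`.
#' @export
gen_te_polyU_dataset <- function(n, target_r2, a = 10, b = 10) {
  stopifnot(n >= 4, target_r2 >= 0, target_r2 <= 1)
  x <- sample(0:8, n, replace = TRUE)
  while (stats::var(x) == 0) x <- sample(0:8, n, replace = TRUE)
  if (target_r2 == 0) b <- 0
  sigma <- if (target_r2 %in% c(0, 1)) {
    if (target_r2 == 1) 0 else 5
  } else {
    sqrt(b^2 * stats::var(x) * (1 - target_r2) / target_r2)
  }
  eps <- stats::rnorm(n)
  # orthogonalize against x and rescale to exactly sigma
  eps <- stats::lm.fit(cbind(1, x), eps)$residuals
  s <- stats::sd(eps)
  eps <- if (s > 0 && sigma > 0) eps * sigma / s else rep(0, n)
  data.frame(polyU_len = x,
             te_percent = a + b * x + eps) |>
    structure(a = a, b = b, sigma = sigma)
}
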