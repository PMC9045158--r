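#' Classifier thresholds for terminator typing
#'
#' The four-type scheme is qualitative in origin; these constants pin it to
#' crisp rules. `polyU_min`: a consecutive-U run at least this long in the
#' 3' window makes a canonical poly(U) terminator (Type I). `u_rich_min`:
#' minimum U count (first 7 window nt) to call a tract "U-rich".
#' `distal_long_bp`: a paired region downstream of the stem defect with at
#' least this many bp counts as "long" (Type IV); at most
#' `distal_short_bp` as short (Type III). `window_len` / `count_len`: the
#' 3' window is `window_len` nt, U counting uses its first `count_len` nt.
#'
#' @param polyU_min,u_rich_min,distal_short_bp,distal_long_bp,window_len,count_len
#'   integer thresholds, defaults 5, 2, 4, 5, 8, 7.
#' @return list of thresholds (class `classify_config`).
#' @export
classify_config <- function(polyU_min = 5L, u_rich_min = 2L,
                            distal_short_bp = 4L, distal_long_bp = 5L,
                            window_len = 8L, count_len = 7L) {
  stopifnot(distal_long_bp == distal_short_bp + 1L,
            count_len <= window_len)
  structure(list(polyU_min = polyU_min, u_rich_min = u_rich_min,
                 distal_short_bp = distal_short_bp,
                 distal_long_bp = distal_long_bp,
                 window_len = window_len, count_len = count_len),
            class = "classify_config")
}

longest_run <- function(chars, letter) {
  r <- rle(chars == letter)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Extract terminator features from a hairpin structure
#'
#' Locates the putative 3' U-rich window and derives the counts used by
#' [classify_type()]. When the stem carries a small unpaired region (a
#' bulge or internal loop of 1-2 nt total), the window starts at the first
#' 3'-arm base distal to it (the 3' strand of the helix segment between the
#' defect and the stem base); otherwise it starts at the first unpaired
#' base 3' of the stem. The window is `window_len` nt, clipped at the end
#' of the scanned sequence.
#'
#' @param structure a `hairpin_structure` (from [min_hairpin()] /
#'   [scan_ir()]).
#' @param config a [classify_config()].
#' @return list of class `terminator_features`: `polyU_run`,
#'   `tail_U_count`, `urich_window`, `tail_paired`, `stem_bp`,
#'   `has_unpaired_region`, `unpaired_size`, `distal_arm_bp`, `dG`.
#' @export
extract_features <- function(structure, config = classify_config()) {
  stopifnot(inherits(structure, "hairpin_structure"))
  pairs <- structure$pairs
  n <- nchar(structure$sequence)
  b <- strsplit(structure$sequence, "", fixed = TRUE)[[1]]
  defects <- structure$defects
  has_def <- nrow(defects) > 0L
  # anchor = outermost small (<= 2 nt total) unpaired region, if any
  tot <- if (has_def) defects$size_5p + defects$size_3p else integer()
  small <- which(tot >= 1L & tot <= 2L)
  anchor <- if (length(small)) small[which.min(defects$outer_pair[small])]
            else NA_integer_
  if (!is.na(anchor)) {
    win_start <- pairs[defects$outer_pair[anchor], 2]
    unpaired_size <- tot[anchor]
    distal_arm_bp <- defects$outer_pair[anchor]
  } else {
    win_start <- pairs[1, 2] + 1L
    unpaired_size <- if (has_def) tot[which.min(defects$outer_pair)] else 0L
    distal_arm_bp <- 0L
  }
  win_end <- min(n, win_start + config$window_len - 1L)
  window <- if (win_start <= n) b[win_start:win_end] else character()
  count_part <- window[seq_len(min(length(window), config$count_len))]
  paired_pos <- c(pairs[, 1], pairs[, 2])
  tail_paired <- sum((win_start:win_end) %in% paired_pos) >= 2L
  structure(list(
    polyU_run = longest_run(window, "U"),
    tail_U_count = sum(count_part == "U"),
    urich_window = paste(window, collapse = ""),
    tail_paired = tail_paired,
    stem_bp = nrow(pairs),
    has_unpaired_region = has_def,
    unpaired_size = as.integer(unpaired_size),
    distal_arm_bp = as.integer(distal_arm_bp),
    dG = structure$dG), class = "terminator_features")
}

#' Assign a terminator type from extracted features
#'
#' Deterministic decision cascade over the four structural types of
#' internal intrinsic terminators:
#' \enumerate{
#'   \item a poly(U) run of at least `polyU_min` -> `I` (canonical
#'     poly(U)-tail terminator);
#'   \item otherwise, no unpaired region in the stem and a U-rich 3' tract
#'     (at least `u_rich_min` U) -> `II`;
#'   \item otherwise, a 1-2 nt unpaired region whose distal (3') paired
#'     tract is short (<= `distal_short_bp` bp), U-rich, and base-paired ->
#'     `III`;
#'   \item otherwise, a 1-2 nt unpaired region with a long distal paired
#'     region (>= `distal_long_bp` bp) or a low 3' U content -> `IV`;
#'   \item anything else -> `unclassified`.
#' }
#'
#' @param features a `terminator_features` list from [extract_features()].
#' @param config a [classify_config()].
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"unclassified"`.
#' @export
classify_type <- function(features, config = classify_config()) {
  f <- features
  if (f$polyU_run >= config$polyU_min) return("I")
  if (!f$has_unpaired_region && f$tail_U_count >= config$u_rich_min)
    return("II")
  small <- f$unpaired_size %in% c(1L, 2L)
  if (small && f$tail_paired && f$distal_arm_bp <= config$distal_short_bp &&
      f$tail_U_count >= config$u_rich_min)
    return("III")
  if (small && (f$distal_arm_bp >= config$distal_long_bp ||
                f$tail_U_count < config$u_rich_min))
    return("IV")
  "unclassified"
}

#' Build a terminator call (features + type) for one scanned structure
#' @param structure a `hairpin_structure`, typically from [scan_ir()].
#' @param config a [classify_config()].
#' @return list of class `terminator_call`: `ir_id`, `structure`,
#'   `features`, `type_label`.
#' @export
terminator_call <- function(structure, config = classify_config()) {
  features <- extract_features(structure, config)
  structure(list(
    ir_id = attr(structure, "ir_id"),
    structure = structure, features = features,
    type_label = classify_type(features, config)), class = "terminator_call")
}

#' Tabulate terminator calls
#' @param calls list of `terminator_call`.
#' @return data frame: ir_id, type, dG, polyU_run, tail_U_count,
#'   tail_paired, stem_bp, unpaired_size, distal_arm_bp, dot_bracket.
#' @export
calls_table <- function(calls) {
  if (!length(calls))
    return(data.frame(ir_id = character(), type = character(),
                      dG = numeric(), polyU_run = integer(),
                      tail_U_count = integer(), tail_paired = logical(),
                      stem_bp = integer(), unpaired_size = integer(),
                      distal_arm_bp = integer(), dot_bracket = character()))
  do.call(rbind, lapply(calls, function(cl) data.frame(
    ir_id = if (is.null(cl$ir_id) || is.na(cl$ir_id)) "" else cl$ir_id,
    type = cl$type_label, dG = cl$features$dG,
    polyU_run = cl$features$polyU_run,
    tail_U_count = cl$features$tail_U_count,
    tail_paired = cl$features$tail_paired, stem_bp = cl$features$stem_bp,
    unpaired_size = cl$features$unpaired_size,
    distal_arm_bp = cl$features$distal_arm_bp,
    dot_bracket = cl$structure$dot_bracket)))
}

#' Position-by-base counts of the 3' U-rich windows (sequence-logo input)
#'
#' Counts bases at each of the first `positions` window positions across a
#' set of calls, plus the per-position information content in bits
#' (log2(4) minus the Shannon entropy of the observed base frequencies).
#'
#' @param calls list of `terminator_call` objects (or of
#'   `terminator_features`).
#' @param positions number of window positions to tabulate (default 7).
#' @return list with `counts` (4 x positions matrix, rows A,C,G,U) and
#'   `information` (bits per position; NA where no sequence reaches it).
#' @export
tail_logo_counts <- function(calls, positions = 7L) {
  tails <- vapply(calls, function(cl) {
    f <- if (inherits(cl, "terminator_call")) cl$features else cl
    f$urich_window
  }, character(1))
  counts <- matrix(0L, 4L, positions,
                   dimnames = list(c("A", "C", "G", "U"),
                                   paste0("pos", seq_len(positions))))
  for (s in tails) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    for (q in seq_len(min(length(b), positions)))
      counts[b[q], q] <- counts[b[q], q] + 1L
  }
  information <- apply(counts, 2, function(col) {
    tot <- sum(col)
    if (!tot) return(NA_real_)
    p <- col[col > 0] / tot
    2 - (-sum(p * log2(p)))
  })
  list(counts = counts, information = information)
}

# position bookkeeping shared by the mutation operators
stem_positions <- function(structure) {
  pairs <- structure$pairs
  list(pairs = pairs, k = nrow(pairs), n = nchar(structure$sequence))
}

drop_positions <- function(sequence, pos) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(b[-pos], collapse = "")
}

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

#' Delete bases from the 5' end of a stem's 5' arm
#'
#' Removes the `n` 5'-most bases of the 5' arm of the hairpin (the outermost
#' paired bases), emulating 5'-truncation constructs used to test whether
#' pairing of the 3' U-rich tract is required for termination. The returned
#' sequence is intended to be refolded with [min_hairpin()].
#'
#' @param structure a `hairpin_structure`.
#' @param n number of bases to delete (0 = identity).
#' @return RNA string.
#' @export
mutate_delete_5arm <- function(structure, n) {
  stopifnot(inherits(structure, "hairpin_structure"), n >= 0)
  if (n == 0) return(structure$sequence)
  sp <- stem_positions(structure)
  arm_len <- sp$pairs[sp$k, 1] - sp$pairs[1, 1] + 1L
  if (n > arm_len) stop("cannot delete ", n, " bases from a ", arm_len,
                        " nt 5' arm")
  drop_positions(structure$sequence, sp$pairs[1, 1] + seq_len(n) - 1L)
}

#' Shorten or lengthen a stem at its loop-proximal end
#'
#' `delta_bp > 0` inserts that many G-C pairs immediately inside the
#' innermost pair (lengthening the stem at the top); `delta_bp < 0` deletes
#' that many innermost pairs. Refold the returned sequence with
#' [min_hairpin()] to obtain the mutant structure.
#'
#' @param structure a `hairpin_structure`.
#' @param delta_bp signed change in stem length (0 = identity).
#' @return RNA string.
#' @export
mutate_stem <- function(structure, delta_bp) {
  stopifnot(inherits(structure, "hairpin_structure"))
  if (delta_bp == 0) return(structure$sequence)
  sp <- stem_positions(structure)
  s <- structure$sequence
  if (delta_bp > 0) {
    ik <- sp$pairs[sp$k, 1]; jk <- sp$pairs[sp$k, 2]
    paste0(substr(s, 1, ik), strrep("G", delta_bp),
           substr(s, ik + 1L, jk - 1L), strrep("C", delta_bp),
           substr(s, jk, nchar(s)))
  } else {
    ndel <- -delta_bp
    if (ndel >= sp$k) stop("cannot delete ", ndel, " pairs from a ",
                           sp$k, " bp stem")
    doomed <- sp$pairs[(sp$k - ndel + 1L):sp$k, , drop = FALSE]
    drop_positions(s, c(doomed[, 1], doomed[, 2]))
  }
}

#' Pair the unpaired region(s) of a stem
#'
#' Converts each small (1-2 nt) bulge or internal loop in the stem into
#' Watson-Crick pairs: for an internal loop the 3'-side bases are
#' substituted with the complement of the 5'-side bases; for a bulge the
#' complementary base(s) are inserted on the opposite strand. Refolding the
#' result gives a defect-free stem with strictly lower free energy. A
#' structure without an unpaired region is returned unchanged with a
#' warning.
#'
#' @param structure a `hairpin_structure`.
#' @return RNA string.
#' @export
mutate_pair_unpaired <- function(structure) {
  stopifnot(inherits(structure, "hairpin_structure"))
  defects <- structure$defects
  tot <- if (nrow(defects)) defects$size_5p + defects$size_3p else integer()
  small <- which(tot >= 1L & tot <= 2L)
  if (!length(small)) {
    warning("structure has no 1-2 nt unpaired region; sequence unchanged")
    return(structure$sequence)
  }
  pairs <- structure$pairs
  b <- strsplit(structure$sequence, "", fixed = TRUE)[[1]]
  # collect all edits against the original coordinates, then apply the
  # substitutions (no shift) and finally the insertions from the largest
  # position downward so earlier insertions never shift later ones
  inserts <- list()
  for (d in small) {
    t_out <- defects$outer_pair[d]
    i_out <- pairs[t_out, 1]; j_out <- pairs[t_out, 2]
    i_in <- pairs[t_out + 1L, 1]; j_in <- pairs[t_out + 1L, 2]
    s5 <- defects$size_5p[d]; s3 <- defects$size_3p[d]
    if (s5 > 0L && s3 > 0L) {          # internal loop: substitute 3' side
      side5 <- b[(i_out + 1L):(i_in - 1L)]
      b[(j_in + 1L):(j_out - 1L)] <- rev(unname(WC_PARTNER[side5]))
    } else if (s5 > 0L) {              # 5' bulge: insert partners 3' side
      side5 <- b[(i_out + 1L):(i_in - 1L)]
      inserts[[length(inserts) + 1L]] <-
        list(after = j_in, what = rev(unname(WC_PARTNER[side5])))
    } else {                           # 3' bulge: insert partners 5' side
      side3 <- b[(j_in + 1L):(j_out - 1L)]
      inserts[[length(inserts) + 1L]] <-
        list(after = i_out, what = rev(unname(WC_PARTNER[side3])))
    }
  }
  if (length(inserts)) {
    afters <- vapply(inserts, function(e) e$after, 0L)
    for (e in inserts[order(afters, decreasing = TRUE)])
      b <- append(b, e$what, after = e$after)
  }
  paste(b, collapse = "")
}
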