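#' @useDynLib termstoich, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

RNA_PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")

encode_rna <- function(sequence) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- match(b, c("A", "C", "G", "U")) - 1L
  if (anyNA(code))
    stop("sequence contains non-ACGU character: ",
         paste(unique(b[is.na(code)]), collapse = ","))
  code
}

pair_code <- function(x, y) {
  p <- paste0(x, y)
  if (!p %in% RNA_PAIR_CODES) NA_character_ else p
}

# cents tables in the fixed AU,UA,CG,GC,GU,UG order expected by src/fold.cpp
params_cents_ordered <- function(params) {
  pc <- params_cents(params)
  pc$stack <- pc$stack[RNA_PAIR_CODES, RNA_PAIR_CODES]
  pc
}

#' Build and validate a single-hairpin secondary structure
#'
#' Assembles a `hairpin_structure` object from a sequence and a nested chain
#' of base pairs, deriving helix segments, the terminal loop, stem defects
#' (bulges and internal loops), the unpaired 5'/3' tails (recorded up to
#' `max_tail` nt), and the free energy under `params`.
#'
#' @param sequence RNA string (ACGU).
#' @param pairs integer matrix with columns `i`, `j` (1-based positions,
#'   i < j), ordered outermost to innermost; may have zero rows.
#' @param params an [energy_params()] object.
#' @param max_tail maximum unpaired tail length recorded on either side.
#' @return A `hairpin_structure` with elements `sequence`, `pairs`,
#'   `stem_segments`, `loop_size`, `defects`, `tail_5p`, `tail_3p`, `dG`
#'   (kcal/mol) and `dot_bracket`.
#' @export
hairpin_structure <- function(sequence, pairs, params = energy_params(),
                              max_tail = 10L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  k <- nrow(pairs)
  if (k > 0) {
    if (any(pairs < 1L) || any(pairs > n)) stop("pair index out of range")
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    if (k > 1) {
      if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) >= 0))
        stop("pairs must be a nested chain, outermost first")
      d5 <- diff(pairs[, 1]) - 1L
      d3 <- -diff(pairs[, 2]) - 1L
      if (any(d5 > 6L) || any(d3 > 6L))
        stop("stem defect larger than 6 nt per side")
    }
    loop_size <- pairs[k, 2] - pairs[k, 1] - 1L
    if (loop_size < 3L) stop("terminal loop smaller than 3 nt")
  } else {
    loop_size <- NA_integer_
  }

  # helix segments and defects, outermost -> innermost
  segs <- data.frame(segment = integer(), first_pair = integer(),
                     n_bp = integer())
  defects <- data.frame(kind = character(), size_5p = integer(),
                        size_3p = integer(), outer_pair = integer(),
                        position = integer())
  if (k > 0) {
    brk <- if (k > 1) which(diff(pairs[, 1]) - 1L + (-diff(pairs[, 2]) - 1L) > 0L)
           else integer()
    starts <- c(1L, brk + 1L)
    ends <- c(brk, k)
    segs <- data.frame(segment = seq_along(starts), first_pair = starts,
                       n_bp = ends - starts + 1L)
    if (length(brk)) {
      d5 <- diff(pairs[, 1]) - 1L
      d3 <- -diff(pairs[, 2]) - 1L
      defects <- data.frame(
        kind = ifelse(d5[brk] == 0L | d3[brk] == 0L, "bulge", "internal"),
        size_5p = d5[brk], size_3p = d3[brk], outer_pair = brk,
        position = rev(seq_along(brk)))   # 1 = defect nearest the loop
    }
  }

  tail_3p <- if (k > 0 && pairs[1, 2] < n)
    substr(sequence, pairs[1, 2] + 1L, min(n, pairs[1, 2] + max_tail)) else ""
  tail_5p <- if (k > 0 && pairs[1, 1] > 1)
    substr(sequence, max(1L, pairs[1, 1] - max_tail), pairs[1, 1] - 1L) else ""

  db <- rep(".", n)
  if (k > 0) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }

  st <- structure(list(
    sequence = sequence, pairs = pairs, stem_segments = segs,
    loop_size = loop_size, defects = defects,
    tail_5p = tail_5p, tail_3p = tail_3p,
    dG = NA_real_, dot_bracket = paste(db, collapse = ""),
    params_version = params$version_tag
  ), class = "hairpin_structure")
  st$dG <- hairpin_energy(st, params)
  st
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("hairpin_structure: ", nrow(x$pairs), " bp stem, loop ", x$loop_size,
      " nt, dG = ", sprintf("%.2f", x$dG), " kcal/mol\n", sep = "")
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n", sep = "")
  if (nrow(x$defects))
    cat("  defects: ",
        paste(sprintf("%s %d+%d nt", x$defects$kind, x$defects$size_5p,
                      x$defects$size_3p), collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Free energy of a hairpin structure under a parameter set
#'
#' Recomputes the component free-energy sum of a structure: stacking terms
#' for consecutive pairs, bulge/internal-loop initiation for stem defects,
#' the hairpin-loop initiation for the terminal loop, and the terminal
#' A-U/G-U closing penalty on the outermost pair. A structure with no pairs
#' has dG = 0. The sum is performed in integer hundredths of kcal/mol, so
#' it reproduces the folding engine's energies exactly.
#'
#' @param structure a `hairpin_structure`.
#' @param params an [energy_params()] object.
#' @return Free energy in kcal/mol.
#' @export
hairpin_energy <- function(structure, params = energy_params()) {
  stopifnot(inherits(structure, "hairpin_structure"))
  pairs <- structure$pairs
  k <- nrow(pairs)
  if (k == 0) return(0)
  b <- strsplit(structure$sequence, "", fixed = TRUE)[[1]]
  pc <- params_cents(params)
  pt <- character(k)
  for (q in seq_len(k)) {
    p <- pair_code(b[pairs[q, 1]], b[pairs[q, 2]])
    if (is.na(p))
      stop("bases ", b[pairs[q, 1]], "-", b[pairs[q, 2]],
           " at (", pairs[q, 1], ",", pairs[q, 2], ") cannot pair")
    pt[q] <- p
  }
  cents <- 0L
  if (k > 1) {
    for (q in seq_len(k - 1)) {
      d5 <- pairs[q + 1, 1] - pairs[q, 1] - 1L
      d3 <- pairs[q, 2] - pairs[q + 1, 2] - 1L
      cents <- cents + if (d5 == 0L && d3 == 0L)
        pc$stack[pt[q], pt[q + 1]]
      else if (d5 == 0L || d3 == 0L)
        loop_penalty_cents("bulge", d5 + d3, pc)
      else
        loop_penalty_cents("internal", d5 + d3, pc)
    }
  }
  cents <- cents + loop_penalty_cents("hairpin",
                                      pairs[k, 2] - pairs[k, 1] - 1L, pc)
  if (pt[1] %in% c("AU", "UA", "GU", "UG")) cents <- cents + pc$term_au
  unname(cents) / 100
}

#' Minimum-free-energy single hairpin of an RNA sequence
#'
#' Dynamic-programming search over all single-hairpin structures (one
#' terminal loop of at least `min_loop` nt; helices interrupted only by
#' bulges or internal loops of at most 6 nt per side; at least `min_stem`
#' base pairs). Ties in free energy are broken toward the larger total stem,
#' then the 5'-most outermost pair, so output is identical across platforms.
#'
#' @param sequence RNA string (ACGU only; non-ACGU is an error).
#' @param params an [energy_params()] object.
#' @param min_stem minimum number of base pairs (default 3).
#' @param min_loop minimum terminal-loop size in nt (default 3).
#' @param require_negative if `TRUE` (default), return `NULL` unless the
#'   optimum has dG < 0; `FALSE` returns the optimum regardless (used when
#'   comparing against the enumeration oracle).
#' @return A `hairpin_structure`, or `NULL` when no qualifying structure
#'   exists (including sequences shorter than `2 * min_stem + min_loop`).
#' @examples
#' st <- min_hairpin("GGGGCAAAAGCCCC")
#' st$dG
#' @export
min_hairpin <- function(sequence, params = energy_params(), min_stem = 3L,
                        min_loop = 3L, require_negative = TRUE) {
  stopifnot(min_stem >= 1L, min_loop >= 3L)
  if (nchar(sequence) < 2L * min_stem + min_loop) return(NULL)
  code <- encode_rna(sequence)
  res <- fold_min_hairpin_cpp(code, params_cents_ordered(params),
                              as.integer(min_stem), as.integer(min_loop))
  if (!res$found) return(NULL)
  if (require_negative && res$dG_cents >= 0L) return(NULL)
  st <- hairpin_structure(sequence, res$pairs, params)
  if (round(st$dG * 100) != res$dG_cents)
    stop("internal error: energy recomputation mismatch (",
         st$dG, " vs ", res$dG_cents / 100, ")")
  st
}

#' Exhaustively enumerate all single-hairpin structures (test oracle)
#'
#' Lists every valid single-hairpin structure of a short sequence with its
#' free energy, by plain recursive enumeration written independently of the
#' dynamic-programming engine. Intended as a verification oracle; sequences
#' longer than 30 nt are refused.
#'
#' @inheritParams min_hairpin
#' @param max_structures guard against combinatorial blow-up.
#' @return A list of `hairpin_structure` objects (possibly empty), in no
#'   particular order.
#' @export
enumerate_hairpins <- function(sequence, params = energy_params(),
                               min_loop = 3L, max_structures = 500000L) {
  n <- nchar(sequence)
  if (n > 30L) stop("enumeration restricted to sequences of at most 30 nt")
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(!b %in% c("A", "C", "G", "U")))
    stop("sequence contains non-ACGU character")
  pairable <- function(x, y) paste0(x, y) %in% RNA_PAIR_CODES
  out <- vector("list", 256L)
  n_out <- 0L
  emit <- function(chain) {
    n_out <<- n_out + 1L
    if (n_out > max_structures) stop("more than ", max_structures,
                                     " structures; raise max_structures")
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- chain
  }
  extend <- function(chain, k, l) {
    if (l - k - 1L >= min_loop) emit(chain)
    for (k2 in (k + 1L):min(k + 7L, l - 1L)) {
      l2min <- max(k2 + 1L, l - 7L)
      if (l2min > l - 1L) next
      for (l2 in l2min:(l - 1L)) {
        if (l2 - k2 - 1L < min_loop) next
        if (!pairable(b[k2], b[l2])) next
        extend(rbind(chain, c(k2, l2)), k2, l2)
      }
    }
  }
  if (n >= min_loop + 2L) {
    for (i in 1:(n - min_loop - 1L)) {
      for (j in (i + min_loop + 1L):n) {
        if (pairable(b[i], b[j])) extend(matrix(c(i, j), ncol = 2), i, j)
      }
    }
  }
  lapply(out[seq_len(n_out)], hairpin_structure, sequence = sequence,
         params = params)
}

# thin wrapper over the compiled exhaustive DFS oracle; returns the minimal
# free energy (kcal/mol) and stem size over structures with >= min_stem
# pairs, or NULL when none exists. Used by the oracle-equivalence tests on
# sequences too long for the R-level enumeration.
oracle_min_hairpin <- function(sequence, params = energy_params(),
                               min_stem = 3L, min_loop = 3L) {
  code <- encode_rna(sequence)
  res <- fold_oracle_dfs_cpp(code, params_cents_ordered(params),
                             as.integer(min_stem), as.integer(min_loop))
  if (!res$found) return(NULL)
  list(dG = res$dG_cents / 100, bp = res$bp, pairs = res$pairs,
       n_structures = res$n_structures)
}

#' Scan one intergenic region for a stem-loop below an energy threshold
#'
#' Folds the region's sense-strand RNA sequence with [min_hairpin()] and
#' reports the structure only when its free energy is strictly below
#' `dG_threshold` (default -10 kcal/mol, the gate used to call a putative
#' stem-loop in an intergenic region). The unpaired tail 3' of the outermost
#' pair is recorded up to 10 nt, clipped at the region end.
#'
#' @param ir a one-row data frame or list with at least `ir_id` and
#'   `sequence` (as produced by [extract_intergenic_regions()]).
#' @param params an [energy_params()] object.
#' @param dG_threshold strict upper bound on dG, kcal/mol.
#' @param ... passed to [min_hairpin()] (e.g. `min_stem`).
#' @return A `hairpin_structure` with an `ir_id` attribute, or `NULL`.
#' @export
scan_ir <- function(ir, params = energy_params(), dG_threshold = -10,
                    ...) {
  sequence <- as.character(ir$sequence)
  ir_id <- if (!is.null(ir$ir_id)) as.character(ir$ir_id) else NA_character_
  if (grepl("[^ACGU]", sequence)) {
    warning("intergenic region ", ir_id,
            " contains non-ACGU characters; skipped")
    return(NULL)
  }
  st <- min_hairpin(sequence, params = params, ...)
  if (is.null(st) || st$dG >= dG_threshold) return(NULL)
  attr(st, "ir_id") <- ir_id
  st
}

#' Scan a table of intergenic regions for candidate stem-loops
#'
#' Applies [scan_ir()] to every row of an intergenic-region table (by
#' default only the "long" regions, > 50 bp) and returns the structures
#' found, plus a tidy summary table.
#'
#' @param irs data frame from [extract_intergenic_regions()].
#' @param params an [energy_params()] object.
#' @param dG_threshold strict dG gate in kcal/mol.
#' @param long_only fold only rows with `is_long` (default `TRUE`).
#' @return List with `structures` (named list of `hairpin_structure`) and
#'   `table` (one row per hit: ir_id, dG, stem_bp, loop_size, dot_bracket,
#'   tail_3p).
#' @export
scan_ir_table <- function(irs, params = energy_params(), dG_threshold = -10,
                          long_only = TRUE) {
  rows <- if (long_only && nrow(irs)) which(irs$is_long) else seq_len(nrow(irs))
  structures <- list()
  tab <- data.frame(ir_id = character(), dG = numeric(), stem_bp = integer(),
                    loop_size = integer(), dot_bracket = character(),
                    tail_3p = character())
  for (r in rows) {
    st <- scan_ir(irs[r, , drop = FALSE], params = params,
                  dG_threshold = dG_threshold)
    if (is.null(st)) next
    structures[[irs$ir_id[r]]] <- st
    tab <- rbind(tab, data.frame(
      ir_id = irs$ir_id[r], dG = st$dG, stem_bp = nrow(st$pairs),
      loop_size = st$loop_size, dot_bracket = st$dot_bracket,
      tail_3p = st$tail_3p))
  }
  list(structures = structures, table = tab)
}
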