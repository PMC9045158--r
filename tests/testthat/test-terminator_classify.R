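test_that("feature extraction reads the 3' window after the stem", {
  f <- extract_features(gc_hairpin_with_tail("UUUUUUAG"))
  expect_identical(f$polyU_run, 6L)
  expect_identical(f$tail_U_count, 6L)
  expect_false(f$tail_paired)
  expect_identical(f$distal_arm_bp, 0L)
  expect_false(f$has_unpaired_region)

  fgc <- extract_features(gc_hairpin_with_tail("GCGCGCG"))
  expect_identical(fgc$polyU_run, 0L)
  expect_identical(fgc$tail_U_count, 0L)
})

test_that("a stem defect relocates the window to the distal 3' arm", {
  # AAA | A(bulge) | GGGGG loop CCCCC | UUU | UAGAG
  seq <- "AAAAGGGGGAAAACCCCCUUUUAGAG"
  pairs <- rbind(cbind(1:3, 21:19), cbind(5:9, 18:14))
  st <- hairpin_structure(seq, pairs)
  expect_identical(nrow(st$defects), 1L)
  expect_identical(st$defects$kind, "bulge")
  f <- extract_features(st)
  # window starts at position 19 (first 3'-arm base outside the bulge)
  expect_identical(f$urich_window, "UUUUAGAG")
  expect_identical(f$tail_U_count, 4L)
  expect_identical(f$polyU_run, 4L)
  expect_true(f$tail_paired)
  expect_identical(f$distal_arm_bp, 3L)
  expect_identical(f$unpaired_size, 1L)
  expect_identical(classify_type(f), "III")
})

test_that("the typing cascade is pinned, total and deterministic", {
  base <- list(polyU_run = 0L, tail_U_count = 0L, urich_window = "",
               tail_paired = FALSE, stem_bp = 8L,
               has_unpaired_region = FALSE, unpaired_size = 0L,
               distal_arm_bp = 0L, dG = -20)
  feats <- function(...) {
    f <- utils::modifyList(base, list(...))
    class(f) <- "terminator_features"
    f
  }
  expect_identical(classify_type(feats(polyU_run = 8L)), "I")
  expect_identical(classify_type(feats(polyU_run = 5L)), "I")
  expect_identical(classify_type(feats(polyU_run = 3L, tail_U_count = 3L)),
                   "II")
  expect_identical(classify_type(
    feats(has_unpaired_region = TRUE, unpaired_size = 1L,
          tail_paired = TRUE, distal_arm_bp = 3L, tail_U_count = 3L)),
    "III")
  expect_identical(classify_type(
    feats(has_unpaired_region = TRUE, unpaired_size = 1L,
          tail_paired = TRUE, distal_arm_bp = 7L, tail_U_count = 1L)),
    "IV")
  # low-U defect stem is IV even with a short distal arm
  expect_identical(classify_type(
    feats(has_unpaired_region = TRUE, unpaired_size = 2L,
          tail_paired = TRUE, distal_arm_bp = 2L, tail_U_count = 0L)),
    "IV")
  # nothing fits: unclassified
  expect_identical(classify_type(feats(tail_U_count = 1L)), "unclassified")
  expect_identical(classify_type(
    feats(has_unpaired_region = TRUE, unpaired_size = 4L,
          tail_U_count = 1L)), "unclassified")
})

test_that("tail logo counts and information content behave analytically", {
  calls <- lapply(1:12, function(q) {
    f <- list(urich_window = "UUUUUUUU")
    class(f) <- "terminator_features"
    f
  })
  lg <- tail_logo_counts(calls)
  expect_true(all(lg$counts["U", ] == 12))
  expect_true(all(lg$information == 2))
  expect_identical(unname(colSums(lg$counts)), rep(12, 7))

  # hand-counted mixed fixture
  mixed <- lapply(c("UUAG", "UAAG", "GUAG", "UUUU"), function(s) {
    f <- list(urich_window = s); class(f) <- "terminator_features"; f
  })
  lgm <- tail_logo_counts(mixed, positions = 4L)
  expect_identical(unname(lgm$counts["U", ]), c(3L, 3L, 1L, 1L))
  expect_identical(unname(lgm$counts["G", ]), c(1L, 0L, 0L, 3L))
  expect_identical(unname(lgm$counts["A", ]), c(0L, 1L, 3L, 0L))

  # uniform random tails: information near zero
  set.seed(53)
  unif <- lapply(1:600, function(q) {
    f <- list(urich_window = random_rna(7))
    class(f) <- "terminator_features"; f
  })
  lgu <- tail_logo_counts(unif)
  expect_true(all(lgu$information < 0.05))
})

test_that("generated terminators are recovered by refold + classify", {
  set.seed(59)
  for (tp in c("I", "II", "III", "IV")) {
    for (q in 1:8) {
      g <- gen_terminator(tp)
      st <- min_hairpin(g$sequence)
      expect_identical(classify_type(extract_features(st)), tp)
      expect_lte(abs(g$dG - g$dG_target), 2)
    }
  }
})

test_that("5'-arm deletion removes pairing of the 3' tract", {
  set.seed(61)
  st <- min_hairpin(gen_terminator("III")$sequence)
  expect_identical(mutate_delete_5arm(st, 0), st$sequence)
  m5 <- mutate_delete_5arm(st, 5)
  expect_identical(nchar(m5), nchar(st$sequence) - 5L)
  # deleting the whole 5' arm leaves nothing able to pair the 3' tract
  arm_len <- st$pairs[nrow(st$pairs), 1] - st$pairs[1, 1] + 1L
  mall <- mutate_delete_5arm(st, arm_len)
  ref <- min_hairpin(mall, require_negative = FALSE)
  expect_true(is.null(ref) || ref$dG > st$dG)
})

test_that("stem lengthening lowers dG, shortening raises it", {
  set.seed(67)
  st <- min_hairpin(gen_terminator("II")$sequence)
  expect_identical(mutate_stem(st, 0), st$sequence)
  up <- min_hairpin(mutate_stem(st, +2), require_negative = FALSE)
  expect_lt(up$dG, st$dG)
  down <- min_hairpin(mutate_stem(st, -4), require_negative = FALSE)
  expect_true(is.null(down) || down$dG > st$dG)
  # a 7-bp stem shrunk by 4 pairs cannot keep more than 3 designed pairs
  sub <- hairpin_structure("GGGGGGGAAAACCCCCCC", cbind(1:7, 18:12))
  shr <- min_hairpin(mutate_stem(sub, -4), require_negative = FALSE)
  expect_true(is.null(shr) || nrow(shr$pairs) <= 3)
})

test_that("pairing the unpaired region strictly lowers refolded dG", {
  set.seed(71)
  for (tp in c("III", "IV")) {
    for (q in 1:6) {
      g <- gen_terminator(tp)
      st <- g$structure
      mut <- mutate_pair_unpaired(st)
      ref <- min_hairpin(mut)
      expect_lt(ref$dG, st$dG)
      f <- extract_features(ref)
      expect_false(f$has_unpaired_region)
    }
  }
  # no unpaired region: identity with a warning
  plain <- gc_hairpin_with_tail("UUUUUU")
  expect_warning(out <- mutate_pair_unpaired(plain), "no 1-2 nt unpaired")
  expect_identical(out, plain$sequence)
})

test_that("bulged A acquires a U partner (A-U pair) when paired up", {
  # single A bulge on the 5' side of a GC stem
  seq <- "GGGACCCAAAAGGGCCC"
  pairs <- rbind(cbind(1:3, 17:15), cbind(5:7, 14:12))
  st <- hairpin_structure(seq, pairs)
  expect_identical(st$defects$kind, "bulge")
  mut <- mutate_pair_unpaired(st)
  expect_identical(nchar(mut), nchar(seq) + 1L)
  # the inserted partner is U, immediately 3' of the inner helix arm
  expect_identical(substr(mut, 15, 15), "U")
  ref <- min_hairpin(mut)
  expect_lt(ref$dG, st$dG)
})
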