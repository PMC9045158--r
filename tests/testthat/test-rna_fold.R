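test_that("hairpin_energy is the pinned component sum", {
  p <- energy_params()
  # 4-bp all-GC helix closing a 4-nt loop: 3 GC/GC stacks + hairpin(4)
  st <- hairpin_structure("GGGGAAAACCCC",
                          cbind(1:4, 12:9), params = p)
  expected <- 3 * p$stack_dG["GC", "GC"] + p$hairpin_init[["4"]]
  expect_equal(st$dG, expected)
  expect_equal(hairpin_energy(st, p), expected)

  # zero-pair structure has zero energy
  st0 <- hairpin_structure("ACGUACGU", matrix(integer(), ncol = 2))
  expect_identical(st0$dG, 0)

  # doubling every parameter doubles the energy
  p2 <- energy_params(scale = 2)
  expect_equal(hairpin_energy(st, p2), 2 * expected)

  # terminal AU penalty applies to the outermost pair
  stau <- hairpin_structure("AGGGAAAACCCU", cbind(1:4, 12:9), params = p)
  expect_equal(stau$dG,
               p$stack_dG["AU", "GC"] + 2 * p$stack_dG["GC", "GC"] +
                 p$hairpin_init[["4"]] + p$terminal_AU_penalty)

  # claimed pair of non-complementary bases is an error
  expect_error(hairpin_structure("GGGGAAAACCCA", cbind(1:4, 12:9)),
               "cannot pair")
})

test_that("min_hairpin finds stems and refuses unfoldable input", {
  st <- min_hairpin("GGGGCAAAAGCCCC")
  expect_s3_class(st, "hairpin_structure")
  expect_gte(nrow(st$pairs), 4)
  expect_lt(st$dG, 0)
  expect_null(min_hairpin("AAAAAAAAAA"))
  expect_null(min_hairpin("ACGU"))        # too short
  expect_error(min_hairpin("ACGTACGTACGTT"), "non-ACGU")
})

test_that("emitted structures recompute to their own energy", {
  set.seed(31)
  p <- energy_params()
  for (q in 1:40) {
    s <- random_rna(sample(15:60, 1))
    st <- min_hairpin(s, p, require_negative = FALSE)
    if (is.null(st)) next
    expect_equal(hairpin_energy(st, p), st$dG)
  }
})

test_that("DP agrees exactly with the exhaustive DFS oracle", {
  set.seed(17)
  p <- energy_params()
  n_checked <- 0L
  for (q in 1:150) {
    s <- random_rna(sample(12:28, 1))
    dp <- min_hairpin(s, p, require_negative = FALSE)
    orc <- termstoich:::oracle_min_hairpin(s, p)
    expect_identical(is.null(dp), is.null(orc))
    if (is.null(dp)) next
    expect_identical(dp$dG, orc$dG)
    expect_identical(nrow(dp$pairs), orc$bp)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 50)
})

test_that("R-level enumeration agrees with both engines on short input", {
  p <- energy_params()
  en <- enumerate_hairpins("GCGAAACGC", p)
  # contains the full 3-bp-stem / 3-nt-loop structure
  has_full <- any(vapply(en, function(x)
    nrow(x$pairs) == 3 && x$loop_size == 3, TRUE))
  expect_true(has_full)
  expect_length(enumerate_hairpins("AAAA", p), 0)
  expect_error(enumerate_hairpins(strrep("A", 31), p), "at most 30")

  set.seed(29)
  for (q in 1:20) {
    s <- random_rna(sample(12:16, 1))
    en <- enumerate_hairpins(s, p)
    en3 <- Filter(function(x) nrow(x$pairs) >= 3, en)
    dp <- min_hairpin(s, p, require_negative = FALSE)
    if (!length(en3)) {
      expect_null(dp)
      next
    }
    emin <- min(vapply(en3, function(x) x$dG, 0))
    expect_identical(dp$dG, emin)
  }
})

test_that("folding is deterministic and ties break toward longer stems", {
  s <- "GGGGCAAAAGCCCCAAAGGGGCAAAAGCCCC"
  a <- min_hairpin(s); b <- min_hairpin(s)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$dG, b$dG)
  # two identical hairpin cassettes: the 5'-most one must win the tie
  expect_identical(a$pairs[1, 1], min_hairpin(s)$pairs[1, 1])
  expect_lte(a$pairs[1, 1], 5L)
})

test_that("scan_ir applies the strict -10 kcal/mol gate", {
  set.seed(41)
  term <- gen_terminator("I")
  flank <- random_rna(20)
  ir <- list(ir_id = "irX", sequence = paste0(flank, term$sequence),
             is_long = TRUE)
  st <- scan_ir(ir)
  expect_s3_class(st, "hairpin_structure")
  expect_lt(st$dG, -10)
  expect_identical(attr(st, "ir_id"), "irX")
  # strictness: a threshold equal to the structure's dG excludes it
  expect_null(scan_ir(ir, dG_threshold = st$dG))
  # N-containing regions are skipped with a warning
  expect_warning(
    expect_null(scan_ir(list(ir_id = "irN",
                             sequence = paste0(flank, "N", flank)))),
    "non-ACGU")
})

test_that("weak low-GC regions yield no call; threshold is monotone", {
  set.seed(43)
  weak <- paste(sample(c("A", "U", "G", "C"), 60, TRUE,
                       prob = c(.4, .4, .1, .1)), collapse = "")
  st <- min_hairpin(weak, require_negative = FALSE)
  if (!is.null(st)) expect_gt(st$dG, -10)

  cfg <- synthetic_config(seed = 47, n_clusters = 8)
  gg <- gen_genome(cfg)
  irs <- extract_all_intergenic_regions(
    find_importer_clusters(gg$bundle), gg$bundle)
  hi <- scan_ir_table(irs, dG_threshold = -10)
  lo <- scan_ir_table(irs, dG_threshold = -15)
  expect_lte(nrow(lo$table), nrow(hi$table))
  expect_true(all(lo$table$ir_id %in% hi$table$ir_id))
})
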