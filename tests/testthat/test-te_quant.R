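test_that("band-intensity TE follows the mono/(mono+bi) definition", {
  expect_equal(te_from_bands(0, 5), 0)
  expect_equal(te_from_bands(3, 3), 50)
  expect_equal(te_from_bands(96.1, 3.9), 96.1)
  expect_error(te_from_bands(-1, 5), "non-negative")
  expect_warning(v <- te_from_bands(0, 0), "zero total")
  expect_true(is.na(v))
})

test_that("band TE is scale-invariant and complements read-through", {
  set.seed(73)
  I_mono <- runif(1000, 0, 100)
  I_bi <- runif(1000, 0.01, 100)
  te <- te_from_bands(I_mono, I_bi)
  for (c_scale in c(0.01, 3, 1e4))
    expect_equal(te_from_bands(c_scale * I_mono, c_scale * I_bi), te)
  readthrough <- 100 * I_bi / (I_mono + I_bi)
  expect_equal(te + readthrough, rep(100, 1000))
})

test_that("qPCR TE maps the downstream/upstream ratio with clipping", {
  expect_equal(as.numeric(te_from_qpcr(1, 0.0930)), 90.70)
  expect_equal(as.numeric(te_from_qpcr(2, 2)), 0)
  clipped <- te_from_qpcr(1, 1.2)
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "clipped"))
  expect_error(te_from_qpcr(0, 1), "positive")
})

test_that("relative level follows the efficiency power law", {
  expect_equal(relative_level(20, 20), 1)
  expect_equal(relative_level(23, 20), 0.125)
  expect_equal(relative_level(18, 20, efficiency = 1.9), 1.9^2)
})

test_that("aggregation reports mean and sample sd per construct", {
  rec <- data.frame(construct_id = "c1", probe = "fbfp",
                    I_mono = c(30, 32, 34), I_bi = c(70, 68, 66),
                    replicate = 1:3)
  agg <- aggregate_te(rec, "northern")
  expect_equal(agg$te_percent, 32)
  expect_equal(agg$sd_percent, 2)
  expect_identical(agg$n_replicates, 3L)
  expect_false(agg$single_replicate)
  one <- aggregate_te(rec[1, ], "northern")
  expect_equal(one$sd_percent, 0)
  expect_true(one$single_replicate)
  # mcherry-probe lanes are not used for TE
  rec2 <- rbind(rec, data.frame(construct_id = "c1", probe = "mcherry",
                                I_mono = c(0, 0, 0), I_bi = c(9, 9, 9),
                                replicate = 1:3))
  expect_equal(aggregate_te(rec2, "northern")$te_percent, 32)
})

test_that("noisy triplicates recover the true TE within 3 standard errors", {
  set.seed(79)
  true_te <- c(slA = 60)
  means <- replicate(40, {
    tab <- gen_band_table(true_te, noise_sd = 5, replicates = 3)
    aggregate_te(tab, "northern")$te_percent
  })
  expect_lt(abs(mean(means) - 60), 3 * 5 / sqrt(3 * 40))
  expect_true(all(abs(means - 60) < 4 * 5 / sqrt(3)))
})

test_that("correlate returns exact values on constructed input", {
  x <- 1:10
  r <- correlate(x, 2 * x)
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  r0 <- correlate(1:4, c(1, -1, -1, 1))   # constructed orthogonal pair
  expect_lt(r0$r2, 1e-20)
  expect_error(correlate(1:2, 1:2), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("Northern and qPCR estimates converge as noise vanishes", {
  set.seed(83)
  true_te <- stats::setNames(seq(15, 95, length.out = 12),
                             sprintf("c%02d", 1:12))
  r2s <- vapply(c(8, 2, 0.2), function(sdv) {
    bands <- gen_band_table(true_te, noise_sd = sdv, replicates = 3)
    q <- gen_qpcr_table(true_te, noise_sd = sdv / 20, replicates = 3)
    a_n <- aggregate_te(bands, "northern")
    a_q <- aggregate_te(qpcr_relative_table(q), "qpcr")
    m <- merge(a_n, a_q, by = "construct_id")
    correlate(m$te_percent.x, m$te_percent.y)$r2
  }, 0)
  expect_true(all(diff(r2s) >= 0) || r2s[3] > r2s[1])
  expect_gt(r2s[3], 0.99)
})

test_that("log2 fold change of upstream over downstream levels", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(8, 1), 3)
  expect_equal(log2_fold_change(1, 4), -2)
  expect_error(log2_fold_change(0, 1), "positive")
})
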