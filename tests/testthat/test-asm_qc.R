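test_that("window medians tile scaffolds exactly", {
  set.seed(401)
  asm <- c(s = rand_dna(2500, 0.5))
  tr <- data.frame(seq_id = "s", start = 0L, end = 2500L, depth = 30)
  w <- window_medians(tr, asm)
  expect_equal(nrow(w), 3L)
  expect_equal(w$end - w$start, c(1000L, 1000L, 500L))
  expect_true(all(w$median_depth_raw == 30))
  expect_equal(sum(w$end - w$start), 2500L)
})

test_that("the window median follows the even-count convention", {
  set.seed(402)
  asm <- c(s = rand_dna(1000, 0.5))
  tr <- data.frame(seq_id = "s", start = c(0L, 500L), end = c(500L, 1000L),
                   depth = c(0, 10))
  w <- window_medians(tr, asm)
  expect_equal(w$median_depth_raw, 5)   # median of {0 x500, 10 x500}
})

test_that("GC normalization is the identity when only one bin is populated", {
  set.seed(403)
  asm <- c(s = paste(rep("ACGT", 2500), collapse = ""))  # constant 50% GC
  tr <- data.frame(seq_id = "s", start = 0L, end = 10000L, depth = 20)
  wn <- gc_normalize(window_medians(tr, asm))
  expect_equal(wn$median_depth_norm, wn$median_depth_raw)
})

test_that("GC normalization removes a planted linear bias", {
  cfg <- assembly_config(n_chrom = 3, chrom_len = 60000)
  sim <- simulate_assembly(cfg, seed = 404)
  tr <- simulate_depth(sim$assembly, mean_depth = 30, gc_bias_slope = 0.8,
                       seed = 405)
  wn <- gc_normalize(window_medians(tr, sim$assembly))
  raw_slope <- coef(lm(wn$median_depth_raw ~ wn$gc))[2] / 30
  norm_slope <- coef(lm(wn$median_depth_norm ~ wn$gc))[2] / 30
  expect_gt(abs(raw_slope), 0.5)
  expect_lt(abs(norm_slope), 0.05)
  # without bias the normalization is a near-identity
  tr0 <- simulate_depth(sim$assembly, mean_depth = 30, gc_bias_slope = 0,
                        seed = 406)
  wn0 <- gc_normalize(window_medians(tr0, sim$assembly))
  expect_lt(max(abs(wn0$median_depth_norm / wn0$median_depth_raw - 1),
                na.rm = TRUE), 0.1)
  expect_lt(median(abs(wn0$median_depth_norm - wn0$median_depth_raw) /
                     wn0$median_depth_raw), 0.02)
})

test_that("scaffold flagging applies the strict 70% rule", {
  # two scaffolds of 10 windows on a large common depth background; one
  # gets 8 outlier windows (flagged), the other exactly 7 (not flagged)
  wins <- data.frame(
    seq_id = rep(c("bg", "s8", "s7"), c(180, 10, 10)),
    start = 0L, end = 1000L, gc = 0.5,
    median_depth_raw = c(rep(30, 180),
                         c(rep(0, 8), 30, 30),
                         c(rep(0, 7), 30, 30, 30)))
  wins$median_depth_norm <- wins$median_depth_raw
  fl <- flag_low_accuracy(wins)
  expect_true(fl$flagged[fl$seq_id == "s8"])
  expect_false(fl$flagged[fl$seq_id == "s7"])
  expect_equal(fl$frac_outlier_windows[fl$seq_id == "s7"], 0.7)
})

test_that("junk scaffolds are always flagged and clean ones never", {
  for (s in 1:3) {
    cfg <- assembly_config(n_chrom = 3, chrom_len = 60000, n_junk = 3,
                           junk_len = 5000)
    sim <- simulate_assembly(cfg, seed = 500 + s)
    tr <- simulate_depth(sim$assembly, mean_depth = 30, gc_bias_slope = 0.8,
                         junk_ids = sim$truth$junk, seed = 600 + s)
    fl <- flag_low_accuracy(gc_normalize(window_medians(tr, sim$assembly)))
    expect_equal(sum(fl$flagged[fl$seq_id %in% sim$truth$junk]), 3L)
    expect_equal(sum(fl$flagged[!fl$seq_id %in% sim$truth$junk]), 0L)
  }
})

test_that("flags are invariant under global depth rescaling", {
  cfg <- assembly_config(n_chrom = 2, chrom_len = 40000, n_junk = 2,
                         junk_len = 5000)
  sim <- simulate_assembly(cfg, seed = 407)
  tr <- simulate_depth(sim$assembly, mean_depth = 30,
                       junk_ids = sim$truth$junk, seed = 408)
  fl1 <- flag_low_accuracy(gc_normalize(window_medians(tr, sim$assembly)))
  tr$depth <- tr$depth * 13
  fl2 <- flag_low_accuracy(gc_normalize(window_medians(tr, sim$assembly)))
  expect_identical(fl1$flagged, fl2$flagged)
})

test_that("SV error filtering applies the strict support-ratio rule", {
  svs <- data.frame(
    seq_id = "c", pos = c(1, 2, 3, 4),
    sv_len = c(60, 40, 50, 55),
    ref_support = c(1, 0, 4, 0),
    alt_support = c(19, 30, 16, 0))
  expect_warning(err <- filter_sv_errors(svs), "zero total support")
  # len 60 ratio 0.05 -> error; len 40 fails size; len 50 ratio exactly 0.2
  # is not < 0.2; zero-support record excluded
  expect_equal(err$pos, 1)
  svs$ref_support[1] <- -1
  expect_error(filter_sv_errors(svs), "negative")
})
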