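test_that("generated elements carry the canonical terminal structure", {
  set.seed(101)
  for (i in 1:25) {
    el <- make_element(element_spec())
    L <- el$truth$length
    expect_identical(substr(el$seq, 1, 2), "TC")
    expect_identical(substr(el$seq, L - 3, L), "CTAG")
    # planted hairpin span is exactly self-reverse-complementary
    hp <- substr(el$seq, el$truth$hairpin_start + 1, el$truth$hairpin_end)
    expect_identical(revcomp(hp), hp)
    expect_true(el$truth$hairpin_end >= L - 4 - 12)
    expect_gte(L, 200)
  }
})

test_that("element lengths follow the configured distribution", {
  set.seed(102)
  lens <- vapply(1:2000, function(i) make_element(element_spec())$truth$length,
                 integer(1))
  # symmetric truncation keeps the mean at the configured value
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 1092), 3 * sqrt(558^2 / length(lens)))
  expect_gte(min(lens), 200)
})

test_that("unrequested substructures are genuinely absent", {
  set.seed(103)
  for (i in 1:10) {
    el <- make_element(element_spec(), with_subtir = FALSE)
    expect_false(el$truth$has_subtir)
    expect_null(find_subtir(el$seq))
    expect_null(find_microsat(el$seq))
  }
})

test_that("plant_elements honors degenerate AT-site probabilities", {
  set.seed(104)
  host <- rand_dna(60000, 0.4)
  pl <- plant_elements(host, 20, element_spec(p_at_site = 1), seq_id = "c")
  expect_true(all(pl$truth$at_site))
  # flanks on the forward strand are A...T for AT-site insertions
  for (i in seq_len(nrow(pl$truth))) {
    expect_identical(substr(pl$seq, pl$truth$start[i], pl$truth$start[i]),
                     "A")
    expect_identical(substr(pl$seq, pl$truth$end[i] + 1,
                            pl$truth$end[i] + 1), "T")
  }
  pl0 <- plant_elements(host, 0, element_spec())
  expect_identical(pl0$seq, host)
  expect_equal(nrow(pl0$truth), 0L)
})

test_that("planted intervals are disjoint and validate against the host", {
  set.seed(105)
  host <- rand_dna(120000, 0.4)
  pl <- plant_elements(host, 40, element_spec(), seq_id = "c")
  tr <- pl$truth[order(pl$truth$start), ]
  expect_true(all(tr$end[-nrow(tr)] <= tr$start[-1]))
  expect_true(all(tr$end <= nchar(pl$seq)))
  expect_equal(nchar(pl$seq), nchar(host) + sum(tr$length))
  # planted element text matches its truth interval and strand
  for (i in sample(nrow(tr), 8)) {
    s <- substr(pl$seq, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") s <- revcomp(s)
    expect_identical(substr(s, 1, 2), "TC")
    expect_identical(substr(s, nchar(s) - 3, nchar(s)), "CTAG")
  }
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- assembly_config(n_chrom = 2, chrom_len = 20000,
                         elements_per_chrom = 3, n_haplotigs = 1)
  a <- simulate_assembly(cfg, seed = 42)
  b <- simulate_assembly(cfg, seed = 42)
  expect_identical(a, b)
  r1 <- simulate_reads(a$assembly[[1]], depth = 3, seed = 9)
  r2 <- simulate_reads(a$assembly[[1]], depth = 3, seed = 9)
  expect_identical(r1, r2)
  d1 <- simulate_depth(a$assembly, mean_depth = 10, seed = 5)
  d2 <- simulate_depth(a$assembly, mean_depth = 10, seed = 5)
  expect_identical(d1, d2)
})

test_that("haplotig truth records are mutated subsequences of their source", {
  cfg <- assembly_config(n_chrom = 2, chrom_len = 30000, n_haplotigs = 2,
                         haplotig_frac = 0.3, haplotig_div = 0.03)
  sim <- simulate_assembly(cfg, seed = 77)
  ht <- sim$truth$haplotigs
  for (i in seq_len(nrow(ht))) {
    src <- substr(sim$assembly[[ht$source[i]]], ht$start[i] + 1, ht$end[i])
    hseq <- sim$assembly[[ht$haplotig_id[i]]]
    expect_equal(nchar(hseq), nchar(src))
    div <- str_hamming(hseq, src) / nchar(src)
    expect_gt(div, 0.015)
    expect_lt(div, 0.045)
  }
})

test_that("simulated depth is non-negative with unbiased window means", {
  set.seed(106)
  asm <- c(s1 = rand_dna(50000, 0.4))
  tr <- simulate_depth(asm, mean_depth = 30, gc_bias_slope = 0, seed = 8)
  expect_true(all(tr$depth >= 0))
  v <- oystr:::depth_vector(tr, "s1", 50000)
  means <- tapply(v, (seq_along(v) - 1) %/% 1000, mean)
  se <- sqrt(30 / 1000)
  expect_true(mean(abs(means - 30) < 3 * se) > 0.95)
})

test_that("noise-free marker maps are perfectly monotone per scaffold", {
  cl <- setNames(rep(2e6, 2), c("lg1", "lg2"))
  map <- split_chromosomes(cl, pieces = 2, seed = 3)
  mk <- simulate_markers(map, markers_per_chrom = 25, cm_noise_sd = 0,
                         seed = 4)
  for (sc in unique(mk$seq_id)) {
    m <- mk[mk$seq_id == sc, ]
    if (nrow(m) < 2) next
    rho <- suppressWarnings(cor(m$cm, m$pos, method = "spearman"))
    expect_equal(abs(rho), 1)
  }
  # all-low MAPQ leaves nothing after the strict filter
  mk_low <- simulate_markers(map, markers_per_chrom = 25, p_low_mapq = 1,
                             low_mapq = 0, seed = 4)
  expect_equal(nrow(filter_markers(mk_low)), 0L)
})
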