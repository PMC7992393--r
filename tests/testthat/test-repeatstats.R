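test_that("end30 slices the terminal 30 bp on the element's own strand", {
  set.seed(901)
  el <- make_element(element_spec(), seed = 3)
  e30 <- end30(el$seq)
  expect_equal(nchar(e30), 30L)
  expect_identical(substr(e30, 27, 30), "CTAG")
  expect_identical(e30, substr(el$seq, el$truth$length - 29,
                               el$truth$length))
  expect_error(end30(strrep("A", 20)), "shorter")
  # strand-aware extraction through element_seq
  host <- rand_dna(40000, 0.4)
  pl <- plant_elements(host, 5, element_spec(), seq_id = "c", p_minus = 1)
  asm <- c(c = pl$seq)
  sc <- scan_genome(asm)
  seqs <- element_seq(asm, sc)
  expect_true(all(substr(end30(seqs), 27, 30) == "CTAG"))
})

test_that("pair identity follows the matching-columns convention", {
  set.seed(902)
  a <- rand_dna(30)
  expect_equal(pair_identity(a, a), 1.0)
  b <- mutate_positions(a, 1)
  expect_equal(pair_identity(a, b), 29 / 30)
  b6 <- a
  for (p in sample(30, 6)) {
    substr(b6, p, p) <- setdiff(BASES, substr(a, p, p))[1]
  }
  expect_equal(pair_identity(a, b6), 24 / 30)
  expect_gte(pair_identity(a, b6), 0.80)
})

test_that("greedy clustering reproduces well-separated families exactly", {
  set.seed(903)
  fx <- two_family_fixture(n_per_family = 25)
  cl <- greedy_cluster(fx$seqs)
  expect_equal(length(unique(cl$family_id)), 2L)
  # same partition as single-linkage brute force on Hamming identity
  sl <- oracle_single_linkage(fx$seqs)
  expect_equal(length(unique(sl)), 2L)
  expect_equal(length(unique(paste(cl$family_id, sl))), 2L)
  expect_identical(cl$family_id == cl$family_id[1], fx$truth == 1)
})

test_that("clustering degenerate inputs behave as defined", {
  seqs <- rep(strrep("ACGTA", 6), 5)
  cl <- greedy_cluster(seqs)
  expect_equal(length(unique(cl$family_id)), 1L)
  expect_equal(conserved_end_count(cl), 5L)
  # mutually dissimilar inputs give all singletons
  set.seed(904)
  repeat {
    rnd <- vapply(1:8, function(i) rand_dna(30), character(1))
    ids <- outer(seq_along(rnd), seq_along(rnd), Vectorize(function(i, j) {
      if (i >= j) 0 else (30 - str_hamming(rnd[i], rnd[j])) / 30
    }))
    if (max(ids) < 0.6) break
  }
  cl2 <- greedy_cluster(rnd)
  expect_equal(length(unique(cl2$family_id)), 8L)
  expect_equal(conserved_end_count(cl2), 0L)
  expect_equal(conserved_end_count(cl2, count_all = TRUE), 8L)
})

test_that("clustering is stable under input permutation", {
  set.seed(905)
  fx <- two_family_fixture(n_per_family = 15)
  cl <- greedy_cluster(fx$seqs)
  perm <- sample(length(fx$seqs))
  cl_p <- greedy_cluster(fx$seqs[perm])
  # partitions agree after mapping back through the permutation
  expect_equal(length(unique(paste(cl$family_id[perm], cl_p$family_id))),
               length(unique(cl_p$family_id)))
})

test_that("capture screen finds planted fragments and rejects noise", {
  set.seed(906)
  prot <- paste(sample(AA20, 180, replace = TRUE), collapse = "")
  frag60 <- substr(prot, 40, 99)
  elem <- paste0("TC", rand_dna(240, 0.45), encode_protein(frag60),
                 rand_dna(150, 0.45), "CTAG")
  hits <- capture_screen(elem, c(p1 = prot))
  expect_gte(nrow(hits), 1L)
  expect_gt(hits$aln_len[1], 50)
  expect_gte(hits$identity[1], 0.85)
  # a 45-residue exact fragment fails the length rule
  frag45 <- substr(prot, 40, 84)
  elem45 <- paste0("TC", rand_dna(240, 0.45), encode_protein(frag45),
                   rand_dna(150, 0.45), "CTAG")
  expect_equal(nrow(capture_screen(elem45, c(p1 = prot))), 0L)
  # elements with no coding content give no match
  set.seed(907)
  nulls <- vapply(1:10, function(i) rand_dna(900, 0.45), character(1))
  expect_equal(nrow(capture_screen(nulls, c(p1 = prot))), 0L)
})

test_that("window counting uses the highest-length-coverage rule", {
  f <- feature_table(c("c1", "c1"), c(95000L, 98000L), c(103000L, 102000L),
                     ".", c("gene", "LTR"))
  wc <- window_counts(f, c(c1 = 300000))
  # [95k,103k): 5 kb in window 0, 3 kb in window 1 -> window 0
  expect_equal(wc$gene_count, c(1L, 0L, 0L))
  # [98k,102k): exact 2 kb / 2 kb tie -> lower window
  expect_equal(wc$LTR_count, c(1L, 0L, 0L))
  expect_error(window_counts(
    feature_table("c9", 0L, 10L), c(c1 = 1000)), "unknown")
})

test_that("window counting conserves the total feature count", {
  set.seed(908)
  for (i in 1:5) {
    n <- 200
    lens <- c(c1 = 550000, c2 = 230000)
    sid <- sample(names(lens), n, replace = TRUE)
    w <- sample(100:220000, n, replace = TRUE)
    st <- vapply(seq_len(n), function(j) {
      sample.int(lens[[sid[j]]] - w[j], 1) - 1L
    }, integer(1))
    f <- feature_table(sid, st, st + w, ".",
                       sample(c("gene", "LTR", "LINE"), n, replace = TRUE))
    wc <- window_counts(f, lens)
    cnt_cols <- grep("_count$", names(wc), value = TRUE)
    expect_equal(sum(unlist(wc[cnt_cols])), n)
  }
})

test_that("density correlation matches the closed form and cor.test", {
  x <- c(1, 4, 2, 8, 5)
  y <- c(3, 9, 1, 11, 6)
  d <- density_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(d$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(d$p, ct$p.value, tolerance = 1e-10)
  expect_equal(density_correlation(1:10, -(1:10))$r, -1)
  expect_true(is.na(density_correlation(rep(1, 5), 1:5)$r))
  ds <- density_correlation(x, y, method = "spearman")
  expect_equal(ds$r, unname(cor.test(x, y, method = "spearman")$estimate))
})

test_that("independent counts rarely correlate", {
  set.seed(909)
  big <- vapply(1:50, function(i) {
    abs(density_correlation(rnorm(200), rnorm(200))$r)
  }, numeric(1))
  expect_gte(mean(big < 0.2), 0.95)
})

test_that("density and enrichment arithmetic", {
  expect_equal(helitron_density(0, 50), 0)
  expect_equal(helitron_density(100, 50), 2)
  expect_equal(helitron_density(751, 647.887097), 1.159152,
               tolerance = 1e-6)
  expect_error(helitron_density(10, 0), "positive")
  expect_length(chromosome_enrichment(setNames(rep(2, 5),
                                               paste0("lg", 1:5))), 0L)
  d <- setNames(c(1, 1, 1, 1, 5), paste0("lg", 1:5))
  expect_identical(chromosome_enrichment(d), "lg5")
  # one chromosome far above the rest in a 10-chromosome fixture
  d10 <- setNames(c(rep(1, 9), 3), paste0("lg", 1:10))
  expect_identical(chromosome_enrichment(d10), "lg10")
})
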