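test_that("minimizer sketches behave like a canonical sampler", {
  set.seed(301)
  s <- rand_dna(10000, 0.45)
  idx <- build_minimizer_index(c(a = s, b = s, r = revcomp(s)))
  # identical contigs share all minimizers
  expect_identical(idx$a$hash, idx$b$hash)
  # a contig and its reverse complement share the canonical minimizer set
  expect_identical(sort(unique(idx$a$hash)), sort(unique(idx$r$hash)))
  # unrelated contigs share almost nothing
  idx2 <- build_minimizer_index(c(x = rand_dna(10000, 0.45),
                                  y = rand_dna(10000, 0.45)))
  shared <- mean(idx2$x$hash %in% idx2$y$hash)
  expect_lt(shared, 0.01)
})

test_that("map_contig sees containment, divergence and unrelatedness", {
  set.seed(302)
  target <- rand_dna(20000, 0.45)
  contigs <- c(
    t = target,
    half = paste0(substr(target, 5000, 10000), rand_dna(5001, 0.45)),
    div = mutate_positions(substr(target, 1, 12000),
                           round(0.03 * 12000)),
    unrel = rand_dna(12000, 0.45))
  idx <- build_minimizer_index(contigs)
  frac <- function(q) map_contig(q, idx, "t")$query_covered_frac
  expect_gte(frac("half"), 0.45)
  expect_lte(frac("half"), 0.55)
  expect_gte(frac("div"), 0.9)
  expect_lte(frac("unrel"), 0.05)
})

test_that("iterative purge implements the length-ordered removal rule", {
  set.seed(303)
  A <- rand_dna(100000, 0.45)
  B <- mutate_positions(substr(A, 20000, 70000), round(0.03 * 50001))
  C <- mutate_positions(substr(A, 40000, 45000), 100)
  pr <- iterative_purge(c(A = A, B = B, C = C))
  # B is a >10 kb haplotig of A; C matches but fails the length condition
  expect_setequal(pr$kept_ids, c("A", "C"))
  expect_identical(pr$removed$contig_id, "B")
  expect_identical(pr$removed$reason, "haplotig_map")
  expect_identical(pr$removed$ref_id, "A")

  # nothing exceeds thresholds: everything kept
  pr2 <- iterative_purge(c(x = rand_dna(20000), y = rand_dna(20000)))
  expect_equal(nrow(pr2$removed), 0L)

  # three mutually identical contigs: exactly the lexicographically first
  # is kept at equal length
  s <- rand_dna(20000, 0.45)
  pr3 <- iterative_purge(c(kb = s, ka = s, kc = s))
  expect_identical(pr3$kept_ids, "ka")
})

test_that("soft-masked repeat matches are ignored by the mapper", {
  set.seed(304)
  repeat_seq <- rand_dna(12000, 0.45)
  c1 <- paste0(rand_dna(4000, 0.45), repeat_seq, rand_dna(4000, 0.45))
  c2 <- paste0(rand_dna(6000, 0.45), repeat_seq, rand_dna(2000, 0.45))
  # unmasked: the shared repeat covers ~60% of c2, so c2 is removed
  pr <- iterative_purge(c(c1 = c1, c2 = c2), min_len = 5000)
  expect_identical(pr$removed$contig_id, "c2")
  # masked: the repeat no longer counts, both contigs survive
  mask <- feature_table(c("c1", "c2"), c(4000L, 6000L),
                        c(16000L, 18000L), ".", "satellite")
  pr2 <- iterative_purge(c(c1 = c1, c2 = c2), mask = mask, min_len = 5000)
  expect_equal(nrow(pr2$removed), 0L)
})

test_that("purge decisions match the exact-alignment oracle", {
  set.seed(305)
  contigs <- character(0)
  base <- rand_dna(6000, 0.45)
  contigs["a"] <- base
  contigs["b"] <- mutate_positions(substr(base, 500, 4300), 110)
  contigs["c"] <- rand_dna(4500, 0.45)
  contigs["d"] <- mutate_positions(substr(base, 2000, 3900), 50)
  contigs["e"] <- rand_dna(2500, 0.45)
  contigs["f"] <- paste0(substr(contigs[["c"]], 100, 2600),
                         rand_dna(200, 0.45))
  appx <- iterative_purge(contigs, min_len = 1000)
  orac <- iterative_purge(contigs, min_len = 1000,
    coverage_fun = function(q, t) {
      oystr:::alignment_covered_frac(contigs[[q]], contigs[[t]])
    })
  expect_setequal(appx$kept_ids, orac$kept_ids)
  expect_setequal(appx$removed$contig_id, orac$removed$contig_id)
})

test_that("purge is idempotent on its own kept set", {
  cfg <- assembly_config(n_chrom = 3, chrom_len = 50000, n_haplotigs = 4,
                         haplotig_frac = 0.5, haplotig_div = 0.03)
  sim <- simulate_assembly(cfg, seed = 306)
  pr <- iterative_purge(sim$assembly)
  pr2 <- iterative_purge(sim$assembly[pr$kept_ids])
  expect_equal(nrow(pr2$removed), 0L)
  expect_setequal(pr2$kept_ids, pr$kept_ids)
})

test_that("keep-list intersection keeps common contigs and labels the rest", {
  u <- c("x", "y", "z")
  r <- intersect_keep_lists(c("x", "y"), c("y", "z"), u)
  expect_identical(r$kept_ids, "y")
  expect_setequal(r$removed$contig_id, c("x", "z"))
  expect_true(all(r$removed$reason == "external_only"))
  expect_identical(intersect_keep_lists(u, u, u)$kept_ids, u)
  expect_warning(intersect_keep_lists("x", "z", u), "empty")
  expect_error(intersect_keep_lists("q", "x", u), "universe")
})
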