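test_that("hairpin finder handles canonical and degenerate cases", {
  # 16-bp exactly self-reverse-complementary span
  hp <- find_hairpins("ACGTACGTACGTACGT", max_mismatch = 0)
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$stem, 8L)
  expect_equal(hp$loop, 0L)
  expect_equal(hp$mismatches, 0L)
  # below the minimum span: nothing
  expect_equal(nrow(find_hairpins(strrep("GAATTC", 2))), 0L)
  expect_equal(nrow(find_hairpins(paste(rep("A", 30), collapse = ""))), 0L)
})

test_that("hairpin finder equals exhaustive enumeration on random DNA", {
  set.seed(701)
  for (i in 1:6) {
    s <- rand_dna(1500, runif(1, 0.3, 0.6))
    expect_equal(find_hairpins(s), oracle_hairpins(s),
                 ignore_attr = TRUE)
    # strict profile too (loop 0, no mismatches)
    expect_equal(
      find_hairpins(s, min_stem = 8, max_mismatch = 0, max_loop = 0),
      oracle_hairpins(s, min_stem = 8, max_mismatch = 0, max_loop = 0),
      ignore_attr = TRUE)
  }
})

test_that("3' candidates demand a hairpin within the configured gap", {
  set.seed(702)
  pal <- "ACGTACGTACGTACGT"          # perfect palindrome, stem 8
  # hairpin ends 6 bp before CTAG: inside the default [2, 30] gap
  s1 <- paste0(rand_dna(60, 0.5), pal, "AAAAAA", "CTAG", rand_dna(40, 0.5))
  th1 <- find_3prime_candidates(s1, max_mismatch = 0)
  expect_true((60 + 16 + 6 + 4) %in% th1$pos)
  # no hairpin upstream: no candidate at that CTAG
  s2 <- paste0(strrep("A", 80), "CTAG", strrep("A", 40))
  expect_equal(nrow(find_3prime_candidates(s2, max_mismatch = 0)), 0L)
  # hairpin 40 bp upstream of the CTAG: outside the gap
  s3 <- paste0(rand_dna(60, 0.5), pal, strrep("A", 40), "CTAG",
               strrep("A", 40))
  th3 <- find_3prime_candidates(s3, max_mismatch = 0)
  expect_false((60 + 16 + 40 + 4) %in% th3$pos)
})

test_that("5' candidates enumerate TC positions with flanks", {
  f <- find_5prime_candidates("ATCG")
  expect_equal(f$pos, 1L)
  expect_equal(f$flank, "A")
  expect_equal(nrow(find_5prime_candidates("TTTT")), 0L)
  set.seed(703)
  s <- rand_dna(2000, 0.5)
  f2 <- find_5prime_candidates(s)
  # brute-force count of TC dinucleotides
  x <- strsplit(s, "")[[1]]
  expect_equal(nrow(f2), sum(x[-length(x)] == "T" & x[-1] == "C"))
})

test_that("planted elements are recovered with exact coordinates", {
  set.seed(704)
  host <- rand_dna(300000, 0.4)
  pl <- plant_elements(host, 40, element_spec(), seq_id = "chr")
  sc <- scan_genome(c(chr = pl$seq))
  key_t <- paste(pl$truth$start, pl$truth$end, pl$truth$strand)
  key_s <- paste(sc$start, sc$end, sc$strand)
  expect_gte(mean(key_t %in% key_s), 0.95)
  m <- match(key_t, key_s)
  ok <- !is.na(m)
  expect_true(all(sc$at_site[m[ok]] == pl$truth$at_site[ok]))
})

test_that("every emitted candidate satisfies its own invariants", {
  set.seed(705)
  host <- rand_dna(150000, 0.4)
  pl <- plant_elements(host, 25, element_spec(), seq_id = "chr")
  asm <- c(chr = pl$seq)
  sc <- scan_genome(asm)
  seqs <- element_seq(asm, sc)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    expect_identical(substr(s, 1, 2), "TC")
    expect_identical(substr(s, nchar(s) - 3, nchar(s)), "CTAG")
    expect_gte(nchar(s), 200)
    hp <- substr(s, sc$hp_rel_start[i] + 1, sc$hp_rel_end[i])
    expect_identical(revcomp(hp), hp)     # strict profile: perfect palindrome
    gap <- (nchar(s) - 4) - sc$hp_rel_end[i]
    expect_gte(gap, 2)
    expect_lte(gap, 12)
  }
})

test_that("scanning is strand symmetric", {
  set.seed(706)
  for (s in 1:3) {
    host <- rand_dna(80000, 0.4)
    pl <- plant_elements(host, 12, element_spec(), seq_id = "g")
    g <- pl$seq
    fwd <- scan_genome(c(g = g))
    rev <- scan_genome(c(g = revcomp(g)))
    L <- nchar(g)
    mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                           strand = ifelse(rev$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start), ]
    expect_identical(mirrored$start, fwd$start)
    expect_identical(mirrored$end, fwd$end)
    expect_identical(mirrored$strand, fwd$strand)
  }
  expect_equal(nrow(scan_genome(character(0))), 0L)
})

test_that("termini pairing picks the nearest compatible 5' candidate", {
  set.seed(707)
  el <- make_element(element_spec(), seed = 9)
  # embed with a decoy TC 100 bp upstream of the element (outside it)
  s <- paste0(strrep("G", 50), "TC", strrep("G", 98), el$seq,
              strrep("G", 60))
  sc <- scan_genome(c(x = s))
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$start, 150L)           # the element's own TC, not the decoy
  expect_equal(sc$end, 150L + el$truth$length)
  # a 3' candidate with no 5' within range yields nothing
  pal <- "ACGTACGTACGTACGT"
  s2 <- paste0(strrep("G", 300), pal, "AAAAAA", "CTAG", strrep("G", 50))
  expect_equal(nrow(scan_genome(c(y = s2))), 0L)
})
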