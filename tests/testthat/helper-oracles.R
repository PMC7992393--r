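# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results by the most direct means available (character vectors,
# exhaustive enumeration, exact alignment) so they share no code path with
# the implementations they check.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "X")

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

mutate_positions <- function(seq, n_mut) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample(length(ch), n_mut)) {
    ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

str_hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# Exhaustive hairpin enumeration over all (start, span) pairs, vectorized
# over starts (the span/stem loops stay explicit).
oracle_hairpins <- function(seq, span_range = c(16, 20), min_stem = 6,
                            max_mismatch = 1, max_loop = NULL) {
  x <- strsplit(seq, "")[[1]]
  cx <- COMP[x]
  n <- length(x)
  rows <- list()
  for (s in span_range[1]:span_range[2]) {
    if (s > n) next
    starts <- seq_len(n - s + 1)               # 1-based span starts
    tmax <- s %/% 2
    tmin <- max(min_stem,
                if (is.null(max_loop)) 1 else ceiling((s - max_loop) / 2))
    if (tmin > tmax) next
    cum <- integer(length(starts))
    best_t <- rep(NA_integer_, length(starts))
    best_mm <- rep(NA_integer_, length(starts))
    for (t in seq_len(tmax)) {
      cum <- cum + (x[starts + t - 1] != cx[starts + s - t])
      if (t >= tmin) {
        upd <- cum <= max_mismatch            # larger t overwrites smaller
        best_t[upd] <- t
        best_mm[upd] <- cum[upd]
      }
    }
    hit <- which(!is.na(best_t))
    if (length(hit)) {
      rows[[length(rows) + 1]] <- data.frame(
        start = starts[hit] - 1, end = starts[hit] - 1 + s,
        stem = best_t[hit], loop = s - 2 * best_t[hit],
        mismatches = best_mm[hit])
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop = integer(0),
                      mismatches = integer(0)))
  }
  hp <- do.call(rbind, rows)
  drop <- rep(FALSE, nrow(hp))
  for (a in seq_len(nrow(hp))) {
    inside <- hp$stem == hp$stem[a] & hp$start <= hp$start[a] &
      hp$end >= hp$end[a] & (hp$start < hp$start[a] | hp$end > hp$end[a])
    if (any(inside)) drop[a] <- TRUE
  }
  hp <- hp[!drop, , drop = FALSE]
  hp <- hp[order(hp$start, hp$end), , drop = FALSE]
  rownames(hp) <- NULL
  hp
}

# Brute-force canonical k-mer histogram via substring enumeration.
oracle_kmer_hist <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("N", kmers)]
  rc <- vapply(kmers, function(s) {
    paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  canon <- pmin(kmers, rc)
  tab <- table(canon)
  hist <- table(as.integer(tab))
  data.frame(depth = as.integer(names(hist)), count = as.integer(hist))
}

# Brute-force subTIR search over all window substring pairs.
oracle_subtir <- function(elem, terminal_window = 50, min_len = 10,
                          max_mismatch = 1) {
  L <- nchar(elem)
  w5 <- strsplit(substr(elem, 1, terminal_window), "")[[1]]
  w3 <- strsplit(substr(elem, L - terminal_window + 1, L), "")[[1]]
  n5 <- length(w5)
  n3 <- length(w3)
  best <- NULL
  for (len in seq.int(min(n5, n3), min_len)) {
    found <- NULL
    for (i in 0:(n5 - len)) {
      rc5 <- COMP[w5[(i + len):(i + 1)]]
      for (j in 0:(n3 - len)) {
        mm <- sum(w3[(j + 1):(j + len)] != rc5)
        if (mm <= max_mismatch) {
          tie <- i + (n3 - (j + len))
          if (is.null(found) || tie < found$tie ||
              (tie == found$tie && i < found$i)) {
            found <- list(i = i, j = j, len = len, mm = mm, tie = tie)
          }
        }
      }
    }
    if (!is.null(found)) {
      best <- list(pos5 = found$i, pos3 = L - terminal_window + found$j,
                   length = found$len, mismatches = found$mm)
      break
    }
  }
  best
}

# Brute-force microsatellite search: all units, phases and extents.
oracle_microsat <- function(elem, window = 50, unit_range = c(1, 6),
                            min_copies = 3, min_span = 9) {
  w <- substr(elem, 1, min(window, nchar(elem)))
  n <- nchar(w)
  best <- NULL
  for (u in unit_range[1]:unit_range[2]) {
    for (start in 0:(n - u)) {
      unit <- substr(w, start + 1, start + u)
      span <- u
      while (start + span < n &&
             substr(w, start + span + 1, start + span + 1) ==
             substr(w, start + (span %% u) + 1, start + (span %% u) + 1)) {
        span <- span + 1
      }
      copies <- span %/% u
      if (copies >= min_copies && span >= min_span) {
        if (is.null(best) || span > best$span ||
            (span == best$span && u < nchar(best$unit))) {
          best <- list(pos = start, unit = unit, copies = copies,
                       span = span)
        }
      }
    }
  }
  best
}

# Single-linkage clustering at a Hamming-identity threshold (valid oracle
# for gap-free fixtures where alignment identity equals Hamming identity).
oracle_single_linkage <- function(seqs, id_threshold = 0.80) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if ((30 - str_hamming(seqs[a], seqs[b])) / 30 >= id_threshold) {
        ra <- find(a)
        rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Two well-separated 3'-end families: within-family identity >= 0.93,
# between-family identity <= 0.5 (seeds at Hamming distance >= 17).
two_family_fixture <- function(n_per_family = 20, max_mut = 2) {
  repeat {
    s1 <- rand_dna(30)
    s2 <- rand_dna(30)
    if (str_hamming(s1, s2) >= 17) break
  }
  fam <- function(seed_seq, n) {
    vapply(seq_len(n), function(i) {
      mutate_positions(seed_seq, sample(0:max_mut, 1))
    }, character(1))
  }
  list(seqs = c(fam(s1, n_per_family), fam(s2, n_per_family)),
       truth = rep(1:2, each = n_per_family))
}

# Minimal Sniffles-style SV VCF fixture.
write_sv_vcf_fixture <- function(path, seq_id, pos, sv_len, dr, dv) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"ref reads\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"variant reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  rec <- sprintf("%s\t%d\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=%d\tDR:DV\t%d:%d",
                 seq_id, pos, sv_len, dr, dv)
  writeLines(c(hdr, rec), path)
  path
}

# Amino-acid alphabet and a codon per residue (for capture fixtures).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
CODON1 <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "TTA", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
            S = "AGT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode_protein <- function(aa_string) {
  paste(CODON1[strsplit(aa_string, "")[[1]]], collapse = "")
}

# Exact (Clopper-Pearson style via qbinom) binomial 99% acceptance band for
# an observed count at the given n and p.
binom99_band <- function(n, p) {
  c(lo = qbinom(0.005, n, p), hi = qbinom(0.995, n, p))
}
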