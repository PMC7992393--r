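#' Specification of a synthetic Helitron-like element
#'
#' Defaults encode the structural statistics observed for intact oyster
#' Helitron-like sequences: length ~ Normal(1092, 558) bp (truncated
#' symmetrically to `[200, 1984]` so the floor does not shift the mean), a
#' perfectly self-complementary hairpin of 16-20 bp (even spans only, since
#' an odd-length span cannot be exactly self-reverse-complementary) ending
#' 5-10 bp upstream of the terminal `CTAG`, AT target-site preference of
#' 0.86, and Helentron substructure rates matching the observed fractions
#' (subTIR in 257/751 elements; of those, 33% with a 5' IR and 1/257 with a
#' 5' microsatellite).
#'
#' @param length_mean,length_sd Element length distribution (bp).
#' @param min_length Hard lower bound on element length (bp).
#' @param hairpin_span Range of the palindromic span (bp); even spans used.
#' @param hairpin_gap Range of the gap between hairpin end and terminal
#'   `CTAG` (bp).
#' @param p_at_site Probability an element inserts between the A and T of a
#'   host `AT` dinucleotide.
#' @param p_subtir,p_ir,p_microsat Substructure probabilities (`p_ir` and
#'   `p_microsat` are conditional on a subTIR being present).
#' @param subtir_len Range of planted subTIR lengths (bp).
#' @param family_tail Optional family tail (a string of hairpin + gap +
#'   `CTAG`, see [make_family_tail()]) shared by family members.
#' @param family_tail_mut Maximum substitutions applied to the family tail's
#'   gap region per member.
#' @return An object of class `element_spec`.
#' @export
element_spec <- function(length_mean = 1092, length_sd = 558,
                         min_length = 200,
                         hairpin_span = c(16L, 20L),
                         hairpin_gap = c(5L, 10L),
                         p_at_site = 0.86,
                         p_subtir = 257 / 751, p_ir = 0.33,
                         p_microsat = 1 / 257,
                         subtir_len = c(10L, 14L),
                         family_tail = NULL, family_tail_mut = 2L) {
  stopifnot(p_at_site >= 0, p_at_site <= 1,
            p_subtir >= 0, p_subtir <= 1, p_ir >= 0, p_ir <= 1,
            p_microsat >= 0, p_microsat <= 1)
  if (hairpin_span[1] > hairpin_span[2] || hairpin_gap[1] > hairpin_gap[2] ||
      subtir_len[1] > subtir_len[2]) {
    stop("inconsistent range (min > max) in element spec")
  }
  if (hairpin_span[1] < 16 || hairpin_span[2] > 20) {
    stop("hairpin_span must lie within [16, 20]")
  }
  if (min_length < 200) stop("min_length must be >= 200")
  structure(list(length_mean = length_mean, length_sd = length_sd,
                 min_length = min_length, hairpin_span = hairpin_span,
                 hairpin_gap = hairpin_gap, p_at_site = p_at_site,
                 p_subtir = p_subtir, p_ir = p_ir, p_microsat = p_microsat,
                 subtir_len = subtir_len, family_tail = family_tail,
                 family_tail_mut = family_tail_mut),
            class = "element_spec")
}

# Random DNA with no "TC" dinucleotide and no "CTAG" motif (iterative
# in-place resampling; vectorized, so long interiors stay unbiased).
random_dna_tc_free <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(p), n, replace = TRUE, prob = p)
  repeat {
    bad <- which(x[-n] == "T" & x[-1] == "C") + 1L
    if (length(bad)) {
      x[bad] <- sample(c("A", "G", "T"), length(bad), replace = TRUE)
      next
    }
    s <- paste(x, collapse = "")
    m <- gregexpr("CTAG", s, fixed = TRUE)[[1]]
    if (m[1L] == -1L) break
    # resample the A of each CTAG to G/T (cannot create a new TC)
    x[as.integer(m) + 2L] <- sample(c("G", "T"), length(m), replace = TRUE)
  }
  paste(x, collapse = "")
}

# Random DNA free of both "TC" and "GA" (needed where the reverse complement
# must also stay TC-free).
random_dna_tc_ga_free <- function(n) {
  repeat {
    s <- random_dna_tc_free(n)
    if (!grepl("GA", s, fixed = TRUE)) return(s)
  }
}

# A random perfect palindrome (self-reverse-complementary string) of even
# span, free of the CTAG motif.
random_palindrome <- function(span) {
  stopifnot(span %% 2 == 0)
  repeat {
    half <- random_dna(span / 2, gc = 0.5)
    pal <- paste0(half, revcomp(half))
    if (!grepl("CTAG", pal, fixed = TRUE)) return(pal)
  }
}

# A microsatellite unit whose repetition contains no TC.
random_microsat_unit <- function(unit_range = c(2L, 4L)) {
  repeat {
    u <- random_dna(sample(unit_range[1]:unit_range[2], 1L))
    if (!grepl("TC", strrep(u, 3L), fixed = TRUE) &&
        length(unique(strsplit(u, "")[[1]])) > 1L) {
      return(u)
    }
  }
}

#' Build a family tail shared by related elements
#'
#' Returns a 34-bp string `hairpin(20) + gap(10) + CTAG` that
#' [make_element()] grafts onto each family member (mutating only the gap
#' region), so that members share a near-identical terminal 30 bp.
#'
#' @param seed Optional RNG seed.
#' @return Character scalar of length 34.
#' @export
make_family_tail <- function(seed = NULL) {
  with_seed(seed, {
    paste0(random_palindrome(20L), random_dna_tc_free(10L), "CTAG")
  })
}

# Structural "skeleton" of one element: length, substructure flags and
# hairpin geometry, drawn exactly once per element so that realization
# retries cannot bias the planted rates or the length distribution.
draw_element_skeleton <- function(spec) {
  len <- 0L
  repeat {
    len <- as.integer(round(rnorm(1L, spec$length_mean, spec$length_sd)))
    hi <- 2 * spec$length_mean - spec$min_length
    if (len >= spec$min_length && len <= hi) break
  }
  has_subtir <- runif(1L) < spec$p_subtir
  has_ir <- has_subtir && runif(1L) < spec$p_ir
  has_microsat <- has_subtir && runif(1L) < spec$p_microsat
  if (is.null(spec$family_tail)) {
    spans <- spec$hairpin_span[1]:spec$hairpin_span[2]
    span <- sample(spans[spans %% 2L == 0L], 1L)
    gap <- sample(spec$hairpin_gap[1]:spec$hairpin_gap[2], 1L)
  } else {
    span <- 20L
    gap <- 10L
  }
  stl <- if (has_subtir) sample(spec$subtir_len[1]:spec$subtir_len[2], 1L)
         else NA_integer_
  list(len = len, has_subtir = has_subtir, has_ir = has_ir,
       has_microsat = has_microsat, span = span, gap = gap, stl = stl)
}

# Realize the sequence for a fixed skeleton; NULL when a junction constraint
# is violated (caller retries the realization, never the skeleton).
build_element_once <- function(spec, sk) {
  len <- sk$len
  if (is.null(spec$family_tail)) {
    tail_seq <- paste0(random_palindrome(sk$span),
                       random_dna_tc_free(sk$gap), "CTAG")
  } else {
    tail_seq <- spec$family_tail
    nmut <- sample(0:spec$family_tail_mut, 1L)
    if (nmut > 0) {
      gpos <- sample(21:30, nmut)  # gap region only; hairpin + CTAG intact
      ch <- strsplit(tail_seq, "")[[1]]
      for (g in gpos) {
        ch[g] <- sample(setdiff(c("A", "G", "T"), ch[g]), 1L)
      }
      tail_seq <- paste(ch, collapse = "")
      if (grepl("TC", tail_seq, fixed = TRUE)) return(NULL)
    }
  }
  tail_len <- nchar(tail_seq)

  # 5' block: TC + optional microsatellite / subTIR 5' copy / IR, then filler.
  s5_seq <- if (sk$has_subtir) random_dna_tc_ga_free(sk$stl) else ""
  parts <- c("TC")
  if (sk$has_microsat) {
    u <- random_microsat_unit()
    parts <- c(parts, strrep(u, max(4L, ceiling(12 / nchar(u)))))
  }
  s5_rel <- NA_integer_
  if (sk$has_subtir) {
    parts <- c(parts, random_dna_tc_free(2L))
    s5_rel <- sum(nchar(parts))       # 0-based offset of s5 within element
    parts <- c(parts, s5_seq)
  }
  ir_rel <- NA_integer_
  if (sk$has_ir) {
    parts <- c(parts, random_dna_tc_free(2L))
    ir_rel <- sum(nchar(parts))
    parts <- c(parts, revcomp(s5_seq))
  }
  head_seq <- paste(parts, collapse = "")
  if (nchar(head_seq) > 50L) return(NULL)

  # 3' block: subTIR 3' copy (revcomp of the 5' copy) just before the tail,
  # kept inside the last 50 bp.
  pre_tail <- if (sk$has_subtir) revcomp(s5_seq) else ""
  if (sk$has_subtir && nchar(pre_tail) + tail_len > 50L) return(NULL)

  interior_len <- len - nchar(head_seq) - nchar(pre_tail) - tail_len
  if (interior_len < 10L) return(NULL)
  elem <- paste0(head_seq, random_dna_tc_free(interior_len), pre_tail,
                 tail_seq)
  stopifnot(nchar(elem) == len)
  span <- sk$span
  gap <- sk$gap
  has_subtir <- sk$has_subtir
  has_ir <- sk$has_ir
  has_microsat <- sk$has_microsat
  stl <- sk$stl

  # Structural validity: unique terminal CTAG in the last 40 bp, no decoy TC
  # start within [2, len - 200] (1-based starts; decoys there would present
  # an alternative 5' terminus at a compatible element length).
  zone_hi <- len - 200L
  if (zone_hi >= 2L) {
    zone <- substr(elem, 2L, zone_hi + 1L)
    if (grepl("TC", zone, fixed = TRUE)) return(NULL)
  }
  body_no_tail <- substr(elem, 1L, len - 4L)
  if (grepl("CTAG", body_no_tail, fixed = TRUE)) return(NULL)

  hp_end_rel <- len - 4L - gap        # 0-based half-open, element-relative
  hp_start_rel <- hp_end_rel - span
  truth <- list(length = len, span = span, gap = gap,
                hairpin_start = hp_start_rel, hairpin_end = hp_end_rel,
                has_subtir = has_subtir, has_ir = has_ir,
                has_microsat = has_microsat,
                subtir_len = stl,
                subtir5_rel = s5_rel, ir_rel = ir_rel,
                family = !is.null(spec$family_tail))
  list(seq = elem, truth = truth)
}

#' Generate one synthetic Helitron-like element
#'
#' The emitted sequence starts `TC`, ends `CTAG`, and carries a perfectly
#' self-complementary hairpin span ending within the configured gap upstream
#' of the terminal `CTAG`. Requested Helentron substructures (subTIR, 5' IR
#' complementary to the subTIR, 5' microsatellite) are planted; unrequested
#' ones are verified absent under the package's own finders, so truth labels
#' are exact. Element interiors (further than 200 bp from the 3' terminus)
#' contain no decoy `TC` start and no internal `CTAG`, making the true
#' terminus pair uniquely identifiable by the structural scan.
#'
#' @param spec An [element_spec()].
#' @param seed Optional RNG seed.
#' @param with_subtir,with_ir,with_microsat Optional logical overrides for
#'   the substructure draws.
#' @return `list(seq, truth)`; `truth` holds length, hairpin coordinates
#'   (element-relative, 0-based half-open) and substructure flags.
#' @export
make_element <- function(spec = element_spec(), seed = NULL,
                         with_subtir = NULL, with_ir = NULL,
                         with_microsat = NULL) {
  stopifnot(inherits(spec, "element_spec"))
  sp <- spec
  if (!is.null(with_subtir)) sp$p_subtir <- as.numeric(with_subtir)
  if (!is.null(with_ir)) sp$p_ir <- as.numeric(with_ir)
  if (!is.null(with_microsat)) sp$p_microsat <- as.numeric(with_microsat)
  with_seed(seed, {
    sk <- draw_element_skeleton(sp)
    for (attempt in 1:500) {
      el <- build_element_once(sp, sk)
      if (is.null(el)) next
      if (element_truth_ok(el)) return(el)
    }
    stop("could not build a structurally valid element in 500 attempts")
  })
}

# Verify that the element's substructure truth labels are exact under the
# package's own finders (absence really means absence).
element_truth_ok <- function(el) {
  tr <- el$truth
  st <- find_subtir(el$seq, terminal_window = 50L, min_len = 10L,
                    max_mismatch = 1L)
  if (!tr$has_subtir) {
    if (!is.null(st)) return(FALSE)
  } else {
    # the found subTIR must be the planted copy, possibly extended by the
    # mismatch allowance (the longest-pair rule absorbs flanking columns)
    if (is.null(st) ||
        st$pos5 > tr$subtir5_rel ||
        st$pos5 + st$length < tr$subtir5_rel + tr$subtir_len ||
        st$length > tr$subtir_len + 4L) {
      return(FALSE)
    }
    ir <- find_5prime_ir(el$seq, st, terminal_window = 50L, max_mismatch = 1L)
    if (tr$has_ir && is.null(ir)) return(FALSE)
    if (!tr$has_ir && !is.null(ir)) return(FALSE)
  }
  ms <- find_microsat(el$seq, window = 50L)
  if (!tr$has_microsat && !is.null(ms)) return(FALSE)
  if (tr$has_microsat && is.null(ms)) return(FALSE)
  TRUE
}

#' Plant elements into a host sequence
#'
#' With probability `p_at_site` an element is inserted between the A and T
#' of a host `AT` dinucleotide (so the element is flanked by `A...T` on its
#' own strand, on either strand of insertion); otherwise at a uniformly
#' chosen non-AT junction. Planted intervals never overlap and truth
#' coordinates refer to the modified sequence.
#'
#' @param host A single named or unnamed DNA string (character scalar).
#' @param n Number of elements to plant.
#' @param spec An [element_spec()].
#' @param seed Optional RNG seed.
#' @param p_minus Probability an element is inserted in reverse orientation.
#' @param seq_id Sequence id recorded in the truth table.
#' @return `list(seq, truth)` where `truth` is a data frame with one row per
#'   planted element (`seq_id, start, end, strand, at_site, length`,
#'   substructure flags, `family`).
#' @export
plant_elements <- function(host, n, spec = element_spec(), seed = NULL,
                           p_minus = 0.5, seq_id = "chr") {
  stopifnot(is.character(host), length(host) == 1L, n >= 0)
  if (n == 0L) {
    return(list(seq = host, truth = empty_element_truth()))
  }
  with_seed(seed, {
    hostc <- strsplit(host, "")[[1]]
    L <- length(hostc)
    at_pos <- which(hostc[-L] == "A" & hostc[-1] == "T")  # cut after A
    non_at <- setdiff(seq_len(L - 1L), at_pos)
    at_flag <- runif(n) < spec$p_at_site
    if (sum(at_flag) > length(at_pos) || sum(!at_flag) > length(non_at)) {
      stop("host too short / lacks AT sites for requested insertions")
    }
    cuts <- integer(n)
    used <- integer(0)
    for (i in seq_len(n)) {
      pool <- if (at_flag[i]) at_pos else non_at
      ok <- FALSE
      for (try in 1:1000) {
        cand <- pool[sample.int(length(pool), 1L)]
        if (!length(used) || min(abs(used - cand)) > 2L) {
          cuts[i] <- cand
          used <- c(used, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot place ", n, " non-overlapping insertions")
    }
    o <- order(cuts)
    cuts <- cuts[o]
    at_flag <- at_flag[o]
    strands <- ifelse(runif(n) < p_minus, "-", "+")
    elems <- vector("list", n)
    for (i in seq_len(n)) elems[[i]] <- make_element(spec)
    lens <- vapply(elems, function(e) e$truth$length, integer(1))
    ins <- vapply(seq_len(n), function(i) {
      s <- elems[[i]]$seq
      if (strands[i] == "-") revcomp(s) else s
    }, character(1))

    pieces <- character(2L * n + 1L)
    prev <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- substr(host, prev + 1L, cuts[i])
      pieces[2L * i] <- ins[i]
      prev <- cuts[i]
    }
    pieces[2L * n + 1L] <- substr(host, prev + 1L, L)
    newseq <- paste(pieces, collapse = "")

    offset <- cumsum(c(0L, lens[-n]))
    start <- cuts + offset            # 0-based: cut after host index `cuts`
    truth <- data.frame(
      seq_id = seq_id, start = start, end = start + lens, strand = strands,
      at_site = at_flag, length = lens,
      has_subtir = vapply(elems, function(e) e$truth$has_subtir, logical(1)),
      has_ir = vapply(elems, function(e) e$truth$has_ir, logical(1)),
      has_microsat = vapply(elems, function(e) e$truth$has_microsat,
                            logical(1)),
      family = vapply(elems, function(e) e$truth$family, logical(1)),
      stringsAsFactors = FALSE)
    list(seq = newseq, truth = truth)
  })
}

empty_element_truth <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), at_site = logical(0), length = integer(0),
             has_subtir = logical(0), has_ir = logical(0),
             has_microsat = logical(0), family = logical(0),
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic assembly
#'
#' @param n_chrom Number of chromosome-scale contigs.
#' @param chrom_len Length of each chromosome (bp; scalar or vector).
#' @param gc Baseline GC fraction (the oyster genome sits near 0.33; the
#'   neutral default here is 0.4 with mild along-chromosome variation).
#' @param gc_amplitude Amplitude of the smooth along-chromosome GC profile.
#' @param elements_per_chrom Planted Helitron-like elements per chromosome.
#' @param element_spec An [element_spec()].
#' @param genes_per_chrom,repeats_per_chrom Feature counts per chromosome
#'   (repeats split evenly across repeat classes).
#' @param n_haplotigs Number of haplotig duplicates to emit.
#' @param haplotig_frac Fraction of the source chromosome each haplotig
#'   copies.
#' @param haplotig_div Per-base divergence of haplotigs from their source.
#' @param n_junk,junk_len Number and length of junk scaffolds (low-accuracy
#'   sequence later given aberrant coverage by [simulate_depth()]).
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(n_chrom = 3L, chrom_len = 100000L, gc = 0.4,
                            gc_amplitude = 0.08, elements_per_chrom = 0L,
                            element_spec = oystr::element_spec(),
                            genes_per_chrom = 0L, repeats_per_chrom = 0L,
                            n_haplotigs = 0L, haplotig_frac = 0.4,
                            haplotig_div = 0.03, n_junk = 0L,
                            junk_len = 20000L) {
  chrom_len <- rep_len(chrom_len, n_chrom)
  stopifnot(gc > 0, gc < 1, haplotig_frac > 0, haplotig_frac <= 1,
            haplotig_div >= 0, haplotig_div < 1)
  structure(as.list(environment()), class = "assembly_config")
}

# Smoothly GC-varying host sequence.
host_sequence <- function(len, gc, amplitude, phase = 0) {
  block <- 1000L
  nb <- ceiling(len / block)
  gcs <- gc + amplitude * sin(2 * pi * (seq_len(nb) / nb) * 3 + phase)
  gcs <- pmin(pmax(gcs, 0.05), 0.95)
  pieces <- vapply(seq_len(nb), function(i) {
    n <- if (i < nb) block else len - block * (nb - 1L)
    random_dna(n, gcs[i])
  }, character(1))
  paste(pieces, collapse = "")
}

# Substitute bases at the given per-base rate (never to the same base).
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  k <- rbinom(1L, n, rate)
  if (k > 0) {
    pos <- sample.int(n, k)
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate an assembly with planted ground truth
#'
#' Chromosomal contigs receive planted elements and annotation features;
#' haplotig duplicates are subsequences of their source contig mutated at
#' the configured divergence; junk scaffolds are unrelated random sequence.
#' Identical seeds give byte-identical output.
#'
#' @param config An [assembly_config()].
#' @param seed Optional RNG seed.
#' @return `list(assembly, truth)`; `assembly` is a named character vector,
#'   `truth` a list with `elements`, `features`, `haplotigs`, `chromosomes`,
#'   `junk` components.
#' @export
simulate_assembly <- function(config = assembly_config(), seed = NULL) {
  stopifnot(inherits(config, "assembly_config"))
  with_seed(seed, {
    chrom_ids <- sprintf("chr%02d", seq_len(config$n_chrom))
    assembly <- character(0)
    elements <- empty_element_truth()
    feats <- list()
    rep_classes <- c("DNA_transposon", "LTR", "LINE", "satellite",
                     "simple_repeat")
    for (i in seq_len(config$n_chrom)) {
      host <- host_sequence(config$chrom_len[i], config$gc,
                            config$gc_amplitude, phase = i)
      pl <- plant_elements(host, config$elements_per_chrom,
                           config$element_spec, seq_id = chrom_ids[i])
      assembly[chrom_ids[i]] <- pl$seq
      elements <- rbind(elements, pl$truth)
      L <- nchar(pl$seq)
      n_gene <- config$genes_per_chrom
      n_rep <- config$repeats_per_chrom
      if (n_gene + n_rep > 0) {
        n <- n_gene + n_rep
        w <- pmin(pmax(round(rnorm(n, 2000, 800)), 300L), 8000L)
        st <- vapply(w, function(wi) sample.int(L - wi, 1L) - 1L, integer(1))
        kl <- c(rep("gene", n_gene),
                sample(rep_classes, n_rep, replace = TRUE))
        feats[[chrom_ids[i]]] <- feature_table(chrom_ids[i], st, st + w,
                                               ".", kl)
      }
    }
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(seq_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 klass = character(0), stringsAsFactors = FALSE)
    haplotigs <- data.frame(haplotig_id = character(0), source = character(0),
                            start = integer(0), end = integer(0),
                            divergence = numeric(0), stringsAsFactors = FALSE)
    if (config$n_haplotigs > 0) {
      for (j in seq_len(config$n_haplotigs)) {
        src <- chrom_ids[((j - 1L) %% config$n_chrom) + 1L]
        L <- nchar(assembly[[src]])
        hlen <- round(config$haplotig_frac * L)
        st <- sample.int(L - hlen, 1L) - 1L
        hid <- sprintf("htig%02d", j)
        hseq <- mutate_sequence(substr(assembly[[src]], st + 1L, st + hlen),
                                config$haplotig_div)
        assembly[hid] <- hseq
        haplotigs <- rbind(haplotigs, data.frame(
          haplotig_id = hid, source = src, start = st, end = st + hlen,
          divergence = config$haplotig_div, stringsAsFactors = FALSE))
      }
    }
    junk_ids <- character(0)
    if (config$n_junk > 0) {
      junk_ids <- sprintf("junk%02d", seq_len(config$n_junk))
      for (id in junk_ids) {
        # junk shares the chromosomal GC profile so that GC normalization
        # is estimated from bins where ordinary sequence dominates
        assembly[id] <- host_sequence(config$junk_len, config$gc,
                                      config$gc_amplitude,
                                      phase = runif(1, 0, 2 * pi))
      }
    }
    rownames(elements) <- NULL
    list(assembly = assembly,
         truth = list(elements = elements, features = features,
                      haplotigs = haplotigs, chromosomes = chrom_ids,
                      junk = junk_ids))
  })
}

#' Simulate a short-read depth track
#'
#' Per-base depths are Poisson around a GC-dependent mean (linear bias in
#' 1-kb window GC). Scaffolds listed in `junk_ids` receive depth scaled by
#' `junk_factor`, emulating low-accuracy sequence whose coverage sits far
#' from the assembly mean.
#'
#' @param assembly Named character vector of sequences.
#' @param mean_depth Target mean depth.
#' @param gc_bias_slope Linear GC bias: window mean is
#'   `mean_depth * (1 + slope * (gc - 0.5))`.
#' @param junk_ids Scaffolds to give aberrant coverage.
#' @param junk_factor Depth multiplier for junk scaffolds.
#' @param seed Optional RNG seed.
#' @param gc_window Window used to compute local GC (bp).
#' @return Depth-run `data.frame` (`seq_id, start, end, depth`).
#' @export
simulate_depth <- function(assembly, mean_depth = 30, gc_bias_slope = 0,
                           junk_ids = character(0), junk_factor = 0.1,
                           seed = NULL, gc_window = 1000L) {
  stopifnot(mean_depth > 0)
  with_seed(seed, {
    out <- vector("list", length(assembly))
    for (i in seq_along(assembly)) {
      id <- names(assembly)[i]
      L <- nchar(assembly[[i]])
      nb <- ceiling(L / gc_window)
      st <- (seq_len(nb) - 1L) * gc_window
      en <- pmin(st + gc_window, L)
      gcw <- gc_fraction(substring(assembly[[i]], st + 1L, en))
      gcw[is.na(gcw)] <- 0.5
      mu <- mean_depth * (1 + gc_bias_slope * (gcw - 0.5))
      mu <- pmax(mu, 0.01)
      if (id %in% junk_ids) mu <- mu * junk_factor
      depth <- rpois(L, rep(mu, times = en - st))
      out[[i]] <- depth_runs(id, depth)
    }
    do.call(rbind, out)
  })
}

#' Simulate whole-genome shotgun reads
#'
#' Reads are drawn uniformly from all haplotypes with per-base substitution
#' errors at `err_rate`. `depth` is the combined sequencing depth over the
#' locus (summed across haplotypes), so a diploid pair at `depth = 60` gives
#' each haplotype ~30x.
#'
#' @param genome Character vector of haplotype sequences (length 1 for a
#'   haploid genome, 2 for a diploid pair).
#' @param read_len Read length (bp).
#' @param depth Combined depth.
#' @param err_rate Per-base substitution error rate.
#' @param seed Optional RNG seed.
#' @return Character vector of reads.
#' @export
simulate_reads <- function(genome, read_len = 150L, depth = 30,
                           err_rate = 0, seed = NULL) {
  stopifnot(all(nchar(genome) >= read_len), depth > 0)
  with_seed(seed, {
    L1 <- nchar(genome[[1]])
    n_total <- round(depth * L1 / read_len)
    n_hap <- length(genome)
    reads <- vector("list", n_hap)
    for (h in seq_len(n_hap)) {
      n <- round(n_total / n_hap)
      Lh <- nchar(genome[[h]])
      starts <- sample.int(Lh - read_len + 1L, n, replace = TRUE)
      reads[[h]] <- substring(genome[[h]], starts, starts + read_len - 1L)
    }
    reads <- unlist(reads, use.names = FALSE)
    if (err_rate > 0) {
      n_err <- rbinom(length(reads), read_len, err_rate)
      idx <- which(n_err > 0)
      for (i in idx) {
        ch <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(read_len, n_err[i])
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        reads[i] <- paste(ch, collapse = "")
      }
    }
    reads
  })
}

#' Split chromosomes into scaffolds (coordinate map only)
#'
#' Produces the scaffold layout used by [simulate_markers()]: each
#' chromosome is cut into `pieces` scaffolds at random breakpoints; each
#' scaffold may be flipped.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param pieces Scaffolds per chromosome.
#' @param flip_p Probability a scaffold is reverse-oriented.
#' @param seed Optional RNG seed.
#' @return `data.frame` with `scaffold_id, chrom, offset, length, strand`.
#' @export
split_chromosomes <- function(chrom_lengths, pieces = 3L, flip_p = 0.5,
                              seed = NULL) {
  stopifnot(!is.null(names(chrom_lengths)), pieces >= 1L)
  with_seed(seed, {
    out <- list()
    sc <- 0L
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      if (pieces == 1L) {
        bp <- integer(0)
      } else {
        bp <- sort(sample(seq(round(0.2 * L), round(0.8 * L)), pieces - 1L))
      }
      bounds <- c(0L, bp, L)
      for (i in seq_len(pieces)) {
        sc <- sc + 1L
        out[[sc]] <- data.frame(
          scaffold_id = sprintf("sc%03d", sc), chrom = ch,
          offset = bounds[i], length = bounds[i + 1L] - bounds[i],
          strand = if (runif(1) < flip_p) "-" else "+",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a linkage-map marker table with alignment records
#'
#' Marker linkage-group labels equal the true chromosome; genetic positions
#' are proportional to physical position plus Gaussian noise; alignment
#' records map markers into the scaffold coordinate system (strand-aware)
#' with configurable MAPQ values.
#'
#' @param scaffold_map Output of [split_chromosomes()].
#' @param markers_per_chrom Markers per chromosome.
#' @param cm_per_chrom Genetic length of each chromosome (cM).
#' @param cm_noise_sd Gaussian noise on cM positions.
#' @param p_low_mapq Fraction of markers given `low_mapq` instead of 60.
#' @param low_mapq The low MAPQ value (default 10, below the >16 filter).
#' @param seed Optional RNG seed.
#' @return Marker `data.frame` (`marker_id, lg, cm, seq_id, pos, mapq`).
#' @export
simulate_markers <- function(scaffold_map, markers_per_chrom = 30L,
                             cm_per_chrom = 60, cm_noise_sd = 0,
                             p_low_mapq = 0, low_mapq = 10L, seed = NULL) {
  stopifnot(markers_per_chrom >= 2L)
  with_seed(seed, {
    out <- list()
    m <- 0L
    for (ch in unique(scaffold_map$chrom)) {
      sm <- scaffold_map[scaffold_map$chrom == ch, , drop = FALSE]
      L <- sum(sm$length)
      pos <- sort(sample.int(L, markers_per_chrom)) - 1L  # 0-based chrom pos
      cm <- pos / L * cm_per_chrom + rnorm(markers_per_chrom, 0, cm_noise_sd)
      cm <- pmax(cm, 0)
      idx <- findInterval(pos, sm$offset)
      sc_pos <- ifelse(sm$strand[idx] == "+",
                       pos - sm$offset[idx],
                       sm$offset[idx] + sm$length[idx] - 1L - pos)
      mapq <- ifelse(runif(markers_per_chrom) < p_low_mapq, low_mapq, 60L)
      ids <- sprintf("m%05d", m + seq_len(markers_per_chrom))
      m <- m + markers_per_chrom
      out[[ch]] <- data.frame(
        marker_id = ids, lg = ch, cm = cm,
        seq_id = sm$scaffold_id[idx], pos = as.integer(sc_pos),
        mapq = as.integer(mapq), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
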