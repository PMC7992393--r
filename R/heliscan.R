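#' Find hairpin-capable inverted-repeat spans
#'
#' Reports every span of total length within `span_range` whose first
#' `stem` bases are the reverse complement of its last `stem` bases with at
#' most `max_mismatch` mispaired positions, `stem >= min_stem` and
#' `loop = span - 2 * stem >= 0`. For each `(start, span)` the maximal stem
#' is reported, and a hairpin strictly inside another hairpin of equal stem
#' is suppressed. Output is sorted by start. Coordinates 0-based half-open.
#'
#' @param seq DNA string.
#' @param span_range Total span range (bp).
#' @param min_stem Minimum stem length (bp).
#' @param max_mismatch Maximum mispaired stem positions.
#' @param max_loop Optional maximum loop length; `NULL` leaves the loop
#'   unconstrained, `0` demands a perfect self-reverse-complementary span.
#' @return `data.frame`: `start, end, stem, loop, mismatches`.
#' @export
find_hairpins <- function(seq, span_range = c(16L, 20L), min_stem = 6L,
                          max_mismatch = 1L, max_loop = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ml <- if (is.null(max_loop)) -1L else as.integer(max_loop)
  hp <- .hairpin_scan_cpp(seq, as.integer(span_range[1]),
                          as.integer(span_range[2]), as.integer(min_stem),
                          as.integer(max_mismatch), ml)
  if (nrow(hp) == 0L) return(hp)
  keep <- rep(TRUE, nrow(hp))
  for (st in unique(hp$stem)) {
    g <- which(hp$stem == st)
    if (length(g) < 2L) next
    for (i in g) {
      inside <- hp$start[g] <= hp$start[i] & hp$end[g] >= hp$end[i] &
        (hp$start[g] < hp$start[i] | hp$end[g] > hp$end[i])
      if (any(inside)) keep[i] <- FALSE
    }
  }
  hp <- hp[keep, , drop = FALSE]
  hp <- hp[order(hp$start, hp$end), , drop = FALSE]
  rownames(hp) <- NULL
  hp
}

#' Find candidate 3' Helitron termini
#'
#' A candidate is a position `p` (0-based, exclusive end) with
#' `seq[p-4..p) == "CTAG"` and a hairpin ending within
#' `[p - 4 - gap_max, p - 4 - gap_min]`. Each candidate is reported with
#' its supporting hairpin (the one ending closest to the terminus; ties by
#' fewer mismatches, then longer stem).
#'
#' @param seq DNA string.
#' @param hairpin_gap Allowed gap range between hairpin end and the start
#'   of the terminal `CTAG` (bp).
#' @param hairpins Optional precomputed hairpin table (from
#'   [find_hairpins()]); computed with the remaining arguments otherwise.
#' @inheritParams find_hairpins
#' @return `data.frame`: `pos, hairpin_start, hairpin_end, stem, loop,
#'   mismatches`.
#' @export
find_3prime_candidates <- function(seq, hairpin_gap = c(2L, 30L),
                                   hairpins = NULL,
                                   span_range = c(16L, 20L), min_stem = 6L,
                                   max_mismatch = 1L, max_loop = NULL) {
  stopifnot(nchar(seq) >= 50L)
  if (is.null(hairpins)) {
    hairpins <- find_hairpins(seq, span_range, min_stem, max_mismatch,
                              max_loop)
  }
  empty <- data.frame(pos = integer(0), hairpin_start = integer(0),
                      hairpin_end = integer(0), stem = integer(0),
                      loop = integer(0), mismatches = integer(0))
  m <- gregexpr("CTAG", seq, fixed = TRUE)[[1]]
  if (m[1L] == -1L || nrow(hairpins) == 0L) return(empty)
  ctag_end <- as.integer(m) + 3L            # 0-based exclusive end of CTAG
  o <- order(hairpins$end, hairpins$mismatches, -hairpins$stem)
  hp <- hairpins[o, , drop = FALSE]
  ends <- hp$end
  rows <- lapply(ctag_end, function(p) {
    lo <- p - 4L - hairpin_gap[2L]
    hi <- p - 4L - hairpin_gap[1L]
    i1 <- findInterval(lo - 1L, ends) + 1L
    i2 <- findInterval(hi, ends)
    if (i2 < i1) return(NULL)
    g <- hp[i1:i2, , drop = FALSE]
    g <- g[order(-g$end, g$mismatches, -g$stem), , drop = FALSE]
    data.frame(pos = p, hairpin_start = g$start[1L],
               hairpin_end = g$end[1L], stem = g$stem[1L],
               loop = g$loop[1L], mismatches = g$mismatches[1L])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Find candidate 5' Helitron termini
#'
#' Positions `q` where `seq[q..q+2) == "TC"`, each with its 5' flanking
#' base (for AT target-site scoring; `NA` at position 0).
#'
#' @param seq DNA string.
#' @return `data.frame`: `pos, flank`.
#' @export
find_5prime_candidates <- function(seq) {
  m <- gregexpr("TC", seq, fixed = TRUE)[[1]]
  if (m[1L] == -1L) {
    return(data.frame(pos = integer(0), flank = character(0),
                      stringsAsFactors = FALSE))
  }
  q <- as.integer(m) - 1L                    # 0-based start of "TC"
  flank <- ifelse(q >= 1L, substring(seq, q, q), NA_character_)
  data.frame(pos = q, flank = flank, stringsAsFactors = FALSE)
}

#' Pair 5' and 3' termini into element candidates
#'
#' For each 3' candidate the nearest upstream 5' candidate giving an
#' element length within `[min_len, max_len]` is paired (one element per
#' 3' terminus). `at_site` is true when the base before the 5' `TC` is `A`
#' and the base after the terminal `CTAG` is `T`. Overlapping candidates
#' are resolved by keeping the one with fewer hairpin mismatches, then the
#' shorter, then the leftmost.
#'
#' @param five Output of [find_5prime_candidates()].
#' @param three Output of [find_3prime_candidates()].
#' @param seq The scanned sequence (for target-site flanks).
#' @param min_len,max_len Element length bounds (bp), bracketing the
#'   ~1.1 kb typical intact element.
#' @return `data.frame`: `start, end, length, at_site, hp_rel_start,
#'   hp_rel_end, stem, loop, mismatches` (hairpin coordinates relative to
#'   the element start on the scanned strand).
#' @export
pair_termini <- function(five, three, seq, min_len = 200L, max_len = 20000L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), at_site = logical(0),
                      hp_rel_start = integer(0), hp_rel_end = integer(0),
                      stem = integer(0), loop = integer(0),
                      mismatches = integer(0))
  if (nrow(five) == 0L || nrow(three) == 0L) return(empty)
  qpos <- sort(five$pos)
  L <- nchar(seq)
  rows <- lapply(seq_len(nrow(three)), function(i) {
    p <- three$pos[i]
    idx <- findInterval(p - min_len, qpos)
    if (idx < 1L) return(NULL)
    q <- qpos[idx]
    if (p - q > max_len) return(NULL)
    at <- q >= 1L && substring(seq, q, q) == "A" &&
      p < L && substring(seq, p + 1L, p + 1L) == "T"
    data.frame(start = q, end = p, length = p - q, at_site = at,
               hp_rel_start = three$hairpin_start[i] - q,
               hp_rel_end = three$hairpin_end[i] - q,
               stem = three$stem[i], loop = three$loop[i],
               mismatches = three$mismatches[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  # overlap resolution: fewer mismatches, then shorter, then leftmost
  o <- order(cand$mismatches, cand$length, cand$start)
  cand <- cand[o, , drop = FALSE]
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!length(acc_start) ||
        !any(cand$start[i] < acc_end & cand$end[i] > acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, cand$start[i])
      acc_end <- c(acc_end, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Default structural-scan parameters
#'
#' The genome-scale scan demands a mismatch-free, fully self-complementary
#' hairpin span (loop 0, stem >= 8) ending 2-12 bp upstream of the terminal
#' `CTAG`. These defaults hold the expected false-element rate on random
#' DNA below ~5 per Mb (see the methods vignette for the derivation); the
#' per-operation defaults of [find_hairpins()] are deliberately more
#' permissive.
#'
#' @param min_len,max_len Element length bounds (bp).
#' @param span_range Hairpin span range (bp).
#' @param min_stem Minimum hairpin stem (bp).
#' @param max_mismatch Maximum mispaired stem positions.
#' @param max_loop Maximum hairpin loop (bp).
#' @param hairpin_gap Hairpin-to-CTAG gap range (bp).
#' @return Named list of parameters for [scan_genome()].
#' @export
scan_params <- function(min_len = 200L, max_len = 20000L,
                        span_range = c(16L, 20L), min_stem = 8L,
                        max_mismatch = 0L, max_loop = 0L,
                        hairpin_gap = c(2L, 12L)) {
  as.list(environment())
}

#' Structure-based Helitron scan over an assembly
#'
#' Both strands of every sequence are scanned (the reverse strand via the
#' reverse complement, with coordinates mapped back to the forward strand).
#' Output is sorted by `(seq_id, start)` and deterministic; scanning the
#' reverse-complemented genome yields exactly the mirror-image candidate
#' set.
#'
#' @param assembly Named character vector of sequences.
#' @param params Parameters from [scan_params()].
#' @return `data.frame` of candidates: `seq_id, start, end` (forward
#'   0-based half-open), `strand, length, at_site, hp_rel_start,
#'   hp_rel_end, stem, loop, mismatches` (hairpin coordinates relative to
#'   the element start on the element's own strand).
#' @export
scan_genome <- function(assembly, params = scan_params()) {
  out <- list()
  for (id in names(assembly)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") assembly[[id]] else revcomp(assembly[[id]])
      if (nchar(s) < 50L) next
      hp <- find_hairpins(s, params$span_range, params$min_stem,
                          params$max_mismatch, params$max_loop)
      three <- find_3prime_candidates(s, params$hairpin_gap, hairpins = hp)
      five <- find_5prime_candidates(s)
      cand <- pair_termini(five, three, s, params$min_len, params$max_len)
      if (nrow(cand) == 0L) next
      L <- nchar(s)
      if (strand == "-") {
        fstart <- L - cand$end
        fend <- L - cand$start
        cand$start <- fstart
        cand$end <- fend
      }
      cand <- cbind(data.frame(seq_id = id, stringsAsFactors = FALSE),
                    cand, data.frame(strand = strand,
                                     stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      at_site = logical(0), hp_rel_start = integer(0),
                      hp_rel_end = integer(0), stem = integer(0),
                      loop = integer(0), mismatches = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, res$end, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract candidate element sequences on their own strand
#'
#' @param assembly Named character vector of sequences.
#' @param candidates Candidate table from [scan_genome()].
#' @return Character vector of element sequences (each starts `TC` and
#'   ends `CTAG` on its own strand).
#' @export
element_seq <- function(assembly, candidates) {
  vapply(seq_len(nrow(candidates)), function(i) {
    s <- substr(assembly[[candidates$seq_id[i]]],
                candidates$start[i] + 1L, candidates$end[i])
    if (candidates$strand[i] == "-") revcomp(s) else s
  }, character(1))
}
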