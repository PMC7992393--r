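#' Find the sub-terminal inverted repeat (subTIR) of an element
#'
#' Searches for the longest pair of substrings — one within the first
#' `terminal_window` bp, one within the last `terminal_window` bp — such
#' that the 3' copy equals the reverse complement of the 5' copy up to
#' `max_mismatch` mismatches and the length reaches `min_len`. Ties are
#' broken by proximity to the termini.
#'
#' @param elem Element sequence (on its own strand).
#' @param terminal_window Terminal window searched at each end (bp).
#' @param min_len Minimum subTIR length (bp).
#' @param max_mismatch Maximum mismatches between the paired copies.
#' @return `list(pos5, pos3, length, mismatches)` (0-based element-relative
#'   starts) or `NULL` when absent.
#' @export
find_subtir <- function(elem, terminal_window = 50L, min_len = 10L,
                        max_mismatch = 1L) {
  L <- nchar(elem)
  if (L < 2L * terminal_window) {
    stop("element shorter than twice the terminal window")
  }
  w5 <- substr(elem, 1L, terminal_window)
  w3 <- substr(elem, L - terminal_window + 1L, L)
  hit <- .subtir_scan_cpp(w5, w3, as.integer(min_len),
                          as.integer(max_mismatch))
  if (!length(hit)) return(NULL)
  list(pos5 = hit[1L], pos3 = L - terminal_window + hit[2L],
       length = hit[3L], mismatches = hit[4L])
}

# Positions (0-based) in `window_seq` where `pattern` matches with at most
# max_mismatch mismatches.
approx_match_positions <- function(window_seq, pattern, max_mismatch) {
  n <- nchar(window_seq)
  m <- nchar(pattern)
  if (m > n) return(integer(0))
  starts <- 0:(n - m)
  hits <- vapply(starts, function(i) {
    hamming(substr(window_seq, i + 1L, i + m), pattern) <= max_mismatch
  }, logical(1))
  starts[hits]
}

#' Find a 5' inverted repeat complementary to the subTIR
#'
#' Looks in the first `terminal_window` bp for a match to the reverse
#' complement of the subTIR's 5' copy, allowing `max_mismatch` mismatches
#' and requiring no overlap with the subTIR's own 5' copy.
#'
#' @param elem Element sequence.
#' @param subtir Output of [find_subtir()]; an error if `NULL` (the IR is
#'   defined relative to the subTIR).
#' @inheritParams find_subtir
#' @return `list(pos, length)` or `NULL` when absent.
#' @export
find_5prime_ir <- function(elem, subtir, terminal_window = 50L,
                           max_mismatch = 1L) {
  if (is.null(subtir)) stop("find_5prime_ir requires a subTIR")
  w5 <- substr(elem, 1L, terminal_window)
  s5 <- substr(elem, subtir$pos5 + 1L, subtir$pos5 + subtir$length)
  target <- revcomp(s5)
  pos <- approx_match_positions(w5, target, max_mismatch)
  # non-overlap with the subTIR's 5' copy
  pos <- pos[pos + subtir$length <= subtir$pos5 |
               pos >= subtir$pos5 + subtir$length]
  if (!length(pos)) return(NULL)
  list(pos = pos[1L], length = subtir$length)
}

#' Find a 5'-terminal microsatellite
#'
#' The longest perfect tandem run within the first `window` bp with unit
#' length in `unit_range`, at least `min_copies` full copies and total span
#' of at least `min_span` bp. Homopolymer runs (unit length 1) also require
#' span `>= min_span`.
#'
#' @param elem Element sequence.
#' @param window 5' window searched (bp).
#' @param unit_range Repeat unit length range (bp).
#' @param min_copies Minimum number of full unit copies.
#' @param min_span Minimum total run span (bp).
#' @return `list(pos, unit, copies, span)` (0-based `pos`) or `NULL`.
#' @export
find_microsat <- function(elem, window = 50L, unit_range = c(1L, 6L),
                          min_copies = 3L, min_span = 9L) {
  w <- substr(elem, 1L, min(window, nchar(elem)))
  x <- strsplit(w, "")[[1]]
  n <- length(x)
  best <- NULL
  for (u in unit_range[1]:unit_range[2]) {
    if (n < u * 2L) next
    eq <- x[(u + 1L):n] == x[1:(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + u        # run of matches plus the first unit
      pos <- starts[j] - 1L           # 0-based start of the tandem run
      copies <- span %/% u
      unit <- substr(w, pos + 1L, pos + u)
      if (copies >= min_copies && span >= min_span &&
          length(unique(strsplit(unit, "")[[1]])) >= 1L) {
        if (is.null(best) || span > best$span ||
            (span == best$span && u < nchar(best$unit))) {
          best <- list(pos = pos, unit = unit, copies = copies, span = span)
        }
      }
    }
  }
  best
}

#' Classify an element from its substructure flags
#'
#' `helitron` when no subTIR is present; `helentron_like` when a subTIR
#' co-occurs with a 5' IR or a 5' microsatellite; `intermediate` when only
#' the subTIR is present. Total on all flag combinations.
#'
#' @param has_subtir,has_ir,has_microsat Logical flags (vectorized).
#' @return Character vector in
#'   `{helitron, intermediate, helentron_like}`.
#' @export
classify_element <- function(has_subtir, has_ir, has_microsat) {
  stopifnot(length(has_ir) == length(has_subtir),
            length(has_microsat) == length(has_subtir))
  ifelse(!has_subtir, "helitron",
         ifelse(has_ir | has_microsat, "helentron_like", "intermediate"))
}

#' Substructure screen and classification of scan candidates
#'
#' Runs [find_subtir()], [find_5prime_ir()] and [find_microsat()] on every
#' candidate and appends the substructure flags and class label.
#'
#' @param assembly Named character vector of sequences.
#' @param candidates Candidate table from [scan_genome()].
#' @param terminal_window,min_subtir,max_mismatch subTIR search parameters.
#' @return `candidates` with added columns `has_subtir, has_ir,
#'   has_microsat, subtir_len, klass`.
#' @export
classify_candidates <- function(assembly, candidates, terminal_window = 50L,
                                min_subtir = 10L, max_mismatch = 1L) {
  n <- nrow(candidates)
  has_subtir <- logical(n)
  has_ir <- logical(n)
  has_ms <- logical(n)
  stl <- rep(NA_integer_, n)
  if (n > 0) {
    seqs <- element_seq(assembly, candidates)
    for (i in seq_len(n)) {
      st <- find_subtir(seqs[i], terminal_window, min_subtir, max_mismatch)
      if (!is.null(st)) {
        has_subtir[i] <- TRUE
        stl[i] <- st$length
        ir <- find_5prime_ir(seqs[i], st, terminal_window, max_mismatch)
        has_ir[i] <- !is.null(ir)
      }
      has_ms[i] <- !is.null(find_microsat(seqs[i]))
    }
  }
  candidates$has_subtir <- has_subtir
  candidates$has_ir <- has_ir
  candidates$has_microsat <- has_ms
  candidates$subtir_len <- stl
  candidates$klass <- classify_element(has_subtir, has_ir, has_ms)
  candidates
}
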