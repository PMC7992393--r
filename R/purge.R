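#' Build a canonical minimizer index over a set of contigs
#'
#' For each contig the `(k, w)` canonical minimizers (hash, 0-based k-mer
#' start) are recorded. Minimizers whose k-mer overlaps a masked interval
#' are dropped, so matches inside repeat-masked regions are ignored by the
#' mapper. Deterministic for fixed `(k, w)`.
#'
#' @param contigs Named character vector of sequences.
#' @param k,w Minimizer k-mer size (`<= 15`) and window.
#' @param mask Optional feature `data.frame` of intervals to soft-mask.
#' @return Named list; per contig `list(hash, pos, length)`.
#' @export
build_minimizer_index <- function(contigs, k = 15L, w = 10L, mask = NULL) {
  stopifnot(is.character(contigs), length(contigs) > 0,
            !is.null(names(contigs)))
  idx <- vector("list", length(contigs))
  names(idx) <- names(contigs)
  for (id in names(contigs)) {
    mm <- .minimizers_cpp(contigs[[id]], k, w)
    hash <- mm$hash
    pos <- mm$pos
    if (!is.null(mask)) {
      mk <- mask[mask$seq_id == id, , drop = FALSE]
      if (nrow(mk)) {
        keep <- rep(TRUE, length(pos))
        for (i in seq_len(nrow(mk))) {
          keep <- keep & !(pos < mk$end[i] & (pos + k) > mk$start[i])
        }
        hash <- hash[keep]
        pos <- pos[keep]
      }
    }
    idx[[id]] <- list(hash = hash, pos = pos, length = nchar(contigs[[id]]))
  }
  attr(idx, "k") <- k
  attr(idx, "w") <- w
  idx
}

#' Map one contig against targets by shared minimizers
#'
#' The query is tiled into 500-bp windows; a window is covered by a target
#' when at least `min_hits` of its minimizers also occur in that target.
#' `query_covered_bp` is the total length of covered windows and
#' `query_covered_frac` is computed against the full query length.
#'
#' @param query_id Query contig id (must be present in `index`).
#' @param index A minimizer index from [build_minimizer_index()].
#' @param target_ids Target ids to map against (default: all others).
#' @param window Query tiling window (bp).
#' @param min_hits Minimum matching minimizers per covered window.
#' @return `data.frame` with one row per target:
#'   `query_id, target_id, query_covered_bp, query_covered_frac`.
#' @export
map_contig <- function(query_id, index, target_ids = NULL, window = 500L,
                       min_hits = 10L) {
  stopifnot(query_id %in% names(index))
  q <- index[[query_id]]
  if (is.null(target_ids)) target_ids <- setdiff(names(index), query_id)
  qlen <- q$length
  nwin <- max(1L, ceiling(qlen / window))
  win_len <- pmin(seq_len(nwin) * window, qlen) -
    (seq_len(nwin) - 1L) * window
  qwin <- q$pos %/% window + 1L
  out <- lapply(target_ids, function(tid) {
    t <- index[[tid]]
    hit <- q$hash %in% t$hash
    covered_bp <- 0L
    if (any(hit)) {
      cnt <- tabulate(qwin[hit], nbins = nwin)
      covered_bp <- sum(win_len[cnt >= min_hits])
    }
    data.frame(query_id = query_id, target_id = tid,
               query_covered_bp = covered_bp,
               query_covered_frac = covered_bp / qlen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Exact-alignment coverage backend: covered fraction of the query by the
# best local alignment against the target (oracle-grade, O(nm); intended
# for small contigs). Returns the covered fraction.
alignment_covered_frac <- function(query_seq, target_seq) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query_seq), Biostrings::DNAString(target_seq),
    type = "local", substitutionMatrix = sub,
    gapOpening = 4, gapExtension = 2)
  covered <- Biostrings::width(Biostrings::pattern(aln))
  covered / nchar(query_seq)
}

#' Iterative length-ordered haplotig purge
#'
#' Contigs are sorted by decreasing length (ties by id). The longest
#' unprocessed contig becomes the reference; every other unprocessed contig
#' is mapped against it, and any contig whose covered fraction reaches
#' `min_frac` and whose length exceeds `min_len` is removed as a haplotig.
#' The reference is then marked kept and both it and the removed contigs
#' leave the pool; the process repeats until the pool is empty. Contigs of
#' length `<= min_len` are never removed by this rule.
#'
#' @param contigs Named character vector of contig sequences.
#' @param mask Optional repeat feature `data.frame`; matches inside masked
#'   intervals are ignored by the internal mapper.
#' @param min_len Removed contigs must be strictly longer than this (bp).
#' @param min_frac Removal requires covered fraction `>=` this (inclusive).
#' @param k,w,window,min_hits Internal mapper parameters (see
#'   [build_minimizer_index()] and [map_contig()]).
#' @param coverage_fun Optional override: `function(query_id, target_id)`
#'   returning the query covered fraction. Used to plug an exact-alignment
#'   oracle in place of the approximate mapper.
#' @return A `purge_result`: `list(kept_ids, removed)` with `removed` a
#'   `data.frame` of `contig_id, reason, ref_id, covered_frac`.
#' @export
iterative_purge <- function(contigs, mask = NULL, min_len = 10000L,
                            min_frac = 0.30, k = 15L, w = 10L,
                            window = 500L, min_hits = 10L,
                            coverage_fun = NULL) {
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))
  lens <- nchar(contigs)
  ids <- names(contigs)[order(-lens, names(contigs))]
  if (is.null(coverage_fun)) {
    index <- build_minimizer_index(contigs, k = k, w = w, mask = mask)
    coverage_fun <- function(query_id, target_id) {
      map_contig(query_id, index, target_ids = target_id,
                 window = window, min_hits = min_hits)$query_covered_frac
    }
  }
  pool <- ids
  kept <- character(0)
  removed <- data.frame(contig_id = character(0), reason = character(0),
                        ref_id = character(0), covered_frac = numeric(0),
                        stringsAsFactors = FALSE)
  while (length(pool) > 0L) {
    ref <- pool[1L]
    others <- pool[-1L]
    drop <- character(0)
    for (q in others) {
      if (nchar(contigs[[q]]) <= min_len) next
      frac <- coverage_fun(q, ref)
      if (frac >= min_frac) {
        drop <- c(drop, q)
        removed <- rbind(removed, data.frame(
          contig_id = q, reason = "haplotig_map", ref_id = ref,
          covered_frac = frac, stringsAsFactors = FALSE))
      }
    }
    kept <- c(kept, ref)
    pool <- setdiff(pool, c(ref, drop))
  }
  structure(list(kept_ids = kept, removed = removed),
            class = "purge_result")
}

#' Intersect two independently curated keep-lists
#'
#' The common contigs are kept; contigs present in only one list are
#' reported removed with reason `external_only`.
#'
#' @param keep_a,keep_b Character vectors of contig ids to keep.
#' @param universe All contig ids under consideration.
#' @return A `purge_result` (`kept_ids`, `removed`).
#' @export
intersect_keep_lists <- function(keep_a, keep_b, universe) {
  extra <- setdiff(c(keep_a, keep_b), universe)
  if (length(extra)) {
    stop("keep-list ids not in universe: ", paste(extra, collapse = ", "))
  }
  kept <- intersect(keep_a, keep_b)
  if (!length(kept)) warning("keep-lists have empty intersection")
  gone <- setdiff(universe, kept)
  structure(list(
    kept_ids = kept,
    removed = data.frame(contig_id = gone,
                         reason = rep_len("external_only", length(gone)),
                         ref_id = rep_len(NA_character_, length(gone)),
                         covered_frac = rep_len(NA_real_, length(gone)),
                         stringsAsFactors = FALSE)),
    class = "purge_result")
}

#' @export
print.purge_result <- function(x, ...) {
  cat("purge result:", length(x$kept_ids), "kept,",
      nrow(x$removed), "removed\n")
  invisible(x)
}
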