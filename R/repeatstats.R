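#' Terminal 30 bp of an element
#'
#' The last 30 bases of the element on its own strand (including the
#' terminal `CTAG`), the unit compared in 3'-end family clustering.
#'
#' @param elem Element sequence(s) on their own strand (character vector).
#' @return Character vector of 30-bp suffixes.
#' @export
end30 <- function(elem) {
  if (any(nchar(elem) < 30L)) stop("element shorter than 30 bp")
  substring(elem, nchar(elem) - 29L, nchar(elem))
}

#' Pairwise identity of two 30-bp terminal sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1, linear
#' gap -2, end gaps penalized; identity is matching columns over total
#' alignment columns (the `iddef 1` convention).
#'
#' @param a,b Sequences of length 30.
#' @return Identity fraction in `[0, 1]`.
#' @export
pair_identity <- function(a, b) {
  stopifnot(nchar(a) == 30L, nchar(b) == 30L)
  pair_identity_many(a, b)[1L]
}

# Vectorized identity of many patterns against one subject.
pair_identity_many <- function(patterns, subject) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2)
  pat <- as.character(Biostrings::alignedPattern(aln))
  subj <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pat), function(i) {
    pc <- strsplit(pat[i], "")[[1]]
    sc <- strsplit(subj[i], "")[[1]]
    sum(pc == sc & pc != "-") / length(pc)
  }, numeric(1))
}

#' Greedy centroid clustering of 3'-end sequences
#'
#' Sequences are processed in order of decreasing abundance (count of
#' identical sequences), ties by first occurrence. Each sequence joins the
#' best existing centroid with identity at least `id_threshold`
#' (`>=`, matching the floor semantics of the usual `-id` flag), otherwise
#' it founds a new family with itself as centroid. Deterministic.
#'
#' @param seqs Character vector of 30-bp terminal sequences.
#' @param id_threshold Identity floor for joining a family.
#' @return `data.frame`: `seq_index, family_id, centroid, identity`;
#'   `seq_index` refers to positions in `seqs`.
#' @export
greedy_cluster <- function(seqs, id_threshold = 0.80) {
  stopifnot(all(nchar(seqs) == 30L))
  n <- length(seqs)
  if (n == 0L) {
    return(data.frame(seq_index = integer(0), family_id = integer(0),
                      centroid = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  first_idx <- match(unique(seqs), seqs)
  uniq <- seqs[first_idx]
  abund <- as.integer(table(factor(seqs, levels = uniq)))
  o <- order(-abund, first_idx)
  uniq <- uniq[o]
  centroids <- character(0)
  fam_of_uniq <- integer(length(uniq))
  id_of_uniq <- numeric(length(uniq))
  for (i in seq_along(uniq)) {
    if (length(centroids)) {
      ids <- pair_identity_many(centroids, uniq[i])
      best <- which.max(ids)
      if (ids[best] >= id_threshold) {
        fam_of_uniq[i] <- best
        id_of_uniq[i] <- ids[best]
        next
      }
    }
    centroids <- c(centroids, uniq[i])
    fam_of_uniq[i] <- length(centroids)
    id_of_uniq[i] <- 1
  }
  pos <- match(seqs, uniq)
  data.frame(seq_index = seq_len(n), family_id = fam_of_uniq[pos],
             centroid = centroids[fam_of_uniq[pos]],
             identity = id_of_uniq[pos], stringsAsFactors = FALSE)
}

#' Count conserved 3' ends
#'
#' By default, members of families of size at least 2 ("conserved" ends);
#' with `count_all = TRUE`, every element counts.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param count_all Count singleton families too.
#' @return Integer count.
#' @export
conserved_end_count <- function(clusters, count_all = FALSE) {
  if (count_all) return(nrow(clusters))
  sizes <- table(clusters$family_id)
  sum(clusters$family_id %in% as.integer(names(sizes)[sizes >= 2L]))
}

#' Screen elements for captured host gene fragments
#'
#' Each element is translated in all six frames; open segments (between
#' stop codons, so no alignment spans a stop) are locally aligned against
#' every protein with BLOSUM62 scoring and affine gaps. A match requires an
#' alignment longer than `min_aln_len` residues with identity at least
#' `min_identity`.
#'
#' @param elems Character vector of element sequences.
#' @param proteins Named character vector of protein sequences.
#' @param min_aln_len Strict lower bound on alignment columns (residues).
#' @param min_identity Identity floor (matching columns over alignment
#'   columns).
#' @return `data.frame`: `elem_index, protein, frame, aln_len, identity`.
#' @export
capture_screen <- function(elems, proteins, min_aln_len = 50L,
                           min_identity = 0.85) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  hits <- list()
  for (e in seq_along(elems)) {
    segs <- list()
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) elems[e] else revcomp(elems[e])
      for (f in 0:2) {
        cod_len <- ((nchar(s) - f) %/% 3L) * 3L
        if (cod_len < 3L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, f + 1L, f + cod_len)),
          if.fuzzy.codon = "X")))
        for (piece in strsplit(aa, "*", fixed = TRUE)[[1]]) {
          if (nchar(piece) > min_aln_len) {
            segs[[length(segs) + 1L]] <- list(aa = piece,
                                              frame = strand * (f + 1L))
          }
        }
      }
    }
    for (sg in segs) {
      for (p in names(proteins)) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(sg$aa), Biostrings::AAString(proteins[[p]]),
          type = "local", substitutionMatrix = get("BLOSUM62"),
          gapOpening = 11, gapExtension = 1)
        pat <- as.character(Biostrings::alignedPattern(aln))
        subj <- as.character(Biostrings::alignedSubject(aln))
        if (nchar(pat) <= min_aln_len) next
        pc <- strsplit(pat, "")[[1]]
        sc <- strsplit(subj, "")[[1]]
        # local alignments can over-extend past the homologous core; score
        # the best contiguous column window (HSP-style) against the rules
        best <- best_identity_window(pc == sc & pc != "-",
                                     min_aln_len, min_identity)
        if (!is.null(best)) {
          hits[[length(hits) + 1L]] <- data.frame(
            elem_index = e, protein = p, frame = sg$frame,
            aln_len = best$len, identity = best$identity,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(elem_index = integer(0), protein = character(0),
                      frame = integer(0), aln_len = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

# Longest contiguous window of alignment columns with length strictly above
# min_len and match fraction >= min_id; NULL if none qualifies.
best_identity_window <- function(match, min_len, min_id) {
  n <- length(match)
  if (n <= min_len) return(NULL)
  cum <- c(0L, cumsum(match))
  best <- NULL
  for (len in seq.int(n, min_len + 1L)) {
    starts <- seq_len(n - len + 1L)
    hits <- cum[starts + len] - cum[starts]
    ok <- which(hits / len >= min_id)
    if (length(ok)) {
      i <- ok[which.max(hits[ok])]
      best <- list(len = len, identity = hits[i] / len)
      break
    }
  }
  best
}

#' Count features in non-overlapping genomic windows
#'
#' Windows of `window` bp tile each chromosome. Every feature is counted
#' exactly once, in the window holding the largest share of its length;
#' exact ties go to the lower-coordinate window.
#'
#' @param features Feature `data.frame` (see [feature_table()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window size (bp; 100 kb is the usual density scale).
#' @return `data.frame` with `seq_id, start, end` and one count column per
#'   feature class present (plus `gene_count` mirroring the `gene` class).
#' @export
window_counts <- function(features, chrom_lengths, window = 100000L) {
  if (any(!features$seq_id %in% names(chrom_lengths))) {
    stop("feature on unknown chromosome")
  }
  if (any(features$end > chrom_lengths[features$seq_id])) {
    stop("feature outside chromosome bounds")
  }
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    nw <- max(1L, ceiling(L / window))
    st <- (seq_len(nw) - 1L) * window
    data.frame(seq_id = ch, start = st, end = pmin(st + window, L),
               stringsAsFactors = FALSE)
  }))
  assign_window <- function(seq_id, start, end) {
    w1 <- start %/% window
    w2 <- (end - 1L) %/% window
    if (w1 == w2) return(w1)
    spans <- w1:w2
    ov <- pmin(end, (spans + 1L) * window) - pmax(start, spans * window)
    spans[which.max(ov)]   # which.max takes the first (lower) on ties
  }
  widx <- vapply(seq_len(nrow(features)), function(i) {
    assign_window(features$seq_id[i], features$start[i], features$end[i])
  }, numeric(1))
  key <- paste(features$seq_id, widx)
  gkey <- paste(grid$seq_id, grid$start %/% window)
  classes <- sort(unique(features$klass))
  for (kl in classes) {
    cnt <- table(key[features$klass == kl])
    col <- integer(nrow(grid))
    m <- match(names(cnt), gkey)
    col[m] <- as.integer(cnt)
    grid[[paste0(kl, "_count")]] <- col
  }
  if (!"gene_count" %in% names(grid)) grid$gene_count <- 0L
  grid
}

#' Pearson density correlation with closed-form p-value
#'
#' Product-moment correlation of two window-count vectors; the two-sided
#' p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Zero variance yields `NA`, not 0.
#'
#' @param x,y Equal-length numeric vectors (`n >= 3`).
#' @param method `"pearson"` (default) or `"spearman"` (ranks first, then
#'   the same transform).
#' @return `list(r, p, n)`.
#' @export
density_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t_stat), df = n - 2), n = n)
}

#' Helitron density per megabase
#'
#' Number of conserved 3' ends divided by genome size in Mb.
#'
#' @param n_conserved_ends Count of conserved 3' ends.
#' @param genome_size_mb Genome size in Mb (`> 0`).
#' @return Density (ends per Mb).
#' @export
helitron_density <- function(n_conserved_ends, genome_size_mb) {
  assert_scalar_number(genome_size_mb, "genome_size_mb")
  if (genome_size_mb <= 0) stop("genome size must be positive")
  n_conserved_ends / genome_size_mb
}

#' Chromosomes enriched for element density
#'
#' A chromosome is enriched when its density strictly exceeds the mean plus
#' one population SD of the per-chromosome densities.
#'
#' @param densities Named numeric vector of per-chromosome densities
#'   (`length >= 2`).
#' @param sd_mult Enrichment threshold in SD units.
#' @return Character vector of enriched chromosome names.
#' @export
chromosome_enrichment <- function(densities, sd_mult = 1) {
  stopifnot(length(densities) >= 2L, !is.null(names(densities)))
  mu <- mean(densities)
  s <- sqrt(mean((densities - mu)^2))   # population SD
  names(densities)[densities > mu + sd_mult * s]
}
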