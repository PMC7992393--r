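#' Read a FASTA file into a named vector of DNA sequences
#'
#' Sequences are uppercase-normalized and validated against the `{A,C,G,T,N}`
#' alphabet; IUPAC ambiguity codes other than `N` are rejected rather than
#' silently converted. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are record ids (first whitespace
#'   token of each header), values the uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(is.na(ids) | ids == "")) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("illegal characters in record: ", ids[bad][1L])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (wrapped at 80 columns)
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over its input; `N` maps to `N`. An involution:
#' `revcomp(revcomp(s)) == s`.
#'
#' @param seq Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq))) stop("illegal character in sequence")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator. A
#' sequence that is all `N` returns `NA_real_`.
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq))
  if (any(nchar(seq) == 0L)) stop("empty sequence")
  x <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- ifelse(denom == 0, NA_real_, (f[, "C"] + f[, "G"]) / denom)
  unname(out)
}

# ---- Feature tables (BED; 0-based half-open, forward-strand coordinates) ----

FEATURE_CLASSES <- c("gene", "DNA_transposon", "LTR", "LINE", "satellite",
                     "simple_repeat", "helitron", "other")

#' Construct a validated feature table
#'
#' @param seq_id,start,end,strand,klass Parallel vectors; `start`/`end` are
#'   0-based half-open, `strand` one of `+`, `-`, `.`.
#' @param seq_lengths Optional named vector of sequence lengths to validate
#'   coordinates against.
#' @return A `data.frame` with columns `seq_id, start, end, strand, klass`.
#' @export
feature_table <- function(seq_id, start, end, strand = ".", klass = "other",
                          seq_lengths = NULL) {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), klass = as.character(klass),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L | df$start >= df$end)) {
    stop("features must satisfy 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("bad strand")
  if (!is.null(seq_lengths)) {
    known <- df$seq_id %in% names(seq_lengths)
    if (any(known & df$end > seq_lengths[df$seq_id])) {
      stop("feature extends past end of its sequence")
    }
  }
  df
}

#' Read features from BED
#'
#' BED is already 0-based half-open, matching the package's internal
#' convention. Column 4 (name) is taken as the feature class.
#'
#' @param path BED file path.
#' @return Feature `data.frame` (see [feature_table()]).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  klass <- if (!is.null(gr$name)) as.character(gr$name) else "other"
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  feature_table(as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                strand, klass)
}

#' Write features to BED
#'
#' @param features Feature `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  strand <- features$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    features$seq_id,
    IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand)
  gr$name <- features$klass
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read genes from a GFF3 file (read-only adapter)
#'
#' GFF3 is 1-based inclusive; coordinates are shifted to the package's
#' 0-based half-open convention on read. Only rows with `type == "gene"`
#' are returned.
#'
#' @param path GFF3 file path.
#' @return Feature `data.frame` with `klass == "gene"`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[as.character(gr$type) == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  feature_table(as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                strand, "gene")
}

# ---- Depth tracks (bedGraph; runs are 0-based half-open) ----

#' Read a depth track from bedGraph
#'
#' @param path bedGraph file path.
#' @return `data.frame` with `seq_id, start, end, depth` (0-based half-open
#'   runs, sorted and non-overlapping per sequence).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   depth = as.numeric(gr$score),
                   stringsAsFactors = FALSE)
  df <- df[order(df$seq_id, df$start), , drop = FALSE]
  if (any(df$depth < 0)) stop("negative depth in bedGraph")
  rownames(df) <- NULL
  df
}

#' Write a depth track to bedGraph
#'
#' @param track Depth-run `data.frame` (`seq_id, start, end, depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$seq_id,
    IRanges::IRanges(start = track$start + 1L, end = track$end))
  gr$score <- track$depth
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Expand a run-encoded depth track to a per-base vector for one sequence.
depth_vector <- function(track, seq_id, seq_length) {
  runs <- track[track$seq_id == seq_id, , drop = FALSE]
  v <- numeric(seq_length)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      v[(runs$start[i] + 1L):min(runs$end[i], seq_length)] <- runs$depth[i]
    }
  }
  v
}

# Compress a per-base depth vector into runs.
depth_runs <- function(seq_id, values) {
  r <- rle(values)
  end <- cumsum(r$lengths)
  data.frame(seq_id = seq_id, start = c(0L, head(end, -1L)), end = end,
             depth = r$values, stringsAsFactors = FALSE)
}

# ---- Structural variants (VCF v4.x read-only subset) ----

#' Read structural variants from a VCF
#'
#' Extracts per-record length and read support. `SVLEN` is taken from INFO;
#' reference/variant supports are looked up first in INFO and then in the
#' first sample's FORMAT fields, under configurable keys (Sniffles-style
#' `DR`/`DV` by default).
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param svlen_key INFO key holding the SV length.
#' @param ref_key,alt_key Keys holding reference / variant read support.
#' @return `data.frame` with `seq_id, pos` (1-based), `sv_len` (absolute bp),
#'   `ref_support, alt_support`.
#' @export
read_sv_vcf <- function(path, svlen_key = "SVLEN", ref_key = "DR",
                        alt_key = "DV") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, svlen_key)))
  pull_support <- function(key) {
    out <- suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
    if (all(is.na(out)) && nrow(v@gt) > 0 && ncol(v@gt) >= 2) {
      g <- vcfR::extract.gt(v, element = key, as.numeric = TRUE)
      out <- as.numeric(g[, 1L])
    }
    out
  }
  ref_support <- pull_support(ref_key)
  alt_support <- pull_support(alt_key)
  if (any(is.na(svlen))) stop("missing ", svlen_key, " in INFO")
  if (any(is.na(ref_support)) || any(is.na(alt_support))) {
    stop("missing support fields ", ref_key, "/", alt_key)
  }
  if (any(ref_support < 0) || any(alt_support < 0)) {
    stop("negative support counts")
  }
  data.frame(seq_id = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             sv_len = abs(as.numeric(svlen)),
             ref_support = as.integer(ref_support),
             alt_support = as.integer(alt_support),
             stringsAsFactors = FALSE)
}

# ---- Linkage-map marker tables ----

#' Read a linkage-map marker table
#'
#' Tab-separated with header; required columns `marker_id, lg, cm`, optional
#' alignment columns `seq_id, pos, mapq` (`pos` in bp, `mapq` in `[0, 60]`).
#'
#' @param path TSV path.
#' @return Marker `data.frame`.
#' @export
read_marker_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("marker_id", "lg", "cm")
  if (!all(req %in% names(df))) {
    stop("marker table needs columns: ", paste(req, collapse = ", "))
  }
  df$cm <- as.numeric(df$cm)
  if (any(!is.finite(df$cm)) || any(df$cm < 0)) stop("cm must be finite and >= 0")
  if ("mapq" %in% names(df)) {
    ok <- is.na(df$mapq) | (df$mapq >= 0 & df$mapq <= 60)
    if (!all(ok)) stop("mapq must be in [0, 60]")
  }
  df
}

#' Write a linkage-map marker table
#'
#' @param markers Marker `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
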