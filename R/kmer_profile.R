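#' Count canonical k-mers into a depth spectrum
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement) are counted across all reads; k-mers containing `N` are
#' skipped. The histogram conserves the total: `sum(depth * count)` equals
#' the number of counted k-mer instances.
#'
#' @param reads Character vector of reads.
#' @param k Odd k-mer size, `1 < k <= 31` (21 is the usual choice for
#'   genome profiling).
#' @return An object of class `kmer_spectrum`: `list(k, hist)` with `hist`
#'   a data frame of `depth` and `count` (distinct canonical k-mers seen at
#'   that depth).
#' @export
count_kmers <- function(reads, k = 21L) {
  stopifnot(is.character(reads), length(reads) > 0)
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    stop("k must be odd (even k makes canonicalization ambiguous for ",
         "self-complementary k-mers)")
  }
  if (k <= 1L || k > 31L) stop("k must satisfy 1 < k <= 31")
  m <- .kmer_hist_cpp(reads, k)
  structure(list(k = k,
                 hist = data.frame(depth = as.integer(m[, 1L]),
                                   count = as.integer(m[, 2L]),
                                   row.names = NULL)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum (k =", x$k, "):",
      sum(as.numeric(x$hist$count)), "distinct canonical k-mers,",
      sum(as.numeric(x$hist$depth) * x$hist$count), "instances\n")
  invisible(x)
}

# Dense smoothed counts over depths 1..max (centered moving average, width 3).
smoothed_hist <- function(spectrum) {
  h <- spectrum$hist
  dmax <- max(h$depth)
  dense <- numeric(dmax)
  dense[h$depth] <- h$count
  s <- dense
  if (dmax >= 3L) {
    s[2:(dmax - 1L)] <- (dense[1:(dmax - 2L)] + dense[2:(dmax - 1L)] +
                           dense[3:dmax]) / 3
  }
  s
}

#' Locate heterozygous and homozygous coverage peaks in a k-mer spectrum
#'
#' The histogram is smoothed with a centered moving average of width 3; the
#' error cutoff is the depth of the first local minimum (depth 1 when the
#' histogram rises from the start, as in error-free data). Local maxima
#' above the cutoff are candidate peaks; with two or more, the two most
#' massive are taken and reported as (het, hom) in depth order, provided
#' their depth ratio lies in the diploid range `[1.6, 2.4]`; otherwise the
#' single dominant peak is the homozygous peak and the het peak is absent.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param min_peak_frac Candidate peaks below this fraction of the tallest
#'   peak's smoothed count are ignored as noise.
#' @return `list(het_peak, hom_peak, error_cutoff, valley)`; `het_peak` and
#'   `valley` are `NA` for a single-peak (haploid-like) spectrum.
#' @export
find_peaks <- function(spectrum, min_peak_frac = 0.05) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  s <- smoothed_hist(spectrum)
  n <- length(s)
  if (n < 3L) stop("spectrum unresolvable: too few depth bins")
  # first local minimum = end of the initial (error) decline
  cutoff <- 1L
  for (d in 2:(n - 1L)) {
    if (s[d] <= s[d - 1L] && s[d] < s[d + 1L]) { cutoff <- d; break }
    if (s[d] > s[d - 1L]) { cutoff <- max(1L, d - 1L); break }
  }
  region <- seq.int(cutoff, n)
  cand <- region[vapply(region, function(d) {
    left <- if (d == 1L) 0 else s[d - 1L]
    right <- if (d == n) 0 else s[d + 1L]
    s[d] > 0 && s[d] >= left && s[d] > right
  }, logical(1))]
  if (!length(cand)) stop("spectrum unresolvable: no peak above error cutoff")
  cand <- cand[s[cand] >= min_peak_frac * max(s[cand])]
  if (length(cand) >= 2L) {
    top2 <- sort(cand[order(s[cand], decreasing = TRUE)][1:2])
    ratio <- top2[2L] / top2[1L]
    if (ratio >= 1.6 && ratio <= 2.4) {
      valley <- top2[1L] + which.min(s[top2[1L]:top2[2L]]) - 1L
      return(list(het_peak = top2[1L], hom_peak = top2[2L],
                  error_cutoff = cutoff, valley = valley))
    }
  }
  hom <- cand[which.max(s[cand])]
  list(het_peak = NA_integer_, hom_peak = hom, error_cutoff = cutoff,
       valley = NA_integer_)
}

#' Estimate haploid genome size from a k-mer spectrum
#'
#' `size = sum(depth * count over depths >= error cutoff) / hom_peak_depth`:
#' total informative k-mer mass divided by the homozygous peak depth gives
#' the haploid-equivalent number of k-mer positions.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param peaks Output of [find_peaks()] (computed if missing).
#' @return Estimated genome size in bp (k-mer positions).
#' @export
estimate_genome_size <- function(spectrum, peaks = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(peaks)) peaks <- find_peaks(spectrum)
  h <- spectrum$hist
  keep <- h$depth >= peaks$error_cutoff
  mass <- sum(as.numeric(h$depth[keep]) * h$count[keep])
  if (peaks$hom_peak <= 0 || mass <= 0) {
    stop("empty spectrum above error cutoff")
  }
  mass / peaks$hom_peak
}

#' Estimate heterozygosity from a bimodal k-mer spectrum
#'
#' Let `F` be the k-mer mass (`depth * count`) in the heterozygous peak
#' region (between the error cutoff and the valley separating the two
#' peaks) divided by the total informative mass. Every heterozygous site
#' disrupts up to `k` spanning k-mers on each haplotype, so the expected
#' het-peak mass fraction is `1 - (1 - h)^k` for per-base heterozygosity
#' `h`; inverting gives `h = 1 - (1 - F)^(1/k)`.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param peaks Output of [find_peaks()] (computed if missing).
#' @return Heterozygosity as a fraction, or `NA_real_` when the spectrum
#'   has no heterozygous peak.
#' @export
estimate_heterozygosity <- function(spectrum, peaks = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(peaks)) peaks <- find_peaks(spectrum)
  if (is.na(peaks$het_peak)) return(NA_real_)
  h <- spectrum$hist
  mass <- function(lo, hi) {
    keep <- h$depth >= lo & h$depth <= hi
    sum(as.numeric(h$depth[keep]) * h$count[keep])
  }
  het_mass <- mass(peaks$error_cutoff, peaks$valley - 1L)
  tot_mass <- mass(peaks$error_cutoff, max(h$depth))
  if (tot_mass <= 0) stop("empty spectrum above error cutoff")
  F <- het_mass / tot_mass
  1 - (1 - F)^(1 / spectrum$k)
}

#' Assemble a k-mer spectrum from a depth histogram table
#'
#' Convenience constructor for histograms read from disk (two-column
#' `depth<TAB>count`, as written by common k-mer counters).
#'
#' @param depth,count Parallel integer vectors.
#' @param k k-mer size the histogram was computed at.
#' @return A `kmer_spectrum`.
#' @export
kmer_spectrum <- function(depth, count, k = 21L) {
  stopifnot(length(depth) == length(count), all(depth >= 1), all(count >= 0))
  o <- order(depth)
  structure(list(k = as.integer(k),
                 hist = data.frame(depth = as.integer(depth[o]),
                                   count = as.numeric(count[o]))),
            class = "kmer_spectrum")
}
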