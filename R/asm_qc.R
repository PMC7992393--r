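#' Median read depth in non-overlapping windows
#'
#' Windows of `window` bp tile each scaffold from position 0; the last
#' window may be shorter. The median is taken over the window's per-base
#' depths; window GC is computed from the assembly sequence.
#'
#' @param track Depth-run `data.frame` (`seq_id, start, end, depth`).
#' @param assembly Named character vector of scaffold sequences.
#' @param window Window size (bp; 1000 matches the common QC convention).
#' @return `data.frame` of QC windows:
#'   `seq_id, start, end, gc, median_depth_raw`.
#' @export
window_medians <- function(track, assembly, window = 1000L) {
  stopifnot(window >= 1L)
  out <- list()
  for (id in names(assembly)) {
    L <- nchar(assembly[[id]])
    if (L < 1L) {
      warning("skipping zero-length scaffold: ", id)
      next
    }
    depth <- depth_vector(track, id, L)
    nw <- ceiling(L / window)
    st <- (seq_len(nw) - 1L) * window
    en <- pmin(st + window, L)
    med <- vapply(seq_len(nw), function(i) {
      median(depth[(st[i] + 1L):en[i]])
    }, numeric(1))
    gcw <- gc_fraction(substring(assembly[[id]], st + 1L, en))
    out[[id]] <- data.frame(seq_id = id, start = st, end = en, gc = gcw,
                            median_depth_raw = med, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GC-normalize window medians
#'
#' Windows are binned by GC in `bin_width` bins. Each bin's scale factor is
#' the global median of window medians divided by the bin median; bins with
#' fewer than `min_bin` windows inherit the factor of the nearest populated
#' bin. `median_depth_norm = median_depth_raw * factor`.
#'
#' @param windows Output of [window_medians()].
#' @param bin_width GC bin width (fraction; default 2%).
#' @param min_bin Minimum windows for a bin to define its own factor.
#' @return `windows` with an added `median_depth_norm` column.
#' @export
gc_normalize <- function(windows, bin_width = 0.02, min_bin = 10L) {
  stopifnot(nrow(windows) >= 1L)
  if (all(windows$median_depth_raw == 0)) {
    stop("all window medians are zero; cannot normalize")
  }
  gc <- windows$gc
  gc[is.na(gc)] <- 0.5
  bin <- floor(gc / bin_width)
  global_med <- median(windows$median_depth_raw)
  tab <- table(bin)
  bins <- as.integer(names(tab))
  bin_med <- vapply(bins, function(b) {
    median(windows$median_depth_raw[bin == b])
  }, numeric(1))
  populated <- bins[tab >= min_bin & bin_med > 0]
  factor_of <- function(b) {
    if (length(populated) == 0L) return(1)
    src <- if (b %in% populated) b else
      populated[which.min(abs(populated - b))]
    global_med / bin_med[match(src, bins)]
  }
  factors <- vapply(bins, factor_of, numeric(1))
  if (length(populated) <= 1L) factors[] <- 1  # single bin: exact identity
  windows$median_depth_norm <-
    windows$median_depth_raw * factors[match(bin, bins)]
  windows
}

#' Flag scaffolds dominated by aberrant coverage
#'
#' The mean and SD are computed assembly-wide over all windows' normalized
#' medians. A window is an outlier when its normalized median deviates from
#' the mean by more than `sd_mult` SD; a scaffold is flagged when its
#' outlier-window fraction strictly exceeds `frac_threshold`.
#'
#' @param windows GC-normalized windows (from [gc_normalize()]).
#' @param frac_threshold Flagging threshold on the outlier fraction
#'   (strict `>`; 0.70 means 7/10 outlier windows does not flag).
#' @param sd_mult Outlier band half-width in SD units (strictly outside).
#' @return `data.frame` per scaffold:
#'   `seq_id, n_windows, frac_outlier_windows, flagged`.
#' @export
flag_low_accuracy <- function(windows, frac_threshold = 0.70, sd_mult = 2.0) {
  if (!"median_depth_norm" %in% names(windows)) {
    stop("windows must be GC-normalized first (see gc_normalize)")
  }
  stopifnot(nrow(windows) >= 2L)
  x <- windows$median_depth_norm
  mu <- mean(x)
  s <- sd(x)
  outlier <- if (s == 0) x != mu else abs(x - mu) > sd_mult * s
  agg <- tapply(outlier, windows$seq_id, mean)
  nw <- tapply(outlier, windows$seq_id, length)
  data.frame(seq_id = names(agg), n_windows = as.integer(nw),
             frac_outlier_windows = as.numeric(agg),
             flagged = as.numeric(agg) > frac_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter structural variants down to putative assembly errors
#'
#' A record is an assembly error when its length is at least `min_size` and
#' the reference-support ratio `ref / (ref + alt)` is strictly below
#' `max_ref_ratio`. Records with zero total support are excluded with a
#' warning.
#'
#' @param svs SV `data.frame` (`seq_id, pos, sv_len, ref_support,
#'   alt_support`), as returned by [read_sv_vcf()].
#' @param min_size Minimum SV size (bp, inclusive).
#' @param max_ref_ratio Strict upper bound on the reference-support ratio.
#' @return The subset of `svs` classified as assembly errors, with an added
#'   `ref_ratio` column.
#' @export
filter_sv_errors <- function(svs, min_size = 50L, max_ref_ratio = 0.2) {
  if (any(svs$sv_len < 0 | svs$ref_support < 0 | svs$alt_support < 0)) {
    stop("negative SV fields")
  }
  tot <- svs$ref_support + svs$alt_support
  if (any(tot == 0)) {
    warning(sum(tot == 0), " SV record(s) with zero total support excluded")
  }
  keep <- tot > 0
  svs <- svs[keep, , drop = FALSE]
  svs$ref_ratio <- svs$ref_support / (svs$ref_support + svs$alt_support)
  err <- svs$sv_len >= min_size & svs$ref_ratio < max_ref_ratio
  res <- svs[err, , drop = FALSE]
  rownames(res) <- NULL
  res
}
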