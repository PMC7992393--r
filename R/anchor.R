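#' Filter linkage-map markers by alignment quality
#'
#' A marker is retained when it has an alignment (`seq_id` and `pos`
#' present) and its MAPQ strictly exceeds `min_mapq_exclusive` (the
#' conventional `MAPQ > 16` cut: 17 kept, 16 dropped).
#'
#' @param markers Marker `data.frame` (see [read_marker_table()]).
#' @param min_mapq_exclusive Strict lower bound on MAPQ.
#' @return The retained subset of `markers`.
#' @export
filter_markers <- function(markers, min_mapq_exclusive = 16L) {
  need <- c("seq_id", "pos", "mapq")
  if (!all(need %in% names(markers))) {
    stop("markers lack alignment columns: ", paste(need, collapse = ", "))
  }
  keep <- !is.na(markers$seq_id) & markers$seq_id != "" &
    !is.na(markers$pos) & !is.na(markers$mapq) &
    markers$mapq > min_mapq_exclusive
  res <- markers[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign scaffolds to linkage groups by marker majority vote
#'
#' Each scaffold is assigned the modal linkage group among its retained
#' markers. The support fraction is reported; scaffolds whose second most
#' common linkage group holds more than `conflict_frac` of their markers
#' are flagged as conflicting rather than silently resolved.
#'
#' @param markers Retained markers (see [filter_markers()]).
#' @param conflict_frac Conflict threshold on the runner-up fraction.
#' @return `data.frame`:
#'   `seq_id, lg, support_fraction, n_markers, conflicting`.
#' @export
assign_lg <- function(markers, conflict_frac = 0.20) {
  stopifnot(nrow(markers) >= 1L)
  out <- lapply(split(markers, markers$seq_id), function(m) {
    tab <- sort(table(m$lg), decreasing = TRUE)
    n <- nrow(m)
    second <- if (length(tab) >= 2L) tab[2L] / n else 0
    data.frame(seq_id = m$seq_id[1L], lg = names(tab)[1L],
               support_fraction = as.numeric(tab[1L]) / n, n_markers = n,
               conflicting = second > conflict_frac,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Order and orient scaffolds within one linkage group
#'
#' Scaffolds are ordered by the mean genetic position (cM) of their
#' markers. Orientation is the sign of the Spearman correlation between
#' marker cM and physical bp on the scaffold: `rho >= 0` is forward. The
#' cM-bp relation is monotone but not linear, hence the rank correlation.
#' `|rho| < 0.5` is reported `uncertain`; fewer than 2 markers gives
#' `unknown`.
#'
#' @param markers Retained markers for scaffolds of a single linkage group.
#' @param uncertain_rho Absolute-correlation threshold below which the
#'   orientation is called uncertain.
#' @return `data.frame` ordered along the linkage group:
#'   `seq_id, mean_cm, n_markers, rho, orientation` (one of `+`, `-`,
#'   `uncertain`, `unknown`).
#' @export
order_orient <- function(markers, uncertain_rho = 0.5) {
  stopifnot(nrow(markers) >= 1L)
  if (length(unique(markers$lg)) > 1L) {
    stop("order_orient expects markers from a single linkage group")
  }
  out <- lapply(split(markers, markers$seq_id), function(m) {
    rho <- NA_real_
    orientation <- "unknown"
    if (nrow(m) >= 2L) {
      rho <- suppressWarnings(cor(m$cm, m$pos, method = "spearman"))
      orientation <- if (is.na(rho)) "uncertain"
        else if (abs(rho) < uncertain_rho) "uncertain"
        else if (rho >= 0) "+" else "-"
    }
    data.frame(seq_id = m$seq_id[1L], mean_cm = mean(m$cm),
               n_markers = nrow(m), rho = rho, orientation = orientation,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$mean_cm, res$seq_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
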