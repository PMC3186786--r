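# Correlation of per-bin crossover counts with repeat-element classes,
# CpG islands, and tandem repeats grouped into length quartiles.
#
# Annotation intervals are counted once in the bin containing their midpoint
# (mirroring event binning); correlations use covered bins only, with
# Bonferroni adjustment over the number of classes tested (capped at 1).

#' Count annotation intervals per bin and class
#'
#' @param intervals Annotation data.frame from [read_annotation_bed()]
#'   (0-based half-open; `class` column).
#' @param bins Bin table / grid (see [make_bin_grid()]).
#' @return Integer matrix, `nrow(bins)` x classes; column names are class
#'   labels. Intervals on chromosomes absent from the grid are skipped with
#'   a warning.
#' @export
count_annotations_per_bin <- function(intervals, bins) {
  classes <- sort(unique(intervals$class))
  counts <- matrix(0L, nrow = nrow(bins), ncol = length(classes),
                   dimnames = list(NULL, classes))
  if (!nrow(intervals)) return(counts)
  known <- intervals$chrom %in% bins$chrom
  if (any(!known))
    warning(sum(!known), " interval(s) on chromosomes absent from the bin grid skipped")
  iv <- intervals[known, , drop = FALSE]
  if (!nrow(iv)) return(counts)
  mid <- (iv$start + iv$end) / 2
  idx <- bin_index(bins, iv$chrom, mid)
  ok <- !is.na(idx)
  if (any(!ok)) warning(sum(!ok), " interval(s) beyond chromosome end skipped")
  tab <- table(idx[ok], iv$class[ok])
  rows <- as.integer(rownames(tab))
  for (cl in colnames(tab)) counts[rows, cl] <- counts[rows, cl] + as.integer(tab[, cl])
  counts
}

#' Correlate per-bin crossover counts with annotation counts
#'
#' Pearson correlation with two-sided p, per annotation class and sex channel
#' (paternal counts, maternal counts, both), over covered bins only.
#' `p_adjusted` is Bonferroni over `adjust_m` tests, capped at 1.
#'
#' @param bins Bin table from [bin_events()].
#' @param annot_counts Matrix from [count_annotations_per_bin()].
#' @param adjust_m Bonferroni multiplier (default: number of classes).
#' @return data.frame: `class`, `sex` (`M`, `F`, `BOTH`), `n_sites`, `r`,
#'   `p_raw`, `p_adjusted`, `n_bins`. Zero-variance vectors give `r = NA`.
#' @export
correlate_annotations <- function(bins, annot_counts, adjust_m = ncol(annot_counts)) {
  stopifnot(nrow(annot_counts) == nrow(bins), adjust_m >= 1)
  sel <- bins$covered
  if (sum(sel) < 3L) stop("fewer than 3 covered bins")
  channels <- list(M = bins$male[sel], F = bins$female[sel], BOTH = bins$both[sel])
  out <- list()
  for (cl in colnames(annot_counts)) {
    a <- annot_counts[sel, cl]
    for (sx in names(channels)) {
      pt <- pearson_test(channels[[sx]], a)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, sex = sx, n_sites = sum(annot_counts[, cl]),
        r = pt$r, p_raw = pt$p,
        p_adjusted = if (is.na(pt$p)) NA_real_ else min(1, pt$p * adjust_m),
        n_bins = pt$n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split tandem repeats into length quartile classes
#'
#' Relabels tandem-repeat intervals by length class: Q1 (1-4 bp), Q2 (5-15),
#' Q3 (16-24), Q4 (>= 25). Non-positive lengths are rejected.
#'
#' @param intervals Annotation data.frame with a `length` column (bp).
#' @return The intervals with `class` replaced by `"Q1"`..`"Q4"`.
#' @export
tandem_quartile_split <- function(intervals) {
  len <- intervals$length
  if (anyNA(len)) stop("tandem repeats must carry a length attribute")
  if (any(len <= 0)) stop("non-positive tandem-repeat length")
  q <- cut(len, breaks = c(0, 4, 15, 24, Inf), labels = paste0("Q", 1:4))
  out <- intervals
  out$class <- as.character(q)
  out
}

#' Per-bin counts of tandem repeats by length quartile
#'
#' @param intervals Tandem-repeat intervals with `length`.
#' @param bins Bin grid.
#' @return Matrix with columns Q1..Q4 (always all four, zero-filled), rows
#'   matching `bins`; the quartile vectors partition the all-repeats counts.
#' @export
tandem_quartile_counts <- function(intervals, bins) {
  split_iv <- tandem_quartile_split(intervals)
  counts <- count_annotations_per_bin(split_iv, bins)
  full <- matrix(0L, nrow = nrow(bins), ncol = 4,
                 dimnames = list(NULL, paste0("Q", 1:4)))
  full[, colnames(counts)] <- counts
  full
}
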