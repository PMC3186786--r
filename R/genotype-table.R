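# Core containers: markers, samples, genotype matrix.
#
# Genotype calls are stored as integer codes in a samples x markers matrix:
#   0 = NOCALL, 1 = AA, 2 = AB (unordered heterozygote), 3 = BB.
# "A"/"B" are per-marker allele labels fixed at read/simulation time; every
# downstream coding is invariant to swapping them.

GT_NOCALL <- 0L
GT_AA <- 1L
GT_AB <- 2L
GT_BB <- 3L

GT_LABELS <- c("NOCALL", "AA", "AB", "BB")

# B-allele dosage per code (NOCALL -> NA)
GT_DOSAGE <- c(NA_integer_, 0L, 1L, 2L)

#' Construct a genotype table
#'
#' Bundles an ordered marker map, a sample sheet with pedigree links, and an
#' integer genotype matrix into a single validated object.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp).
#'   Markers must be sorted by chromosome and strictly increasing position
#'   within each chromosome; ids must be unique.
#' @param samples data.frame with columns `id`, `family_id`, `father_id`,
#'   `mother_id` (NA when unknown) and `sex` (`"M"`, `"F"` or `"U"`).
#' @param calls integer matrix (`nrow(samples)` x `nrow(markers)`) of genotype
#'   codes 0 = NOCALL, 1 = AA, 2 = AB, 3 = BB.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(markers, samples, calls) {
  stopifnot(is.data.frame(markers), all(c("id", "chrom", "pos") %in% names(markers)),
            is.data.frame(samples), all(c("id", "family_id", "father_id", "mother_id", "sex") %in% names(samples)))
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  samples$id <- as.character(samples$id)
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (anyDuplicated(samples$id)) stop("duplicate individual ids: ",
                                      paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) stop("marker positions not strictly increasing on ", ch)
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("calls matrix must be n_samples x n_markers")
  if (any(calls < 0L | calls > 3L, na.rm = TRUE) || anyNA(calls))
    stop("genotype codes must be integers in 0..3")
  rownames(calls) <- samples$id
  colnames(calls) <- markers$id
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "samples x", nrow(x$markers), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  cr <- call_rates(x)
  cat("call rate: median", signif(stats::median(cr), 4),
      "range", signif(min(cr), 4), "-", signif(max(cr), 4), "\n")
  invisible(x)
}

#' Per-sample genotype call rates
#'
#' @param gt A [genotype_table()].
#' @return Named numeric vector, fraction of non-NOCALL entries per sample.
#' @export
call_rates <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  rowMeans(gt$calls != GT_NOCALL)
}

#' Subset a genotype table by samples and/or markers
#'
#' @param gt A [genotype_table()].
#' @param samples character vector of sample ids to keep (default all).
#' @param markers logical/integer/character index of markers to keep.
#' @return A new `genotype_table`.
#' @export
subset_genotypes <- function(gt, samples = NULL, markers = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  si <- if (is.null(samples)) seq_len(nrow(gt$samples)) else match(samples, gt$samples$id)
  if (anyNA(si)) stop("unknown sample id(s)")
  mi <- if (is.null(markers)) seq_len(nrow(gt$markers)) else markers
  genotype_table(gt$markers[mi, , drop = FALSE],
                 gt$samples[si, , drop = FALSE],
                 gt$calls[si, mi, drop = FALSE])
}

# marker indices of one chromosome, in map order
chrom_index <- function(gt, chrom) which(gt$markers$chrom == chrom)
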