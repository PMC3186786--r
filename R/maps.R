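# Fixed-width genome bins, sex-specific recombination maps, per-arm
# centromere-distance regressions, and comparison with external genetic maps.
#
# Bin grid: 1 Mb by default, covering each chromosome fully (last bin
# truncated at the chromosome end). A bin is "covered" when it contains at
# least one array SNP; uncovered bins are masked from regressions and
# correlations. Events are anchored at the midpoint of their uninformative
# region.

#' Build a fixed-width bin grid
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_width Bin width in bp (default 1 Mb).
#' @param snp_positions Optional marker data.frame (`chrom`, `pos`) defining
#'   SNP coverage; bins without any SNP get `covered = FALSE` (all bins
#'   covered when NULL).
#' @return data.frame: `chrom`, `start` (0-based), `end`, `mid`, `covered`.
#' @export
make_bin_grid <- function(chrom_lengths, bin_width = 1e6, snp_positions = NULL) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0), bin_width > 0)
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    start <- seq(0, L - 1, by = bin_width)
    end <- pmin(start + bin_width, L)
    out[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                            mid = (start + end) / 2, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  bins$covered <- TRUE
  if (!is.null(snp_positions)) {
    bins$covered <- FALSE
    idx <- bin_index(bins, snp_positions$chrom, snp_positions$pos - 1, bin_width)
    bins$covered[unique(idx[!is.na(idx)])] <- TRUE
  }
  attr(bins, "bin_width") <- bin_width
  bins
}

# row index in `bins` of the bin containing 0-based position `pos0`
bin_index <- function(bins, chrom, pos0, bin_width = attr(bins, "bin_width")) {
  if (is.null(bin_width)) bin_width <- max(bins$end - bins$start)
  first <- match(unique(bins$chrom), bins$chrom)
  names(first) <- unique(bins$chrom)
  off <- first[chrom]
  idx <- off + floor(pos0 / bin_width)
  # clamp positions in the truncated last bin / reject beyond chromosome
  last <- c(first[-1] - 1L, nrow(bins))
  names(last) <- names(first)
  bad <- !is.na(idx) & (idx > last[chrom] | pos0 < 0)
  idx[bad] <- NA_integer_
  unname(idx)
}

#' Bin crossover events into a sex-specific count table
#'
#' Each event is anchored at the midpoint of its uninformative region and
#' counted in the containing bin under the sex of the recombining parent
#' (paternal = male, maternal = female).
#'
#' @param events Events data.frame with `chrom`, `left_pos`, `right_pos`,
#'   `parent` (`"paternal"`/`"maternal"`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param snp_positions Optional marker data.frame for coverage masking.
#' @param bin_width Bin width in bp (default 1 Mb).
#' @return Bin table: grid columns plus `male`, `female`, `both`.
#' @export
bin_events <- function(events, chrom_lengths, snp_positions = NULL,
                       bin_width = 1e6) {
  bins <- make_bin_grid(chrom_lengths, bin_width, snp_positions)
  bins$male <- 0L; bins$female <- 0L
  if (!is.null(events) && nrow(events)) {
    if (!all(events$chrom %in% names(chrom_lengths)))
      stop("event on chromosome absent from chrom_lengths")
    mid <- (as.numeric(events$left_pos) + as.numeric(events$right_pos)) / 2
    if (any(mid > chrom_lengths[events$chrom]))
      stop("event anchored beyond chromosome length")
    idx <- bin_index(bins, events$chrom, mid - 0.5, bin_width)  # 1-based mid -> 0-based
    if (anyNA(idx)) stop("event anchored beyond chromosome length")
    sex <- ifelse(events$parent == "paternal", "male", "female")
    tab <- table(idx, sex)
    rows <- as.integer(rownames(tab))
    if ("male" %in% colnames(tab)) bins$male[rows] <- bins$male[rows] + as.integer(tab[, "male"])
    if ("female" %in% colnames(tab)) bins$female[rows] <- bins$female[rows] + as.integer(tab[, "female"])
  }
  bins$both <- bins$male + bins$female
  attr(bins, "bin_width") <- bin_width
  bins
}

#' Per-arm regression of bin counts on distance from the centromere
#'
#' For each chromosome arm and sex, ordinary least squares of the per-bin
#' event count on the distance (Mb) from the nearest centromere boundary to
#' the bin midpoint, with a two-sided t-test of slope != 0. Arms with fewer
#' than 3 covered bins give NA (e.g. acrocentric p arms without SNP
#' coverage). Only covered bins enter.
#'
#' @param bins Bin table from [bin_events()].
#' @param centromeres data.frame with `chrom`, `cen_start`, `cen_end`
#'   (0-based bp).
#' @return data.frame: `chrom`, `arm`, `sex`, `slope`, `p_value`, `n_bins`.
#' @export
arm_regression <- function(bins, centromeres) {
  out <- list()
  for (ch in unique(bins$chrom)) {
    ci <- match(ch, centromeres$chrom)
    if (is.na(ci)) {
      if (any(bins$both[bins$chrom == ch] > 0))
        stop("missing centromere for chromosome with events: ", ch)
      next
    }
    cs <- centromeres$cen_start[ci]; ce <- centromeres$cen_end[ci]
    b <- bins[bins$chrom == ch & bins$covered, , drop = FALSE]
    for (arm in c("p", "q")) {
      sub <- if (arm == "p") b[b$mid < cs, , drop = FALSE] else b[b$mid > ce, , drop = FALSE]
      dist_mb <- if (arm == "p") (cs - sub$mid) / 1e6 else (sub$mid - ce) / 1e6
      for (sex in c("M", "F")) {
        y <- if (sex == "M") sub$male else sub$female
        if (nrow(sub) < 3L || (sex == "M" && ch == "chrX")) {
          out[[length(out) + 1L]] <- data.frame(chrom = ch, arm = arm, sex = sex,
                                                slope = NA_real_, p_value = NA_real_,
                                                n_bins = nrow(sub))
          next
        }
        fit <- ols_slope_test(dist_mb, y)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, arm = arm, sex = sex,
                                              slope = fit$slope, p_value = fit$p,
                                              n_bins = nrow(sub))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribute a cumulative genetic map onto the bin grid
#'
#' Assumes a constant crossover rate between adjacent map markers (piecewise
#' linear cumulative cM in physical position); each bin receives the cM
#' accumulated inside it, so per-chromosome totals are conserved.
#'
#' @param gmap data.frame with `chrom`, `pos` (bp), `cM` (cumulative,
#'   non-decreasing within chromosome).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_width Bin width in bp (default 1 Mb).
#' @return data.frame: `chrom`, `start`, `end`, `cM`.
#' @export
genetic_map_to_bins <- function(gmap, chrom_lengths, bin_width = 1e6) {
  bins <- make_bin_grid(chrom_lengths, bin_width)
  bins$cM <- 0
  for (ch in unique(gmap$chrom)) {
    g <- gmap[gmap$chrom == ch, , drop = FALSE]
    g <- g[order(g$pos), , drop = FALSE]
    if (nrow(g) < 2L) stop("need >= 2 map markers on ", ch)
    if (is.unsorted(g$cM)) stop("decreasing cumulative cM on ", ch)
    if (!ch %in% bins$chrom) next
    sel <- bins$chrom == ch
    # cumulative cM at bin boundaries; flat beyond the terminal markers
    F_ <- function(x) stats::approx(g$pos, g$cM, xout = x, rule = 2)$y
    bins$cM[sel] <- F_(bins$end[sel]) - F_(bins$start[sel])
  }
  bins[, c("chrom", "start", "end", "cM")]
}

#' Correlate a recombination map with external genetic maps
#'
#' Pearson correlation between per-bin sex-combined event counts and per-bin
#' cM, over covered bins, one coefficient per map source.
#'
#' @param bins Bin table from [bin_events()].
#' @param bin_cm Named list of per-bin cM data.frames from
#'   [genetic_map_to_bins()] (same grid), or a single such data.frame.
#' @return data.frame: `source`, `r`, `n_bins` (`r` = NA with < 3 common
#'   bins).
#' @export
compare_maps <- function(bins, bin_cm) {
  if (is.data.frame(bin_cm)) bin_cm <- list(map = bin_cm)
  out <- lapply(names(bin_cm), function(src) {
    cm <- bin_cm[[src]]
    stopifnot(nrow(cm) == nrow(bins))
    sel <- bins$covered
    r <- if (sum(sel) < 3L) NA_real_ else
      suppressWarnings(stats::cor(bins$both[sel], cm$cM[sel]))
    data.frame(source = src, r = r, n_bins = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a centromere table
#'
#' @param path TSV with columns chrom, cen_start, cen_end (0-based bp).
#' @return data.frame.
#' @export
read_centromeres <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "cen_start", "cen_end"))
}

#' Read a genetic map table
#'
#' @param path TSV with columns chrom, pos (bp), cM (cumulative).
#' @return data.frame.
#' @export
read_genetic_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "pos", "cM"))
}
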