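# Two-state switch scan shared by the PST and IBD callers.
#
# A switch code is a per-marker vector over one unit of analysis (a sibling
# pair for PST, a child for IBD) with values 0 = UNINFORMATIVE and two
# informative states (1/2). Crossovers appear as state changes along a
# chromosome; the uninformative region of an event runs from the last
# informative marker of the old state to the first accepted marker of the
# new state.

#' Construct a switch code
#'
#' @param code Integer vector over all markers of `markers` (0 =
#'   uninformative, 1, 2 = the two informative states).
#' @param labels Character(2): names of states 1 and 2 (e.g.
#'   `c("IDENTICAL","NOT_IDENTICAL")` or `c("GF","GM")`).
#' @param markers Marker data.frame (`id`, `chrom`, `pos`) the code is
#'   aligned to.
#' @param family,parent,unit Bookkeeping: family unit id, `"paternal"` or
#'   `"maternal"`, and the analysis unit (pair id `"c1+c2"` or child id).
#' @return An object of class `switch_code`.
#' @export
switch_code <- function(code, labels, markers, family = NA_character_,
                        parent = NA_character_, unit = NA_character_) {
  code <- as.integer(code)
  stopifnot(length(code) == nrow(markers), all(code %in% 0:2),
            length(labels) == 2)
  structure(list(code = code, labels = labels, markers = markers,
                 family = family, parent = parent, unit = unit),
            class = "switch_code")
}

#' @export
print.switch_code <- function(x, ...) {
  cat("switch_code [", x$labels[1], "/", x$labels[2], "] ",
      x$family, " ", x$parent, " ", x$unit, ": ",
      sum(x$code > 0L), "/", length(x$code), " informative markers\n", sep = "")
  invisible(x)
}

#' Detect crossover events from a switch code
#'
#' Scans informative codes chromosome by chromosome. Runs of an informative
#' state shorter than `min_run` are treated as genotyping noise and recoded
#' uninformative; each state change between the remaining runs emits one
#' event whose uninformative region spans from the last marker of the old
#' run to the first marker of the new run. A switch at the first or last
#' informative marker of a chromosome is still an event; no event can be
#' placed beyond the terminal informative markers.
#'
#' @param code A [switch_code()].
#' @param min_run Minimum accepted run length (default 3; use 1 for
#'   error-free data).
#' @return data.frame of events: `family`, `parent`, `unit`, `chrom`,
#'   `left_pos`, `right_pos`, `left_marker`, `right_marker`, `from_state`,
#'   `to_state`, `n_uninformative`, `region_bp`.
#' @export
detect_switches <- function(code, min_run = 3L) {
  stopifnot(inherits(code, "switch_code"), min_run >= 1L)
  out <- list()
  for (ch in unique(code$markers$chrom)) {
    idx <- which(code$markers$chrom == ch)
    v <- code$code[idx]
    inf <- which(v > 0L)
    if (length(inf) < 2L) {
      warning("fewer than 2 informative markers on ", ch, " for unit ",
              code$unit, "; no events called there")
      next
    }
    r <- rle(v[inf])
    keep <- r$lengths >= min_run
    if (!any(keep)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # surviving runs; merge adjacent equal states after dropping short runs
    st <- r$values[keep]; s0 <- starts[keep]; e0 <- ends[keep]
    merged_state <- st[1]; merged_start <- s0[1]; merged_end <- e0[1]
    ms <- integer(0); ma <- integer(0); me <- integer(0)
    for (k in seq_along(st)[-1]) {
      if (st[k] == merged_state) {
        merged_end <- e0[k]
      } else {
        ms <- c(ms, merged_state); ma <- c(ma, merged_start); me <- c(me, merged_end)
        merged_state <- st[k]; merged_start <- s0[k]; merged_end <- e0[k]
      }
    }
    ms <- c(ms, merged_state); ma <- c(ma, merged_start); me <- c(me, merged_end)
    if (length(ms) < 2L) next
    for (k in seq_len(length(ms) - 1L)) {
      li <- idx[inf[me[k]]]       # last marker of old-state run (full index)
      ri <- idx[inf[ma[k + 1L]]]  # first marker of accepted new-state run
      out[[length(out) + 1L]] <- data.frame(
        family = code$family, parent = code$parent, unit = code$unit,
        chrom = ch,
        left_pos = code$markers$pos[li], right_pos = code$markers$pos[ri],
        left_marker = code$markers$id[li], right_marker = code$markers$id[ri],
        from_state = code$labels[ms[k]], to_state = code$labels[ms[k + 1L]],
        n_uninformative = ri - li - 1L,
        region_bp = code$markers$pos[ri] - code$markers$pos[li],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}

empty_events <- function() {
  data.frame(family = character(0), parent = character(0), unit = character(0),
             chrom = character(0), left_pos = integer(0), right_pos = integer(0),
             left_marker = character(0), right_marker = character(0),
             from_state = character(0), to_state = character(0),
             n_uninformative = integer(0), region_bp = integer(0),
             stringsAsFactors = FALSE)
}
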