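# Three-generation identity-by-descent (IBD) comparator.
#
# For the paternal side of a child with both paternal grandparents typed:
# the allele the father transmitted to the child is resolved by subtracting
# the co-parent's contribution (transmitted_allele); the transmitted allele
# is then assigned to the grandfather (GF) or grandmother (GM) when exactly
# one of the two carrier assignments is Mendelian-consistent. A GF<->GM
# switch along the chromosome marks a crossover in the father's meiosis.
# All logic is single-marker; no multi-marker inference is attempted.

# alleles carried by a genotype code (B-allele values); NOCALL -> NULL
alleles_of <- list(NULL, 0L, 0:1, 1L)

# lookup tables for transmitted_allele over code triples (focal parent,
# coparent, child), built by enumeration of the allele decompositions
ta_tables <- local({
  allele <- array(NA_integer_, dim = c(4, 4, 4))
  status <- array("NOCALL", dim = c(4, 4, 4))
  for (f in 1:3) for (cp in 1:3) for (c_ in 1:3) {
    dc <- c_ - 1L  # child B dosage
    sols <- unique(unlist(lapply(alleles_of[[cp + 1L]], function(q) {
      t <- dc - q
      if (t %in% alleles_of[[f + 1L]]) t else NULL
    })))
    if (length(sols) == 1L) {
      allele[f + 1L, cp + 1L, c_ + 1L] <- sols
      status[f + 1L, cp + 1L, c_ + 1L] <- "OK"
    } else if (length(sols) > 1L) {
      status[f + 1L, cp + 1L, c_ + 1L] <- "AMBIGUOUS"
    } else {
      status[f + 1L, cp + 1L, c_ + 1L] <- "MENDEL_ERROR"
    }
  }
  list(allele = allele, status = status)
})

#' Resolve which allele a parent transmitted to a child
#'
#' Uses the co-parent's genotype to subtract the other contribution. The
#' result is unique, ambiguous (also when any call is missing), or
#' Mendelian-impossible.
#'
#' @param child,parent,coparent Integer genotype codes (0 = NOCALL, 1 = AA,
#'   2 = AB, 3 = BB); vectors of equal length are accepted.
#' @return List with `allele` (0 = A, 1 = B, NA when unresolved) and `status`
#'   (`"OK"`, `"AMBIGUOUS"`, `"MENDEL_ERROR"`, `"NOCALL"`).
#' @export
transmitted_allele <- function(child, parent, coparent) {
  stopifnot(length(child) == length(parent), length(parent) == length(coparent))
  i <- cbind(parent + 1L, coparent + 1L, child + 1L)
  list(allele = ta_tables$allele[i], status = ta_tables$status[i])
}

# does genotype code g carry allele a? (g must be called)
carries <- function(g, a) (g == GT_AB) | (g == GT_AA & a == 0L) | (g == GT_BB & a == 1L)

#' Grandparental-origin (IBD) coding for one child
#'
#' At each marker the code is GF or GM when the focal parent is heterozygous,
#' the transmitted allele is uniquely resolved, and exactly one grandparent
#' assignment is Mendelian-consistent; uninformative otherwise (focal parent
#' homozygous, ambiguous transmission, both grandparents possible carriers,
#' any NOCALL, or Mendelian impossibility). For the paternal side chrX is
#' excluded.
#'
#' @param gt A [genotype_table()].
#' @param family A family unit with the relevant grandparent pair.
#' @param child Sibling id.
#' @param parent `"paternal"` or `"maternal"`.
#' @return A [switch_code()] with states GF/GM.
#' @export
ibd_code_child <- function(gt, family, child, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  gp <- if (parent == "paternal") family$pat_grandparents else family$mat_grandparents
  if (is.null(gp)) stop("IBD requires three generations: no ",
                        parent, " grandparent pair in family ", family$id)
  stopifnot(child %in% family$siblings)
  fo <- gt$calls[focal_parent_id(family, parent), ]
  co <- gt$calls[coparent_id(family, parent), ]
  c_ <- gt$calls[child, ]
  gf <- gt$calls[gp[1], ]
  gm <- gt$calls[gp[2], ]
  ta <- transmitted_allele(c_, fo, co)
  ok <- fo == GT_AB & ta$status == "OK" & gf != GT_NOCALL & gm != GT_NOCALL
  t_ <- ta$allele
  o_ <- 1L - t_
  e1 <- ok & carries(gf, t_) & carries(gm, o_)  # GF supplied the transmitted allele
  e2 <- ok & carries(gm, t_) & carries(gf, o_)
  code <- rep(0L, length(fo))
  code[e1 & !e2] <- 1L
  code[e2 & !e1] <- 2L
  keep <- if (parent == "paternal") gt$markers$chrom != "chrX" else
    rep(TRUE, nrow(gt$markers))
  switch_code(code[keep], c("GF", "GM"), gt$markers[keep, , drop = FALSE],
              family = family$id, parent = parent, unit = child)
}

#' Call IBD crossover events for all three-generation families
#'
#' @param gt A [genotype_table()].
#' @param families List of family units; only those with the relevant
#'   grandparent pair are analyzed.
#' @param parent `"paternal"`, `"maternal"` or `"both"`.
#' @param min_run Noise filter for the switch scan.
#' @return Events data.frame (unit = child id), one row per detected
#'   crossover in that child's focal-parent meiosis.
#' @export
ibd_call <- function(gt, families, parent = c("both", "paternal", "maternal"),
                     min_run = 3L) {
  parent <- match.arg(parent)
  sides <- if (parent == "both") PARENT_SIDES else parent
  out <- list()
  any_family <- FALSE
  for (fu in families) {
    for (side in sides) {
      gp <- if (side == "paternal") fu$pat_grandparents else fu$mat_grandparents
      if (is.null(gp)) next
      any_family <- TRUE
      for (ch in fu$siblings) {
        code <- ibd_code_child(gt, fu, ch, side)
        out[[length(out) + 1L]] <- detect_switches(code, min_run = min_run)
      }
    }
  }
  if (!any_family) stop("IBD requires three generations: no family has the ",
                        "requested grandparent pair(s)")
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}

#' Compare PST and IBD uninformative regions over matched events
#'
#' Each PST pair event is matched to the overlapping IBD event(s) of either
#' sibling of the pair (same family, parental side, and chromosome); a PST
#' event overlapping two IBD events is paired with each separately. The
#' paired region sizes are compared with a two-sided paired t-test
#' (difference = PST - IBD) and summarized with means, SDs and quartiles
#' (Q2 = median; Q1/Q3 by linear interpolation).
#'
#' @param ibd_events Events from [ibd_call()].
#' @param pst_events Pair-level events from [pst_call()] (`$pair_events`).
#' @return Object of class `method_comparison`: `pairs` (matched records)
#'   and `summary` (n, means, SDs, quartiles, t, p).
#' @export
compare_methods <- function(ibd_events, pst_events) {
  recs <- list()
  if (!is.null(pst_events) && nrow(pst_events) && !is.null(ibd_events) && nrow(ibd_events)) {
    for (i in seq_len(nrow(pst_events))) {
      pe <- pst_events[i, ]
      kids <- strsplit(pe$unit, "+", fixed = TRUE)[[1]]
      cand <- ibd_events[ibd_events$family == pe$family &
                           ibd_events$parent == pe$parent &
                           ibd_events$chrom == pe$chrom &
                           ibd_events$unit %in% kids, , drop = FALSE]
      if (!nrow(cand)) next
      hit <- pmax(cand$left_pos, pe$left_pos) < pmin(cand$right_pos, pe$right_pos)
      for (j in which(hit))
        recs[[length(recs) + 1L]] <- data.frame(
          family = pe$family, parent = pe$parent, chrom = pe$chrom,
          pst_unit = pe$unit, ibd_unit = cand$unit[j],
          pst_region_bp = pe$region_bp, ibd_region_bp = cand$region_bp[j],
          pst_n_uninf = pe$n_uninformative, ibd_n_uninf = cand$n_uninformative[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    warning("no matched PST/IBD event pairs")
    pairs <- data.frame()
    summary <- list(n = 0L)
  } else {
    pairs <- do.call(rbind, recs)
    tt <- paired_t(pairs$pst_region_bp, pairs$ibd_region_bp)
    summary <- list(n = nrow(pairs),
                    ibd_mean_bp = mean(pairs$ibd_region_bp),
                    pst_mean_bp = mean(pairs$pst_region_bp),
                    ibd_sd_bp = stats::sd(pairs$ibd_region_bp),
                    pst_sd_bp = stats::sd(pairs$pst_region_bp),
                    ibd_quartiles_bp = quartiles(pairs$ibd_region_bp),
                    pst_quartiles_bp = quartiles(pairs$pst_region_bp),
                    ibd_mean_n_uninf = mean(pairs$ibd_n_uninf),
                    pst_mean_n_uninf = mean(pairs$pst_n_uninf),
                    mean_diff_bp = tt$mean_diff,
                    t = tt$t, p = tt$p)
  }
  structure(list(pairs = pairs, summary = summary), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  s <- x$summary
  cat("method_comparison:", s$n, "matched event pairs\n")
  if (s$n > 0) {
    cat(sprintf("  mean region: PST %.0f bp vs IBD %.0f bp (diff %.0f bp)\n",
                s$pst_mean_bp, s$ibd_mean_bp, s$mean_diff_bp))
    cat(sprintf("  mean uninformative SNPs: PST %.1f vs IBD %.1f\n",
                s$pst_mean_n_uninf, s$ibd_mean_n_uninf))
    cat(sprintf("  paired t = %.3f, p = %.3g\n", s$t, s$p))
  }
  invisible(x)
}

#' Check PST pair events against the union of the two children's IBD events
#'
#' Over one family, sibling pair and parental side: PST-informative markers
#' define inter-marker gaps; a PST event occupies exactly one gap, and each
#' IBD event of either child is assigned to the gap(s) its interval
#' intersects. A gap agrees when PST presence equals odd parity of the IBD
#' events assigned to it. IBD events spanning several gaps (or lying outside
#' PST informative coverage) are reported as unresolved rather than
#' violations; two same-gap IBD events cancelling to even parity are the
#' expected PST miss and count as agreement.
#'
#' @param gt A [genotype_table()].
#' @param family Family unit with the relevant grandparents.
#' @param pair Character(2) sibling ids.
#' @param parent `"paternal"` or `"maternal"`.
#' @param min_run Switch-scan noise filter (1 for error-free data).
#' @return List with `gaps` (per-gap parity table), `n_violations`,
#'   `unresolved` (IBD events not assignable to a single gap), and the event
#'   tables used.
#' @export
union_equivalence_check <- function(gt, family, pair,
                                    parent = c("paternal", "maternal"),
                                    min_run = 1L) {
  parent <- match.arg(parent)
  code <- pst_code_pair(gt, family, pair, parent)
  pst_ev <- detect_switches(code, min_run = min_run)
  ibd_codes <- lapply(pair, function(ch) ibd_code_child(gt, family, ch, parent))
  ibd_ev <- do.call(rbind, lapply(ibd_codes, detect_switches, min_run = min_run))
  gaps_all <- list(); unresolved <- 0L
  for (ch in unique(code$markers$chrom)) {
    idx <- which(code$markers$chrom == ch)
    pos <- code$markers$pos[idx][code$code[idx] > 0L]
    if (length(pos) < 2L) next
    gl <- pos[-length(pos)]; gr <- pos[-1]
    n_pst <- integer(length(gl)); n_ibd <- integer(length(gl))
    # a gap is cross-checkable only when both of its boundary markers are
    # also IBD-informative for BOTH children: the two methods then bracket
    # any crossover inside the gap identically, so parities must agree.
    # Elsewhere the coarser coding can hide an even number of crossovers
    # (the expected-miss case) and the gap is left unresolved.
    ibd_pos <- lapply(ibd_codes, function(icode) {
      s <- icode$markers$chrom == ch
      icode$markers$pos[s][icode$code[s] > 0L]
    })
    on_both <- function(p) all(vapply(ibd_pos, function(q) p %in% q, logical(1)))
    bound_ok <- vapply(pos, on_both, logical(1))
    resolved <- bound_ok[-length(pos)] & bound_ok[-1]
    pe <- pst_ev[pst_ev$chrom == ch, , drop = FALSE]
    if (nrow(pe)) {
      gi <- match(pe$left_pos, gl)
      n_pst[gi[!is.na(gi)]] <- n_pst[gi[!is.na(gi)]] + 1L
    }
    ie <- ibd_ev[ibd_ev$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ie))) {
      touch <- which(pmax(gl, ie$left_pos[i]) < pmin(gr, ie$right_pos[i]))
      if (length(touch) == 1L) {
        n_ibd[touch] <- n_ibd[touch] + 1L
      } else {
        unresolved <- unresolved + 1L
        resolved[touch] <- FALSE
      }
    }
    gaps_all[[length(gaps_all) + 1L]] <- data.frame(
      chrom = ch, left = gl, right = gr, n_pst = n_pst, n_ibd = n_ibd,
      resolved = resolved,
      agree = !resolved | (n_ibd %% 2L) == n_pst, stringsAsFactors = FALSE)
  }
  gaps <- if (length(gaps_all)) do.call(rbind, gaps_all) else
    data.frame(chrom = character(0), left = integer(0), right = integer(0),
               n_pst = integer(0), n_ibd = integer(0), resolved = logical(0),
               agree = logical(0))
  list(gaps = gaps, n_violations = sum(!gaps$agree), unresolved = unresolved,
       pst_events = pst_ev, ibd_events = ibd_ev)
}
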