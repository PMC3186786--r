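# Parent-sibling tracing (PST): crossover calling from two-generation
# pedigrees with >= 2 siblings.
#
# A marker is informative for the paternal side when the father is
# heterozygous (AB) and the mother homozygous (AA/BB): each child's genotype
# then reveals which paternal allele it received. Over a sibling pair the
# marker is coded IDENTICAL (same genotype) or NOT_IDENTICAL; a state switch
# along the chromosome marks a crossover in one of the pair's two paternal
# meioses (odd-parity combination). The maternal side is symmetric.

PARENT_SIDES <- c("paternal", "maternal")

focal_parent_id <- function(family, parent) {
  if (parent == "paternal") family$father_id else family$mother_id
}
coparent_id <- function(family, parent) {
  if (parent == "paternal") family$mother_id else family$father_id
}

#' Per-marker PST informativeness for one family and parental side
#'
#' A marker is informative when the focal parent is heterozygous, the
#' co-parent homozygous, both are called, and no child of the family is
#' Mendelian-inconsistent with the parents at that marker.
#'
#' @param gt A [genotype_table()].
#' @param family A family unit (see [build_family_units()]).
#' @param parent `"paternal"` or `"maternal"`.
#' @return List with `informative` (logical per marker) and `reason`
#'   (character per marker: `OK`, `NOCALL`, `PARENT_HOM`, `COPARENT_HET`,
#'   `MENDEL_ERROR`).
#' @export
pst_informative_mask <- function(gt, family, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  fo <- gt$calls[focal_parent_id(family, parent), ]
  co <- gt$calls[coparent_id(family, parent), ]
  fa <- gt$calls[family$father_id, ]
  mo <- gt$calls[family$mother_id, ]
  mendel_bad <- rep(FALSE, length(fo))
  for (ch in family$siblings) {
    c_ <- gt$calls[ch, ]
    mendel_bad <- mendel_bad | !mendel_ok_table[cbind(fa + 1L, mo + 1L, c_ + 1L)]
  }
  reason <- rep("OK", length(fo))
  reason[mendel_bad] <- "MENDEL_ERROR"
  reason[co == GT_AB & !mendel_bad] <- "COPARENT_HET"
  reason[fo %in% c(GT_AA, GT_BB) & !mendel_bad] <- "PARENT_HOM"
  reason[fo == GT_NOCALL | co == GT_NOCALL] <- "NOCALL"
  informative <- fo == GT_AB & co %in% c(GT_AA, GT_BB) & !mendel_bad
  list(informative = unname(informative), reason = unname(reason))
}

#' PST identity coding over one sibling pair
#'
#' At each informative marker with both siblings called, codes IDENTICAL when
#' the two genotypes agree and NOT_IDENTICAL otherwise; uninformative
#' elsewhere. For the paternal side chrX is excluded (no paternal
#' recombination is assayed there).
#'
#' @param gt A [genotype_table()].
#' @param family A family unit containing both siblings.
#' @param pair Character(2): the two sibling ids.
#' @param parent `"paternal"` or `"maternal"`.
#' @return A [switch_code()] with states IDENTICAL/NOT_IDENTICAL.
#' @export
pst_code_pair <- function(gt, family, pair, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  stopifnot(length(pair) == 2)
  if (!all(pair %in% family$siblings))
    stop("pair (", paste(pair, collapse = ", "), ") are not full siblings of family ",
         family$id)
  mask <- pst_informative_mask(gt, family, parent)
  c1 <- gt$calls[pair[1], ]
  c2 <- gt$calls[pair[2], ]
  usable <- mask$informative & c1 != GT_NOCALL & c2 != GT_NOCALL
  code <- ifelse(usable, ifelse(c1 == c2, 1L, 2L), 0L)
  keep <- if (parent == "paternal") gt$markers$chrom != "chrX" else
    rep(TRUE, nrow(gt$markers))
  switch_code(code[keep], c("IDENTICAL", "NOT_IDENTICAL"),
              gt$markers[keep, , drop = FALSE],
              family = family$id, parent = parent,
              unit = paste(sort(pair), collapse = "+"))
}

#' Call PST crossover events for a whole dataset
#'
#' Runs the sibling-pair coding and switch scan over every PST-usable family
#' (>= 2 siblings) and both parental sides, then attributes events to
#' individual meioses where sibling parity permits (see
#' [attribute_events()]).
#'
#' @param gt A [genotype_table()].
#' @param families List of family units.
#' @param parent `"paternal"`, `"maternal"` or `"both"`.
#' @param min_run Noise filter for the switch scan (see [detect_switches()]).
#' @return List with `pair_events` (per sibling-pair events) and `events`
#'   (attributed events; `attribution` is a child id, a pair id for 2-sibling
#'   families, or `"UNATTRIBUTED"`).
#' @export
pst_call <- function(gt, families, parent = c("both", "paternal", "maternal"),
                     min_run = 3L) {
  parent <- match.arg(parent)
  sides <- if (parent == "both") PARENT_SIDES else parent
  usable <- Filter(function(f) isTRUE(f$pst_usable), families)
  if (!length(usable))
    stop("PST requires at least two genotyped siblings in at least one family")
  pair_events <- list(); attributed <- list()
  for (fu in usable) {
    pairs <- utils::combn(sort(fu$siblings), 2L, simplify = FALSE)
    for (side in sides) {
      ev <- list()
      for (pr in pairs) {
        code <- pst_code_pair(gt, fu, pr, side)
        ev[[length(ev) + 1L]] <- detect_switches(code, min_run = min_run)
      }
      ev <- do.call(rbind, ev)
      pair_events[[length(pair_events) + 1L]] <- ev
      attributed[[length(attributed) + 1L]] <- attribute_events(ev, fu, side)
    }
  }
  list(pair_events = do.call(rbind, pair_events),
       events = do.call(rbind, attributed))
}

#' Attribute pairwise PST events to individual meioses
#'
#' For families with >= 3 siblings, overlapping pairwise switch intervals are
#' clustered; a cluster is assigned to child c exactly when switches appear
#' in every pair containing c and in no pair excluding c (a pair switch
#' reflects the odd-parity combination of its two meioses). Clusters with any
#' other support pattern stay `UNATTRIBUTED`. For 2-sibling families events
#' are reported at pair level (the pair aggregates the parent's two meioses).
#'
#' @param pair_events Events data.frame from the pairwise switch scan for one
#'   family and one parental side.
#' @param family The family unit.
#' @param parent `"paternal"` or `"maternal"`.
#' @return data.frame with `family`, `parent`, `chrom`, `left_pos`,
#'   `right_pos`, `attribution`, `n_meioses` (1 for a child, 2 for a pair),
#'   `supporting_pairs`, `n_uninformative`, `region_bp`.
#' @export
attribute_events <- function(pair_events, family, parent) {
  empty <- data.frame(family = character(0), parent = character(0),
                      chrom = character(0), left_pos = integer(0),
                      right_pos = integer(0), attribution = character(0),
                      n_meioses = integer(0), supporting_pairs = character(0),
                      n_uninformative = integer(0), region_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(pair_events) || !nrow(pair_events)) return(empty)
  sibs <- sort(family$siblings)
  if (length(sibs) == 2L) {
    out <- pair_events[, c("family", "parent", "chrom", "left_pos", "right_pos")]
    out$attribution <- pair_events$unit
    out$n_meioses <- 2L
    out$supporting_pairs <- pair_events$unit
    out$n_uninformative <- pair_events$n_uninformative
    out$region_bp <- pair_events$region_bp
    rownames(out) <- NULL
    return(out)
  }
  pair_list <- utils::combn(sibs, 2L, simplify = FALSE)
  all_pairs <- vapply(pair_list, paste, "", collapse = "+")
  pairs_with <- lapply(sibs, function(s)
    all_pairs[vapply(pair_list, function(p) s %in% p, logical(1))])
  names(pairs_with) <- sibs
  out <- list()
  for (ch in unique(pair_events$chrom)) {
    ev <- pair_events[pair_events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$left_pos, ev$right_pos), , drop = FALSE]
    cl <- integer(nrow(ev)); cur <- 0L; maxr <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$left_pos[i] >= maxr) { cur <- cur + 1L; maxr <- ev$right_pos[i] }
      else maxr <- max(maxr, ev$right_pos[i])
      cl[i] <- cur
    }
    for (k in unique(cl)) {
      sub <- ev[cl == k, , drop = FALSE]
      support <- sort(unique(sub$unit))
      who <- sibs[vapply(sibs, function(s) setequal(support, pairs_with[[s]]),
                         logical(1))]
      attribution <- if (length(who) == 1L) who else "UNATTRIBUTED"
      l <- max(sub$left_pos); r <- min(sub$right_pos)
      if (l >= r) { l <- min(sub$left_pos); r <- max(sub$right_pos) }
      out[[length(out) + 1L]] <- data.frame(
        family = family$id, parent = parent, chrom = ch,
        left_pos = l, right_pos = r, attribution = attribution,
        n_meioses = 1L, supporting_pairs = paste(support, collapse = ","),
        n_uninformative = min(sub$n_uninformative), region_bp = r - l,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Per-meiosis crossover counts and sex-specific summaries
#'
#' Builds the full table of analysis units (each child meiosis for >= 3
#' sibling families, each sibling pair for 2-sibling families, per parental
#' side), including units with zero events, and summarizes per-meiosis rates
#' by parental sex. For pair units the per-meiosis rate is count/2 (a pair
#' switch aggregates the parent's two meioses).
#'
#' @param events Attributed events (see [pst_call()]); `UNATTRIBUTED` rows
#'   are excluded from per-unit counts but tallied.
#' @param families List of family units (defines the unit universe).
#' @return List with `units` (family, parent, unit, n_meioses, n_events,
#'   rate), `summary` (per parent_sex: n_meioses, mean, sd, median),
#'   `chrom_counts` (chrom, male, female, female_male_ratio) and
#'   `n_unattributed`.
#' @export
summarize_meioses <- function(events, families) {
  units <- list()
  for (fu in Filter(function(f) isTRUE(f$pst_usable), families)) {
    sibs <- sort(fu$siblings)
    us <- if (length(sibs) == 2L) paste(sibs, collapse = "+") else sibs
    nm <- if (length(sibs) == 2L) 2L else 1L
    for (side in PARENT_SIDES)
      units[[length(units) + 1L]] <- data.frame(
        family = fu$id, parent = side, unit = us, n_meioses = nm,
        stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, units)
  attributed <- events[events$attribution != "UNATTRIBUTED", , drop = FALSE]
  key <- function(f, p, u) paste(f, p, u, sep = "\r")
  cnt <- table(key(attributed$family, attributed$parent, attributed$attribution))
  units$n_events <- as.integer(cnt[key(units$family, units$parent, units$unit)])
  units$n_events[is.na(units$n_events)] <- 0L
  units$rate <- units$n_events / units$n_meioses
  sex_of <- c(paternal = "M", maternal = "F")
  units$parent_sex <- sex_of[units$parent]
  summ <- do.call(rbind, lapply(split(units, units$parent_sex), function(d)
    data.frame(parent_sex = d$parent_sex[1],
               n_meioses = sum(d$n_meioses),
               mean = sum(d$n_events) / sum(d$n_meioses),
               sd = stats::sd(d$rate),
               median = stats::median(d$rate))))
  rownames(summ) <- NULL
  chrom_counts <- NULL
  if (nrow(attributed)) {
    tab <- table(attributed$chrom, sex_of[attributed$parent])
    chrom_counts <- data.frame(chrom = rownames(tab),
                               male = if ("M" %in% colnames(tab)) as.integer(tab[, "M"]) else 0L,
                               female = if ("F" %in% colnames(tab)) as.integer(tab[, "F"]) else 0L,
                               stringsAsFactors = FALSE)
    chrom_counts$female_male_ratio <- chrom_counts$female / chrom_counts$male
    chrom_counts <- chrom_counts[order(chrom_rank(chrom_counts$chrom)), , drop = FALSE]
    rownames(chrom_counts) <- NULL
  }
  list(units = units[, c("family", "parent", "parent_sex", "unit", "n_meioses",
                         "n_events", "rate")],
       summary = summ, chrom_counts = chrom_counts,
       n_unattributed = sum(events$attribution == "UNATTRIBUTED"))
}
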