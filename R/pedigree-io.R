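# PED/MAP input, family assembly, QC filtering, and BED-like interval I/O.
#
# Input dialect: PLINK-style text PED (family, individual, father, mother,
# sex, phenotype-ignored, then one allele pair per marker) plus MAP (chrom,
# id, cM-ignored, bp). Allele letters are arbitrary; at each marker the
# lexicographically smaller observed allele becomes "A". "0" or "N" is a
# missing allele; a half-missing pair is treated as NOCALL.
#
# Coordinates: marker positions are 1-based (map convention); all BED output
# is 0-based half-open.

PED_MISSING <- c("0", "N")

#' Read pedigree genotypes from PED/MAP files
#'
#' @param ped_path Path to a PLINK-style PED text file.
#' @param map_path Path to the matching MAP file (chrom, id, cM, bp).
#' @return A list with `genotypes` (a [genotype_table()], markers sorted by
#'   chromosome and position) and `families` (list of family units, see
#'   [build_family_units()]).
#' @export
read_pedigree_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric", "integer"))
  ord <- order(chrom_rank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  n <- length(lines)
  if (n == 0L) stop("PED file is empty: ", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt != 6L + 2L * m)
  if (length(bad))
    stop("PED line ", bad[1], ": expected ", 6L + 2L * m, " fields (6 + 2 alleles x ",
         m, " markers), found ", nt[bad[1]])
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)

  samples <- data.frame(id = tok[, 2],
                        family_id = tok[, 1],
                        father_id = ifelse(tok[, 3] %in% c("0", ""), NA_character_, tok[, 3]),
                        mother_id = ifelse(tok[, 4] %in% c("0", ""), NA_character_, tok[, 4]),
                        sex = c("U", "M", "F")[match(tok[, 5], c("0", "1", "2"), nomatch = 1L)],
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$id))
    stop("duplicate individual ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))

  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  # PED allele columns follow the original MAP row order; reorder to sorted map
  a1 <- a1[, ord, drop = FALSE]
  a2 <- a2[, ord, drop = FALSE]
  calls <- matrix(GT_NOCALL, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 %in% PED_MISSING | x2 %in% PED_MISSING
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) > 2L)
      stop("marker ", map$id[j], ": more than two alleles observed (",
           paste(alleles, collapse = ","), ")")
    if (length(alleles) == 0L) next
    A <- alleles[1]
    B <- if (length(alleles) == 2L) alleles[2] else NA_character_
    okA1 <- x1 == A
    okB1 <- !is.na(B) & x1 == B
    okA2 <- x2 == A
    okB2 <- !is.na(B) & x2 == B
    unparseable <- !miss & !(okA1 | okB1) | !miss & !(okA2 | okB2)
    if (any(unparseable))
      stop("PED line ", which(unparseable)[1], ", marker ", map$id[j],
           ": genotype token not parseable")
    d <- ifelse(okB1, 1L, 0L) + ifelse(okB2, 1L, 0L)  # B-allele dosage
    calls[, j] <- ifelse(miss, GT_NOCALL, d + 1L)     # 0->AA,1->AB,2->BB
  }

  markers <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                        stringsAsFactors = FALSE)
  gt <- genotype_table(markers, samples, calls)
  check_pedigree_acyclic(samples)
  fams <- build_family_units(samples)
  list(genotypes = gt, families = fams)
}

# natural chromosome ordering: chr1..chr22, then chrX, chrY, then others
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  num[core == "X"] <- 23
  num[core == "Y"] <- 24
  num[is.na(num)] <- 25 + match(core[is.na(num)], sort(unique(core[is.na(num)])))
  num
}

check_pedigree_acyclic <- function(samples) {
  idx <- stats::setNames(seq_len(nrow(samples)), samples$id)
  for (i in seq_len(nrow(samples))) {
    seen <- character(0)
    frontier <- stats::na.omit(c(samples$father_id[i], samples$mother_id[i]))
    while (length(frontier)) {
      if (samples$id[i] %in% frontier)
        stop("individual ", samples$id[i], " is its own ancestor")
      seen <- union(seen, frontier)
      up <- idx[frontier]
      up <- up[!is.na(up)]
      frontier <- setdiff(stats::na.omit(c(samples$father_id[up], samples$mother_id[up])), seen)
    }
  }
  invisible(TRUE)
}

#' Assemble family units from a sample sheet
#'
#' A family unit is one father/mother couple plus all their common children
#' present in the table. Children whose father or mother is absent from the
#' table do not enter any unit. Grandparent pairs are attached when both
#' parents of the father (paternal side) or of the mother (maternal side) are
#' present. PST requires at least two siblings; units with fewer are retained
#' (flagged `pst_usable = FALSE`) for other uses.
#'
#' @param samples data.frame with columns `id`, `family_id`, `father_id`,
#'   `mother_id`, `sex`.
#' @return A named list of `family_unit` objects.
#' @export
build_family_units <- function(samples) {
  present <- samples$id
  kid <- !is.na(samples$father_id) & !is.na(samples$mother_id) &
    samples$father_id %in% present & samples$mother_id %in% present
  if (!any(kid)) return(list())
  couples <- unique(samples[kid, c("family_id", "father_id", "mother_id")])
  fams <- list()
  for (k in seq_len(nrow(couples))) {
    fa <- couples$father_id[k]; mo <- couples$mother_id[k]
    fsex <- samples$sex[samples$id == fa]
    msex <- samples$sex[samples$id == mo]
    if (fsex == "F") stop("father ", fa, " has sex F")
    if (msex == "M") stop("mother ", mo, " has sex M")
    sibs <- samples$id[kid & samples$father_id == fa & samples$mother_id == mo]
    gp <- function(parent) {
      i <- match(parent, samples$id)
      g <- c(samples$father_id[i], samples$mother_id[i])
      if (anyNA(g) || !all(g %in% present)) NULL else g
    }
    fu <- structure(list(id = paste0(couples$family_id[k], ":", fa, "+", mo),
                         family_id = couples$family_id[k],
                         father_id = fa, mother_id = mo,
                         siblings = sibs,
                         pat_grandparents = gp(fa),
                         mat_grandparents = gp(mo),
                         pst_usable = length(sibs) >= 2L),
                    class = "family_unit")
    fams[[fu$id]] <- fu
  }
  short <- vapply(fams, function(f) !f$pst_usable, logical(1))
  if (any(short))
    warning(sum(short), " family unit(s) with < 2 siblings are unusable for PST: ",
            paste(names(fams)[short], collapse = ", "))
  fams
}

#' @export
print.family_unit <- function(x, ...) {
  cat("family_unit", x$id, "-", length(x$siblings), "sibling(s)",
      if (!is.null(x$pat_grandparents)) "| paternal grandparents" else "",
      if (!is.null(x$mat_grandparents)) "| maternal grandparents" else "", "\n")
  invisible(x)
}

#' Quality-control filter on samples and families
#'
#' Removes samples whose genotype call rate is strictly below
#' `min_call_rate` (boundary samples are retained), then removes individuals
#' that belong to no family unit, and re-validates families (PST needs >= 2
#' remaining siblings). The filter is idempotent.
#'
#' @param gt A [genotype_table()].
#' @param families Optional list of family units (rebuilt after filtering
#'   either way; accepted for interface symmetry).
#' @param min_call_rate Exclusion threshold on the per-sample call rate
#'   (default 0.90; exclusion is strict `<`).
#' @return List with `genotypes`, `families`, and `report` (data.frame:
#'   sample_id, call_rate, excluded_reason; empty reason = retained).
#' @export
qc_filter <- function(gt, families = NULL, min_call_rate = 0.90) {
  stopifnot(inherits(gt, "genotype_table"))
  cr <- call_rates(gt)
  reason <- rep("", nrow(gt$samples))
  reason[cr < min_call_rate] <- "low_call_rate"
  keep <- gt$samples$id[reason == ""]
  sub <- gt$samples[gt$samples$id %in% keep, , drop = FALSE]
  fams <- suppressWarnings(build_family_units(sub))
  linked <- unique(unlist(lapply(fams, function(f)
    c(f$father_id, f$mother_id, f$siblings, f$pat_grandparents, f$mat_grandparents))))
  reason[reason == "" & !(gt$samples$id %in% linked)] <- "no_pedigree_links"
  report <- data.frame(sample_id = gt$samples$id, call_rate = unname(cr),
                       excluded_reason = reason, stringsAsFactors = FALSE)
  kept <- gt$samples$id[reason == ""]
  if (!length(fams)) stop("no analyzable families after QC")
  out <- subset_genotypes(gt, samples = kept)
  fams <- suppressWarnings(build_family_units(out$samples))
  list(genotypes = out, families = fams, report = report)
}

#' Write pedigree genotypes as PED/MAP
#'
#' Inverse of [read_pedigree_genotypes()]: alleles written as A/B letters,
#' missing calls as "0 0", sex as 1/2/0.
#'
#' @param gt A [genotype_table()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pedigree_genotypes <- function(gt, ped_path, map_path) {
  stopifnot(inherits(gt, "genotype_table"))
  map <- data.frame(gt$markers$chrom, gt$markers$id, 0, gt$markers$pos)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pair <- c("0 0", "A A", "A B", "B B")[gt$calls + 1L]
  dim(pair) <- dim(gt$calls)
  sexcode <- c(M = "1", F = "2", U = "0")[gt$samples$sex]
  lead <- paste(gt$samples$family_id, gt$samples$id,
                ifelse(is.na(gt$samples$father_id), "0", gt$samples$father_id),
                ifelse(is.na(gt$samples$mother_id), "0", gt$samples$mother_id),
                sexcode, "0")
  body <- apply(pair, 1L, paste, collapse = " ")
  writeLines(paste(lead, body), ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a BED-like annotation file
#'
#' Expects 0-based half-open intervals with columns chrom, start, end, and
#' optionally a class label (4th) and a length attribute in bp (5th; used for
#' tandem repeats).
#'
#' @param path Path to the annotation file (`#` comment lines ignored).
#' @return data.frame with columns `chrom`, `start`, `end`, `class`,
#'   `length` (NA when absent).
#' @export
read_annotation_bed <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      class = character(0), length = numeric(0), stringsAsFactors = FALSE))
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 3L)) stop("annotation line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(toks, `[`, "", 1L)
  start <- as.integer(vapply(toks, `[`, "", 2L))
  end <- as.integer(vapply(toks, `[`, "", 3L))
  if (anyNA(start) || anyNA(end))
    stop("annotation line ", which(is.na(start) | is.na(end))[1], ": non-numeric interval")
  bad <- which(end <= start)
  if (length(bad)) stop("annotation line ", bad[1], ": end <= start")
  cls <- ifelse(nf >= 4L, vapply(toks, function(t) if (length(t) >= 4L) t[4] else "", ""), "feature")
  cls[cls == ""] <- "feature"
  len <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  len[has5] <- suppressWarnings(as.numeric(vapply(toks[has5], `[`, "", 5L)))
  data.frame(chrom = chrom, start = start, end = end, class = cls, length = len,
             stringsAsFactors = FALSE)
}

#' Read crossover events from a BED6 file written by [write_events_bed()]
#'
#' @param path Path to the events BED file.
#' @return Events data.frame (`family`, `parent`, `unit`, `chrom`,
#'   `left_pos`, `right_pos`, `n_uninformative`, `region_bp`).
#' @export
read_events_bed <- function(path) {
  iv <- read_annotation_bed(path)  # chrom/start/end/class(=name)/length(=score)
  if (!nrow(iv))
    return(empty_events()[, c("family", "parent", "unit", "chrom", "left_pos",
                              "right_pos", "n_uninformative", "region_bp")])
  name <- strsplit(iv$class, "|", fixed = TRUE)
  bad <- lengths(name) != 3L
  if (any(bad)) stop("events line ", which(bad)[1],
                     ": name field is not family|unit|parent")
  data.frame(family = vapply(name, `[`, "", 1L),
             parent = vapply(name, `[`, "", 3L),
             unit = vapply(name, `[`, "", 2L),
             chrom = iv$chrom,
             left_pos = iv$start + 1L, right_pos = iv$end,
             n_uninformative = as.integer(iv$length),
             region_bp = iv$end - (iv$start + 1L),
             stringsAsFactors = FALSE)
}

#' Write crossover events as BED6
#'
#' One line per event, 0-based half-open over the uninformative region
#' (`left_pos - 1` to `right_pos`). The name field encodes
#' family|unit|parent-of-origin; the score field is the uninformative SNP
#' count; strand is ".".
#'
#' @param events Events data.frame as returned by [detect_switches()] /
#'   [pst_call()] / [ibd_call()].
#' @param path Output path.
#' @param header Optional extra header comment lines (without leading `#`).
#' @return Invisibly, `path`.
#' @export
write_events_bed <- function(events, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pstrace ", as.character(utils::packageVersion("pstrace")),
                      " crossover events (BED6; score = uninformative SNP count)"),
               paste0("# ", header)[length(header) > 0]), con)
  if (!is.null(events) && nrow(events)) {
    rk <- chrom_rank(events$chrom)
    if (anyNA(rk)) {
      warning("unsortable chromosome names; writing events in input order")
    } else {
      events <- events[order(rk, events$left_pos), , drop = FALSE]
    }
    writeLines(paste(events$chrom, events$left_pos - 1L, events$right_pos,
                     paste(events$family, events$unit, events$parent, sep = "|"),
                     events$n_uninformative, ".", sep = "\t"), con)
  }
  invisible(path)
}
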