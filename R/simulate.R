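# Pedigree-genotype simulator with known truth crossovers.
#
# Generative model: founder haplotypes are drawn marker-by-marker with
# B-allele frequency ~ Uniform(maf_range); each meiosis draws
# K ~ Poisson(sex-specific map length in Morgans) crossover positions
# uniformly on the chromosome (no interference) and forms the gamete by
# alternating parental haplotype segments from a random starting phase.
# Genotyping noise: with probability genotype_error_rate a call is replaced
# by a uniformly chosen different call; NOCALLs are applied independently.
# chrX is modelled as a diploid chromosome whose male map length is 0, so
# only maternal meioses recombine there (the callers skip paternal chrX).

# hg-style chromosome lengths (bp), chr1..chr22 (+ chrX on request)
HS_CHROM_MB <- c(chr1 = 247, chr2 = 243, chr3 = 199, chr4 = 191, chr5 = 181,
                 chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 140, chr10 = 135,
                 chr11 = 134, chr12 = 132, chr13 = 114, chr14 = 106, chr15 = 100,
                 chr16 = 89, chr17 = 79, chr18 = 76, chr19 = 64, chr20 = 62,
                 chr21 = 47, chr22 = 50, chrX = 155)

#' Human-like chromosome lengths
#'
#' @param n_autosomes Number of autosomes to include (1..22), largest first.
#' @param include_x Also include chrX.
#' @return Named numeric vector of lengths in bp.
#' @export
default_chrom_lengths <- function(n_autosomes = 22, include_x = FALSE) {
  stopifnot(n_autosomes >= 1, n_autosomes <= 22)
  len <- HS_CHROM_MB[seq_len(n_autosomes)]
  if (include_x) len <- c(len, HS_CHROM_MB["chrX"])
  len * 1e6
}

#' Sex-specific genetic map lengths proportional to physical length
#'
#' Distributes genome-wide expected crossover counts (Morgans; 23.8 male and
#' 39.5 female by default, the sex asymmetry of human meiosis) over the
#' supplied chromosomes proportionally to physical length. chrX gets male map
#' length 0.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param male_total,female_total Genome totals in Morgans.
#' @return List with named numeric vectors `male` and `female` (Morgans).
#' @export
default_sex_map_lengths <- function(chrom_lengths, male_total = 23.8,
                                    female_total = 39.5) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  auto <- names(chrom_lengths)[names(chrom_lengths) != "chrX"]
  male <- stats::setNames(rep(0, length(chrom_lengths)), names(chrom_lengths))
  male[auto] <- male_total * chrom_lengths[auto] / sum(chrom_lengths[auto])
  female <- female_total * chrom_lengths / sum(chrom_lengths)
  list(male = male, female = female)
}

#' Simulation configuration
#'
#' @param n_families Number of nuclear families.
#' @param sibs_per_family Siblings per family (>= 2 for PST).
#' @param include_grandparents Simulate both grandparent couples (required
#'   for the IBD comparator).
#' @param chrom_lengths Named vector, chromosome lengths in bp.
#' @param sex_map_lengths List with named vectors `male` and `female` of
#'   per-chromosome map lengths in Morgans; default proportional maps with
#'   genome totals 23.8 (male) and 39.5 (female).
#' @param n_markers_per_chrom SNP markers per chromosome.
#' @param maf_range Range of the per-marker B-allele frequency (drawn
#'   uniformly; upper bound <= 0.5).
#' @param genotype_error_rate Probability a call is replaced by a uniformly
#'   chosen different call.
#' @param nocall_rate Probability a call is missing (applied independently).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 10, sibs_per_family = 2,
                       include_grandparents = FALSE,
                       chrom_lengths = default_chrom_lengths(),
                       sex_map_lengths = default_sex_map_lengths(chrom_lengths),
                       n_markers_per_chrom = 400,
                       maf_range = c(0.2, 0.5),
                       genotype_error_rate = 0.005,
                       nocall_rate = 0.02,
                       seed = 1L) {
  stopifnot(n_families >= 1, sibs_per_family >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            nocall_rate >= 0, nocall_rate <= 1,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  for (s in c("male", "female")) {
    stopifnot(all(names(chrom_lengths) %in% names(sex_map_lengths[[s]])),
              all(sex_map_lengths[[s]] >= 0))
  }
  if ("chrX" %in% names(chrom_lengths)) sex_map_lengths$male["chrX"] <- 0
  if (n_markers_per_chrom < 1 &&
      any(sex_map_lengths$male > 0 | sex_map_lengths$female > 0))
    stop("zero markers on a chromosome with positive map length")
  structure(list(n_families = as.integer(n_families),
                 sibs_per_family = as.integer(sibs_per_family),
                 include_grandparents = isTRUE(include_grandparents),
                 chrom_lengths = chrom_lengths,
                 sex_map_lengths = sex_map_lengths,
                 n_markers_per_chrom = as.integer(n_markers_per_chrom),
                 maf_range = maf_range,
                 genotype_error_rate = genotype_error_rate,
                 nocall_rate = nocall_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pedigree SNP dataset with known crossovers
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a [genotype_table()]), `families` (family
#'   units), `truth` (data.frame of true crossovers: chrom, pos, family,
#'   parent_id, child_id, parent_sex), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  m_per <- cfg$n_markers_per_chrom
  n_chrom <- length(chroms)
  m_total <- m_per * n_chrom

  marker_pos <- integer(0); marker_chrom <- character(0)
  slice <- vector("list", n_chrom); names(slice) <- chroms
  for (ci in seq_len(n_chrom)) {
    L <- cfg$chrom_lengths[ci]
    if (m_per > L) stop("more markers than bp on ", chroms[ci])
    pos <- sort(sample.int(as.integer(L), m_per))
    slice[[ci]] <- seq.int((ci - 1L) * m_per + 1L, ci * m_per)
    marker_pos <- c(marker_pos, pos)
    marker_chrom <- c(marker_chrom, rep(chroms[ci], m_per))
  }
  markers <- data.frame(id = sprintf("snp%05d", seq_len(m_total)),
                        chrom = marker_chrom, pos = marker_pos,
                        stringsAsFactors = FALSE)
  freq_b <- stats::runif(m_total, cfg$maf_range[1], cfg$maf_range[2])

  founder_haps <- function()
    matrix(stats::rbinom(2L * m_total, 1L, rep(freq_b, each = 2L)),
           nrow = 2L, ncol = m_total)

  # one meiosis: gamete vector + the crossover breakpoints it used
  meiosis <- function(haps, parent_sex) {
    gam <- integer(m_total)
    br_chrom <- character(0); br_pos <- numeric(0)
    map <- cfg$sex_map_lengths[[if (parent_sex == "M") "male" else "female"]]
    for (ci in seq_len(n_chrom)) {
      idx <- slice[[ci]]
      k <- stats::rpois(1L, map[chroms[ci]])
      breaks <- if (k > 0L) sort(stats::runif(k, 0, cfg$chrom_lengths[ci])) else numeric(0)
      phase <- (stats::rbinom(1L, 1L, 0.5) + findInterval(marker_pos[idx], breaks)) %% 2L
      g <- haps[1L, idx]
      w <- phase == 1L
      if (any(w)) g[w] <- haps[2L, idx][w]
      gam[idx] <- g
      if (k > 0L) {
        br_chrom <- c(br_chrom, rep(chroms[ci], k))
        br_pos <- c(br_pos, breaks)
      }
    }
    list(gam = gam, chrom = br_chrom, pos = br_pos)
  }

  roles_per_fam <- cfg$sibs_per_family + 2L + if (cfg$include_grandparents) 4L else 0L
  n_ind <- cfg$n_families * roles_per_fam
  dosage <- matrix(0L, nrow = n_ind, ncol = m_total)
  ids <- character(n_ind); fam_ids <- character(n_ind)
  fathers <- rep(NA_character_, n_ind); mothers <- rep(NA_character_, n_ind)
  sexes <- character(n_ind)
  truth_list <- list()
  row <- 0L

  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("fam%03d", f)
    nm <- function(role) paste0(fam, "_", role)
    note_truth <- function(mei, parent_id, child_id, parent_sex) {
      if (length(mei$pos))
        truth_list[[length(truth_list) + 1L]] <<- data.frame(
          chrom = mei$chrom, pos = mei$pos, family = fam,
          parent_id = parent_id, child_id = child_id,
          parent_sex = parent_sex, stringsAsFactors = FALSE)
    }
    new_row <- function(id, fa, mo, sex) {
      row <<- row + 1L
      ids[row] <<- id; fam_ids[row] <<- fam
      fathers[row] <<- fa; mothers[row] <<- mo; sexes[row] <<- sex
      row
    }
    if (cfg$include_grandparents) {
      gp <- list(pgf = founder_haps(), pgm = founder_haps(),
                 mgf = founder_haps(), mgm = founder_haps())
      for (g in names(gp))
        dosage[new_row(nm(g), NA, NA, if (grepl("f$", g)) "M" else "F"), ] <-
          gp[[g]][1L, ] + gp[[g]][2L, ]
      m1 <- meiosis(gp$pgf, "M"); m2 <- meiosis(gp$pgm, "F")
      note_truth(m1, nm("pgf"), nm("fa"), "M"); note_truth(m2, nm("pgm"), nm("fa"), "F")
      fa_haps <- rbind(m1$gam, m2$gam)
      m3 <- meiosis(gp$mgf, "M"); m4 <- meiosis(gp$mgm, "F")
      note_truth(m3, nm("mgf"), nm("mo"), "M"); note_truth(m4, nm("mgm"), nm("mo"), "F")
      mo_haps <- rbind(m3$gam, m4$gam)
      dosage[new_row(nm("fa"), nm("pgf"), nm("pgm"), "M"), ] <- fa_haps[1L, ] + fa_haps[2L, ]
      dosage[new_row(nm("mo"), nm("mgf"), nm("mgm"), "F"), ] <- mo_haps[1L, ] + mo_haps[2L, ]
    } else {
      fa_haps <- founder_haps(); mo_haps <- founder_haps()
      dosage[new_row(nm("fa"), NA, NA, "M"), ] <- fa_haps[1L, ] + fa_haps[2L, ]
      dosage[new_row(nm("mo"), NA, NA, "F"), ] <- mo_haps[1L, ] + mo_haps[2L, ]
    }
    for (s in seq_len(cfg$sibs_per_family)) {
      cid <- nm(paste0("c", s))
      mp <- meiosis(fa_haps, "M"); mm <- meiosis(mo_haps, "F")
      note_truth(mp, nm("fa"), cid, "M"); note_truth(mm, nm("mo"), cid, "F")
      dosage[new_row(cid, nm("fa"), nm("mo"),
                     if (stats::rbinom(1L, 1L, 0.5) == 1L) "M" else "F"), ] <-
        mp$gam + mm$gam
    }
  }

  calls <- dosage + 1L  # dosage 0/1/2 -> AA/AB/BB codes
  if (cfg$genotype_error_rate > 0) {
    hit <- which(stats::runif(length(calls)) < cfg$genotype_error_rate)
    if (length(hit)) {
      shift <- sample.int(2L, length(hit), replace = TRUE)  # 1 or 2 steps around {1,2,3}
      calls[hit] <- (calls[hit] - 1L + shift) %% 3L + 1L
    }
  }
  if (cfg$nocall_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$nocall_rate] <- GT_NOCALL
  }

  samples <- data.frame(id = ids, family_id = fam_ids, father_id = fathers,
                        mother_id = mothers, sex = sexes, stringsAsFactors = FALSE)
  gt <- genotype_table(markers, samples, calls)
  truth <- if (length(truth_list)) do.call(rbind, truth_list) else
    data.frame(chrom = character(0), pos = numeric(0), family = character(0),
               parent_id = character(0), child_id = character(0),
               parent_sex = character(0), stringsAsFactors = FALSE)
  list(genotypes = gt,
       families = suppressWarnings(build_family_units(samples)),
       truth = truth, config = cfg)
}

# allowed child dosage sets given parent genotype codes (0..3); NOCALL -> any
mendel_ok_table <- local({
  alleles <- list(`0` = 0:1, `1` = 0L, `2` = 0:1, `3` = 1L)  # by code
  ok <- array(TRUE, dim = c(4, 4, 4))
  for (f in 0:3) for (m in 0:3) for (c in 0:3) {
    if (f == 0L || m == 0L || c == 0L) next  # NOCALL never inconsistent
    possible <- unique(outer(alleles[[f + 1L]], alleles[[m + 1L]], `+`))
    ok[f + 1L, m + 1L, c + 1L] <- (c - 1L) %in% possible  # child dosage = code-1
  }
  ok
})

#' Audit Mendelian consistency of child genotypes
#'
#' Flags (family, marker, child) combinations where the child call is
#' impossible given the two parental calls; NOCALL anywhere is never flagged.
#'
#' @param gt A [genotype_table()].
#' @param families List of family units.
#' @return data.frame with columns `family`, `marker`, `chrom`, `pos`,
#'   `child_id` (zero rows when fully consistent).
#' @export
mendelian_audit <- function(gt, families) {
  stopifnot(inherits(gt, "genotype_table"))
  out <- list()
  for (fu in families) {
    f <- gt$calls[fu$father_id, ]
    m <- gt$calls[fu$mother_id, ]
    for (ch in fu$siblings) {
      c_ <- gt$calls[ch, ]
      bad <- which(!mendel_ok_table[cbind(f + 1L, m + 1L, c_ + 1L)])
      if (length(bad))
        out[[length(out) + 1L]] <- data.frame(
          family = fu$id, marker = gt$markers$id[bad],
          chrom = gt$markers$chrom[bad], pos = gt$markers$pos[bad],
          child_id = ch, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), marker = character(0),
                      chrom = character(0), pos = integer(0),
                      child_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Plant an annotation track coupled to per-bin crossover counts
#'
#' Generates point-like annotation intervals whose per-bin counts follow
#' Poisson(base_rate + direction * effect * bin count), for testing the
#' annotation-correlation machinery with a known planted signal.
#'
#' @param bins A bin table (see [bin_events()]).
#' @param counts Per-bin numeric vector coupled to the annotation rate
#'   (e.g. `bins$both`).
#' @param base_rate Baseline expected features per bin.
#' @param effect Coupling strength (features per crossover count unit).
#' @param direction +1 (positive coupling) or -1 (negative).
#' @param class Class label for the generated intervals.
#' @return Annotation data.frame as from [read_annotation_bed()].
#' @export
simulate_annotation_track <- function(bins, counts, base_rate = 20, effect = 0.7,
                                      direction = 1, class = "planted") {
  stopifnot(nrow(bins) == length(counts), direction %in% c(-1, 1))
  lam <- pmax(0.05, base_rate + direction * effect * counts)
  n <- stats::rpois(nrow(bins), lam)
  n[!bins$covered] <- 0L
  idx <- rep(seq_len(nrow(bins)), n)
  if (!length(idx))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      class = character(0), length = numeric(0), stringsAsFactors = FALSE))
  mid <- floor(stats::runif(length(idx), bins$start[idx], bins$end[idx] - 1))
  data.frame(chrom = bins$chrom[idx], start = as.integer(mid),
             end = as.integer(mid + 1L), class = class, length = NA_real_,
             stringsAsFactors = FALSE)
}
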