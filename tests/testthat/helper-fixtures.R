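# Fixture builders shared across the suite. All data are generated in code.

# genotype codes, for readable fixtures
AA <- 1L; AB <- 2L; BB <- 3L; NC <- 0L

# A minimal genotype table: one chromosome, given calls per individual.
# `calls` is a named list id -> integer vector; pedigree columns supplied in
# `samples`.
toy_gt <- function(calls, samples, chrom = "chr1",
                   pos = seq_len(length(calls[[1]])) * 1e6) {
  m <- length(calls[[1]])
  markers <- data.frame(id = sprintf("m%02d", seq_len(m)), chrom = chrom, pos = pos)
  mat <- do.call(rbind, calls)
  rownames(mat) <- names(calls)
  genotype_table(markers, samples, mat[samples$id, , drop = FALSE])
}

std_samples <- function(ids, fam = "f1", fa = "fa", mo = "mo",
                        with_gp = FALSE) {
  kids <- setdiff(ids, c("fa", "mo", "pgf", "pgm", "mgf", "mgm"))
  df <- data.frame(id = ids, family_id = fam,
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "U", stringsAsFactors = FALSE)
  df$sex[df$id == "fa"] <- "M"; df$sex[df$id == "mo"] <- "F"
  df$father_id[df$id %in% kids] <- fa
  df$mother_id[df$id %in% kids] <- mo
  if (with_gp) {
    df$sex[df$id %in% c("pgf", "mgf")] <- "M"
    df$sex[df$id %in% c("pgm", "mgm")] <- "F"
    df$father_id[df$id == "fa"] <- "pgf"; df$mother_id[df$id == "fa"] <- "pgm"
    df$father_id[df$id == "mo"] <- "mgf"; df$mother_id[df$id == "mo"] <- "mgm"
  }
  df
}

# Three-generation toy family on one chromosome where every marker is both
# PST- and IBD-informative for the paternal side: father AB phased
# GF-hap = A, GM-hap = B; GF = AA, GM = BB; mother and her parents AA.
# Children receive a paternal gamete defined by crossover breakpoints
# (phase 0 = GF hap = A) and a maternal A allele.
toy_three_gen <- function(n_markers, breaks_by_child, pos = seq_len(n_markers) * 1e6) {
  gamete <- function(breaks) {
    phase <- findInterval(pos, sort(breaks)) %% 2L
    phase  # allele: 0 = A (GF), 1 = B (GM)
  }
  kids <- names(breaks_by_child)
  calls <- c(list(pgf = rep(AA, n_markers), pgm = rep(BB, n_markers),
                  mgf = rep(AA, n_markers), mgm = rep(AA, n_markers),
                  fa = rep(AB, n_markers), mo = rep(AA, n_markers)),
             lapply(breaks_by_child, function(b) gamete(b) + 1L))  # A+A=AA, B+A=AB
  samples <- std_samples(c("pgf", "pgm", "mgf", "mgm", "fa", "mo", kids),
                         with_gp = TRUE)
  gt <- toy_gt(calls, samples, pos = pos)
  fams <- suppressWarnings(build_family_units(samples))
  list(gt = gt, family = fams[["f1:fa+mo"]], families = fams)
}

# small error-free three-generation simulation used by several tests
small_sim <- function(n_families = 5, sibs = 2, seed = 42, n_chrom = 3,
                      markers = 300, gp = TRUE, error = 0, nocall = 0) {
  cl <- default_chrom_lengths(n_chrom)
  cfg <- sim_config(n_families = n_families, sibs_per_family = sibs,
                    include_grandparents = gp, chrom_lengths = cl,
                    n_markers_per_chrom = markers,
                    genotype_error_rate = error, nocall_rate = nocall,
                    seed = seed)
  simulate_dataset(cfg)
}

main_families <- function(sim) Filter(function(f) length(f$siblings) >= 2, sim$families)

# Expected events by truth parity: for each chromosome, gaps between
# consecutive informative markers of `code`; a gap with an odd number of
# truth crossovers must carry exactly one event. Returns "chrom:left:right"
# keys.
expected_gap_events <- function(code_obj, truth) {
  tpb <- split(truth$pos, truth$chrom)
  out <- character(0)
  for (ch in unique(code_obj$markers$chrom)) {
    sel <- code_obj$markers$chrom == ch
    pos <- code_obj$markers$pos[sel][code_obj$code[sel] > 0L]
    if (length(pos) < 2L) next
    tp <- tpb[[ch]]
    cnt <- if (length(tp)) tabulate(findInterval(tp, pos), nbins = length(pos))
           else integer(length(pos))
    gaps <- which(cnt[seq_len(length(pos) - 1L)] %% 2L == 1L)
    if (length(gaps))
      out <- c(out, paste(ch, pos[gaps], pos[gaps + 1L], sep = ":"))
  }
  out
}

event_keys <- function(events) {
  if (is.null(events) || !nrow(events)) return(character(0))
  paste(events$chrom, events$left_pos, events$right_pos, sep = ":")
}

# hand-built PST pair event row
pair_ev <- function(unit, l, r, chrom = "chr1") {
  data.frame(family = "f1:fa+mo", parent = "paternal", unit = unit, chrom = chrom,
             left_pos = l, right_pos = r, left_marker = "x", right_marker = "y",
             from_state = "IDENTICAL", to_state = "NOT_IDENTICAL",
             n_uninformative = 1L, region_bp = r - l, stringsAsFactors = FALSE)
}

truth_of <- function(sim, parent_id, children) {
  sim$truth[sim$truth$parent_id == parent_id & sim$truth$child_id %in% children, ]
}
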