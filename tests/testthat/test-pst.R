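test_that("informative mask follows the het-father/hom-mother rule with reasons", {
  gt <- toy_gt(list(fa = c(AB, AB, AA, AB, NC),
                    mo = c(AA, AB, AA, BB, AA),
                    c1 = c(AB, AA, AB, AB, AA),
                    c2 = c(AA, AA, AA, BB, AA)),
               std_samples(c("fa", "mo", "c1", "c2")))
  fam <- build_family_units(gt$samples)[[1]]
  pat <- pst_informative_mask(gt, fam, "paternal")
  mat <- pst_informative_mask(gt, fam, "maternal")
  expect_equal(pat$informative, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(pat$reason, c("OK", "COPARENT_HET", "MENDEL_ERROR", "OK", "NOCALL"))
  # maternal side: marker 1 has hom mother -> PARENT_HOM; marker 3 is a
  # family-level Mendelian error (AA x AA -> AB) and is masked for both sides
  expect_equal(mat$informative, c(FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(mat$reason, c("PARENT_HOM", "COPARENT_HET", "MENDEL_ERROR",
                             "PARENT_HOM", "NOCALL"))
})

test_that("sibling-pair coding matches the identity schema", {
  gt <- toy_gt(list(fa = c(AB, AB, AB, AB),
                    mo = c(AA, AA, AA, AB),
                    c1 = c(AB, AB, NC, AB),
                    c2 = c(AA, AB, AA, AB)),
               std_samples(c("fa", "mo", "c1", "c2")))
  fam <- build_family_units(gt$samples)[[1]]
  code <- pst_code_pair(gt, fam, c("c1", "c2"), "paternal")
  # Aa vs AA -> not identical; Aa vs Aa -> identical; missing child -> U;
  # het mother -> U
  expect_equal(code$code, c(2L, 1L, 0L, 0L))
  # symmetry
  rev_ <- pst_code_pair(gt, fam, c("c2", "c1"), "paternal")
  expect_identical(code$code, rev_$code)
  expect_identical(code$unit, rev_$unit)
  # non-siblings are rejected
  expect_error(pst_code_pair(gt, fam, c("c1", "mo"), "paternal"),
               "not full siblings")
})

test_that("coding is invariant to swapping allele labels at any marker", {
  sim <- small_sim(n_families = 3, seed = 17, markers = 120, gp = TRUE,
                   error = 0.01, nocall = 0.02)
  gt <- sim$genotypes
  fam <- main_families(sim)[[1]]
  pair <- sort(fam$siblings)[1:2]
  before_pst <- pst_code_pair(gt, fam, pair, "paternal")$code
  before_ibd <- ibd_code_child(gt, fam, pair[1], "paternal")$code
  set.seed(99)
  swap <- sample(ncol(gt$calls), 40)
  sw <- gt
  sw$calls[, swap] <- ifelse(sw$calls[, swap] == AA, BB,
                             ifelse(sw$calls[, swap] == BB, AA, sw$calls[, swap]))
  expect_identical(pst_code_pair(sw, fam, pair, "paternal")$code, before_pst)
  expect_identical(ibd_code_child(sw, fam, pair[1], "paternal")$code, before_ibd)
})

make_code <- function(v, labels = c("IDENTICAL", "NOT_IDENTICAL")) {
  m <- length(v)
  switch_code(v, labels,
              data.frame(id = sprintf("m%02d", 1:m), chrom = "chr1", pos = (1:m) * 1e6),
              family = "f", parent = "paternal", unit = "c1+c2")
}

test_that("switch scan emits events at state changes with exact flanks", {
  ev <- detect_switches(make_code(c(1, 1, 1, 2, 2, 2)), min_run = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left_pos, 3e6)
  expect_equal(ev$right_pos, 4e6)
  expect_equal(ev$n_uninformative, 0L)

  expect_equal(nrow(detect_switches(make_code(rep(1, 6)), min_run = 1)), 0L)

  # isolated opposite code is recoded as noise under min_run = 2
  expect_equal(nrow(detect_switches(make_code(c(1, 2, 1, 1)), min_run = 2)), 0L)

  # uninformative markers inside the switch window are counted and measured
  ev2 <- detect_switches(make_code(c(1, 1, 0, 0, 2, 2)), min_run = 1)
  expect_equal(ev2$left_pos, 2e6)
  expect_equal(ev2$right_pos, 5e6)
  expect_equal(ev2$n_uninformative, 2L)
  expect_equal(ev2$region_bp, 3e6)
})

test_that("a switch at a terminal informative marker is still an event", {
  ev <- detect_switches(make_code(c(1, 1, 1, 2)), min_run = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$right_pos, 4e6)
})

test_that("fewer than two informative markers yields an empty warning result", {
  expect_warning(ev <- detect_switches(make_code(c(0, 0, 1, 0))), "fewer than 2")
  expect_equal(nrow(ev), 0L)
})

test_that("raising min_run never increases the number of events", {
  set.seed(7)
  for (rep in 1:20) {
    v <- sample(0:2, 60, replace = TRUE, prob = c(0.2, 0.4, 0.4))
    code <- make_code(v)
    n <- sapply(1:5, function(k)
      nrow(suppressWarnings(detect_switches(code, min_run = k))))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("parity attribution assigns events to the shared child", {
  fam <- structure(list(id = "f1:fa+mo", family_id = "f1", father_id = "fa",
                        mother_id = "mo", siblings = c("c1", "c2", "c3"),
                        pat_grandparents = NULL, mat_grandparents = NULL,
                        pst_usable = TRUE), class = "family_unit")
  # switch in pairs (c1,c2) and (c1,c3) but not (c2,c3) -> child c1
  ev <- rbind(pair_ev("c1+c2", 1e6, 2e6), pair_ev("c1+c3", 1.2e6, 2.2e6))
  at <- attribute_events(ev, fam, "paternal")
  expect_equal(nrow(at), 1L)
  expect_equal(at$attribution, "c1")
  expect_equal(at$n_meioses, 1L)

  # switch only in (c2,c3): even-parity ambiguity -> UNATTRIBUTED
  at2 <- attribute_events(pair_ev("c2+c3", 1e6, 2e6), fam, "paternal")
  expect_equal(at2$attribution, "UNATTRIBUTED")
})

test_that("two-sibling families report pair-level events", {
  fam <- structure(list(id = "f1:fa+mo", family_id = "f1", father_id = "fa",
                        mother_id = "mo", siblings = c("c1", "c2"),
                        pat_grandparents = NULL, mat_grandparents = NULL,
                        pst_usable = TRUE), class = "family_unit")
  at <- attribute_events(pair_ev("c1+c2", 1e6, 2e6), fam, "paternal")
  expect_equal(at$attribution, "c1+c2")
  expect_equal(at$n_meioses, 2L)
})

test_that("meiosis summaries compute sex-specific means and medians", {
  fam <- structure(list(id = "f1:fa+mo", family_id = "f1", father_id = "fa",
                        mother_id = "mo", siblings = c("c1", "c2", "c3"),
                        pat_grandparents = NULL, mat_grandparents = NULL,
                        pst_usable = TRUE), class = "family_unit")
  ev <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      data.frame(family = "f1:fa+mo", parent = "paternal", chrom = "chr1",
                 left_pos = i * 1e6, right_pos = i * 1e6 + 1e5, attribution = "c1",
                 n_meioses = 1L, supporting_pairs = "", n_uninformative = 0L,
                 region_bp = 1e5, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(1:5, function(i)
      data.frame(family = "f1:fa+mo", parent = "paternal", chrom = "chr1",
                 left_pos = i * 2e6, right_pos = i * 2e6 + 1e5, attribution = "c2",
                 n_meioses = 1L, supporting_pairs = "", n_uninformative = 0L,
                 region_bp = 1e5, stringsAsFactors = FALSE))))
  # only c1 and c2 recombined; c3 had zero events but still counts as a meiosis
  summ <- summarize_meioses(ev, list(fam))
  male <- summ$summary[summ$summary$parent_sex == "M", ]
  expect_equal(male$n_meioses, 3L)
  expect_equal(male$mean, 8 / 3)
  expect_equal(male$median, 3)
  # with no maternal events the maternal mean is zero
  female <- summ$summary[summ$summary$parent_sex == "F", ]
  expect_equal(female$mean, 0)
})

test_that("PST calling requires two genotyped siblings somewhere", {
  gt <- toy_gt(list(fa = c(AB, AB), mo = c(AA, AA), c1 = c(AA, AB)),
               std_samples(c("fa", "mo", "c1")))
  fams <- suppressWarnings(build_family_units(gt$samples))
  expect_error(pst_call(gt, fams), "at least two")
})
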