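test_that("transmitted-allele resolution matches its specification cases", {
  # child AB, mother AA, father AB -> paternal allele is B
  r <- transmitted_allele(AB, AB, AA)
  expect_equal(r$allele, 1L)
  expect_equal(r$status, "OK")
  # everyone AB -> ambiguous
  expect_equal(transmitted_allele(AB, AB, AB)$status, "AMBIGUOUS")
  # child AA, mother AA, father AB -> paternal allele is A
  r2 <- transmitted_allele(AA, AB, AA)
  expect_equal(r2$allele, 0L)
  # impossible transmission
  expect_equal(transmitted_allele(BB, AA, AA)$status, "MENDEL_ERROR")
  # missing calls are never resolved
  expect_equal(transmitted_allele(NC, AB, AA)$status, "NOCALL")
})

test_that("transmitted-allele lookup agrees with brute-force enumeration", {
  sets <- list(NULL, 0L, 0:1, 1L)  # alleles per code, NOCALL first
  for (f in 1:3) for (cp in 1:3) for (c_ in 1:3) {
    sols <- integer(0)
    for (t in sets[[f + 1L]]) for (q in sets[[cp + 1L]])
      if (t + q == c_ - 1L) sols <- union(sols, t)
    got <- transmitted_allele(c_, f, cp)
    if (length(sols) == 1L) {
      expect_equal(got$allele, sols)
      expect_equal(got$status, "OK")
    } else if (length(sols) > 1L) {
      expect_equal(got$status, "AMBIGUOUS")
    } else {
      expect_equal(got$status, "MENDEL_ERROR")
    }
  }
})

test_that("grandparental coding assigns unique carriers and stays silent otherwise", {
  # markers: 1 unique GM carrier; 2 both grandparents het; 3 father hom;
  # 4 unique GF carrier; 5 both assignments possible
  gt <- toy_gt(list(pgf = c(AA, AB, AA, AA, AB),
                    pgm = c(BB, AB, AA, BB, AB),
                    mgf = rep(AA, 5), mgm = rep(AA, 5),
                    fa = c(AB, AB, AA, AB, AB),
                    mo = c(AA, AA, AA, AA, AA),
                    c1 = c(AB, AB, AA, AA, AB),
                    c2 = rep(AA, 5)),
               std_samples(c("pgf", "pgm", "mgf", "mgm", "fa", "mo", "c1", "c2"),
                           with_gp = TRUE))
  fam <- suppressWarnings(build_family_units(gt$samples))[["f1:fa+mo"]]
  code <- ibd_code_child(gt, fam, "c1", "paternal")
  expect_equal(code$labels, c("GF", "GM"))
  # 1: transmitted B, GF=AA lacks B -> GM; 4: transmitted A with GM=BB -> GF
  expect_equal(code$code, c(2L, 0L, 0L, 1L, 0L))
})

test_that("IBD coding needs the three-generation pedigree", {
  gt <- toy_gt(list(fa = c(AB, AB), mo = c(AA, AA),
                    c1 = c(AA, AB), c2 = c(AB, AA)),
               std_samples(c("fa", "mo", "c1", "c2")))
  fam <- build_family_units(gt$samples)[[1]]
  expect_error(ibd_code_child(gt, fam, "c1", "paternal"), "three generations")
  expect_error(ibd_call(gt, list(fam)), "three generations")
})

test_that("IBD switch scan uses the same event contract as PST", {
  mk <- function(v) switch_code(v, c("GF", "GM"),
                                data.frame(id = sprintf("m%d", seq_along(v)),
                                           chrom = "chr1", pos = seq_along(v) * 1e6),
                                family = "f", parent = "paternal", unit = "c1")
  ev <- detect_switches(mk(c(1, 1, 2, 2)), min_run = 1)
  expect_equal(ev$left_pos, 2e6)
  expect_equal(ev$right_pos, 3e6)
  expect_equal(nrow(detect_switches(mk(rep(1, 4)), min_run = 1)), 0L)
  ev2 <- detect_switches(mk(c(1, 0, 0, 2)), min_run = 1)
  expect_equal(ev2$n_uninformative, 2L)
})

ibd_ev_row <- function(unit, l, r, chrom = "chr1") {
  data.frame(family = "f1:fa+mo", parent = "paternal", unit = unit, chrom = chrom,
             left_pos = l, right_pos = r, left_marker = "x", right_marker = "y",
             from_state = "GF", to_state = "GM", n_uninformative = 5L,
             region_bp = r - l, stringsAsFactors = FALSE)
}

test_that("method comparison pairs overlapping events and tests region sizes", {
  pst <- pair_ev("c1+c2", 1.0e6, 2.0e6)
  ibd <- ibd_ev_row("c1", 0.8e6, 2.5e6)
  cmp <- compare_methods(ibd, pst)
  expect_equal(cmp$summary$n, 1L)
  # a single pair leaves the t-statistic undefined (zero degrees of freedom)
  expect_true(is.na(cmp$summary$t))

  # identical sizes over several events: t = 0, p = 1
  pst5 <- do.call(rbind, lapply(1:5, function(i) pair_ev("c1+c2", i * 1e6, i * 1e6 + 4e5)))
  ibd5 <- do.call(rbind, lapply(1:5, function(i) ibd_ev_row("c2", i * 1e6, i * 1e6 + 4e5)))
  cmp5 <- compare_methods(ibd5, pst5)
  expect_equal(cmp5$summary$t, 0)
  expect_equal(cmp5$summary$p, 1)

  # non-overlapping events are never paired
  expect_warning(cmp0 <- compare_methods(ibd_ev_row("c1", 9e6, 9.5e6), pst),
                 "no matched")
  expect_equal(cmp0$summary$n, 0L)
})

test_that("halved PST regions give a significant negative paired difference", {
  set.seed(4)
  ibd_sizes <- round(runif(50, 2e5, 2e6))
  starts <- seq(1e6, by = 4e6, length.out = 50)
  ibd <- do.call(rbind, lapply(1:50, function(i)
    ibd_ev_row("c1", starts[i], starts[i] + ibd_sizes[i])))
  pst <- do.call(rbind, lapply(1:50, function(i)
    pair_ev("c1+c2", starts[i], starts[i] + ibd_sizes[i] / 2)))
  cmp <- compare_methods(ibd, pst)
  expect_equal(cmp$summary$n, 50L)
  expect_lt(cmp$summary$mean_diff_bp, 0)
  expect_lt(cmp$summary$p, 0.01)
  # closed-form paired t on the constructed differences
  d <- pst$region_bp - ibd$region_bp
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$summary$t, t_manual, tolerance = 1e-12)
})

test_that("PST pair events are the odd-parity union of the children's IBD events", {
  # deterministic construction: c1 recombines once, c2 four times
  toy <- toy_three_gen(60, list(c1 = c(30.5e6),
                                c2 = c(10.5e6, 20.5e6, 40.5e6, 50.5e6)))
  pst <- detect_switches(pst_code_pair(toy$gt, toy$family, c("c1", "c2"), "paternal"),
                         min_run = 1)
  ibd1 <- detect_switches(ibd_code_child(toy$gt, toy$family, "c1", "paternal"),
                          min_run = 1)
  ibd2 <- detect_switches(ibd_code_child(toy$gt, toy$family, "c2", "paternal"),
                          min_run = 1)
  expect_equal(nrow(ibd1), 1L)
  expect_equal(nrow(ibd2), 4L)
  expect_equal(nrow(pst), 5L)
  chk <- union_equivalence_check(toy$gt, toy$family, c("c1", "c2"), "paternal")
  expect_equal(chk$n_violations, 0L)

  # both children recombining in the same marker gap: PST misses it (even
  # parity) and the union check records agreement, not a violation
  toy2 <- toy_three_gen(60, list(c1 = c(30.2e6), c2 = c(30.7e6)))
  pst2 <- detect_switches(pst_code_pair(toy2$gt, toy2$family, c("c1", "c2"), "paternal"),
                          min_run = 1)
  expect_equal(nrow(pst2), 0L)
  chk2 <- union_equivalence_check(toy2$gt, toy2$family, c("c1", "c2"), "paternal")
  expect_equal(chk2$n_violations, 0L)
  expect_equal(sum(chk2$gaps$n_ibd), 2L)

  # no events anywhere: equivalence holds trivially
  toy3 <- toy_three_gen(20, list(c1 = numeric(0), c2 = numeric(0)))
  chk3 <- union_equivalence_check(toy3$gt, toy3$family, c("c1", "c2"), "paternal")
  expect_equal(chk3$n_violations, 0L)
  expect_equal(nrow(chk3$pst_events), 0L)
})
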