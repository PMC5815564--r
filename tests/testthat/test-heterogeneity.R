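test_that("presence classification follows the all/some/one definitions", {
  # present in 3/3 assessable regions
  expect_equal(classify_presence(alt = c(25, 30, 20), depth = c(100, 100, 100),
                                 clonal_vaf = rep(0.25, 3)), "ubiquitous")
  # present in 1/4, all assessable
  expect_equal(classify_presence(alt = c(25, 0, 0, 0), depth = rep(100, 4),
                                 clonal_vaf = rep(0.25, 4)), "private")
  expect_equal(classify_presence(alt = c(25, 30, 0), depth = rep(100, 3),
                                 clonal_vaf = rep(0.25, 3)), "shared")
  expect_error(classify_presence(alt = c(0, 0), depth = c(100, 100),
                                 clonal_vaf = c(0.25, 0.25)),
               class = "invalid_input")
})

test_that("low-depth regions are excluded from absence calls by the power rule", {
  # depth 2 cannot give 95% power to see a clonal VAF-0.25 mutation:
  # P(alt >= 2 | Binom(2, 0.25)) = 0.0625 by direct calculation
  expect_lt(1 - pbinom(1, 2, 0.25), 0.95)
  expect_equal(classify_presence(alt = c(25, 30, 0), depth = c(100, 100, 2),
                                 clonal_vaf = rep(0.25, 3)), "ubiquitous")
  # the same absence at adequate depth counts: shared
  expect_equal(classify_presence(alt = c(25, 30, 0), depth = c(100, 100, 80),
                                 clonal_vaf = rep(0.25, 3)), "shared")
})

test_that("per-patient classes partition the mutation set", {
  cfg <- sim_config(n_patients = 2, seed = 13)
  co <- simulate_cohort(cfg)
  for (pid in unique(co$variants$patient_id)) {
    v <- co$variants[co$variants$patient_id == pid, ]
    regs <- co$sheet$regions[co$sheet$regions$patient_id == pid, ]
    cls <- classify_patient_presence(v, setNames(regs$purity, regs$region_id))
    tab <- table(factor(cls$class,
                        levels = c("ubiquitous", "shared", "private")))
    expect_equal(sum(tab), nrow(cls))
    expect_true(all(cls$class %in% c("ubiquitous", "shared", "private")))
  }
})

test_that("SNV burden arithmetic", {
  expect_equal(snv_burden(30, 30), 1.0)
  expect_equal(snv_burden(0, 30), 0)
  expect_error(snv_burden(5, 0), class = "invalid_parameter")
})

test_that("a simulated hypermutator ranks first in cohort burden", {
  cfg <- sim_config(n_patients = 6, seed = 31, mmrd_rate = 0)
  co <- simulate_cohort(cfg)
  # make one patient mismatch-repair deficient by brute force: tenfold load
  cfg2 <- sim_config(n_patients = 6, seed = 31, mmrd_rate = 1)
  hyper <- simulate_patient(cfg2, "P001", "mHNPC", seed = 999)
  v <- rbind(co$variants[co$variants$patient_id != "P001", ], hyper$variants)
  s <- rbind(co$segments[co$segments$patient_id != "P001", ], hyper$segments)
  sheet <- co$sheet
  sheet$regions <- rbind(
    sheet$regions[sheet$regions$patient_id != "P001", ],
    hyper$sheet_regions)
  prof <- build_patient_profiles(v, s, sheet)
  expect_equal(prof$patient_id[which.max(prof$burden_per_mb)], "P001")
})

test_that("FGA hand cases: neutral genome, single gain, union semantics", {
  neutral <- make_segments("P1", "R1", list(list("chr1", 1, 2e9, 1, 1)))
  expect_equal(compute_fga(neutral, toy_genome()), 0)

  gain1 <- make_segments("P1", "R1", list(list("chr1", 1e6, 30999999 + 1e6, 2, 1)))
  expect_equal(compute_fga(gain1, toy_genome()), 31e6 / 3e9)

  # 30 Mb gain on a 3,000 Mb genome -> exactly 0.01
  gain <- make_segments("P1", "R1", list(list("chr1", 1, 30e6, 2, 1)))
  expect_equal(compute_fga(gain, toy_genome()), 0.01)

  # union semantics: event in 3/3 regions vs 1/3 regions, identical FGA
  all3 <- do.call(rbind, lapply(c("R1", "R2", "R3"), function(r) {
    make_segments("P1", r, list(list("chr1", 1, 30e6, 2, 1)))
  }))
  one3 <- rbind(make_segments("P1", "R1", list(list("chr1", 1, 30e6, 2, 1))),
                make_segments("P1", "R2", list(list("chr1", 40e6, 41e6 - 1, 1, 1))),
                make_segments("P1", "R3", list(list("chr1", 40e6, 41e6 - 1, 1, 1))))
  expect_equal(compute_fga(all3, toy_genome()), compute_fga(one3, toy_genome()))
  expect_error(compute_fga(all3[0, ], toy_genome()), class = "invalid_input")
})

test_that("heterogeneous SCNA fraction hand cases", {
  # identical alteration in both regions -> fully homogeneous
  same <- rbind(make_segments("P1", "R1", list(list("chr1", 1, 10e6, 2, 1))),
                make_segments("P1", "R2", list(list("chr1", 1, 10e6, 2, 1))))
  expect_equal(scna_heterogeneous_fraction(same), 0)

  # altered in one of two regions -> fully heterogeneous
  onereg <- rbind(make_segments("P1", "R1", list(list("chr1", 1, 10e6, 2, 1))),
                  make_segments("P1", "R2", list(list("chr1", 1, 10e6, 1, 1))))
  expect_equal(scna_heterogeneous_fraction(onereg), 1.0)

  # 10 Mb ubiquitous gain + 10 Mb private loss -> 0.5
  mixed <- rbind(
    make_segments("P1", "R1", list(list("chr1", 1, 10e6, 2, 1),
                                   list("chr1", 20e6, 30e6 - 1, 1, 0))),
    make_segments("P1", "R2", list(list("chr1", 1, 10e6, 2, 1)))
  )
  expect_equal(scna_heterogeneous_fraction(mixed), 0.5)

  # opposite directions at the same locus are heterogeneous
  flip <- rbind(make_segments("P1", "R1", list(list("chr1", 1, 10e6, 2, 1))),
                make_segments("P1", "R2", list(list("chr1", 1, 10e6, 1, 0))))
  expect_equal(scna_heterogeneous_fraction(flip), 1.0)

  single <- make_segments("P1", "R1", list(list("chr1", 1, 10e6, 2, 1)))
  expect_warning(out <- scna_heterogeneous_fraction(single),
                 class = "single_region")
  expect_true(is.na(out))
})

test_that("metrics are invariant to splitting a segment into abutting halves", {
  whole <- rbind(
    make_segments("P1", "R1", list(list("chr1", 1, 30e6, 2, 1))),
    make_segments("P1", "R2", list(list("chr1", 10e6, 20e6, 1, 0))))
  split2 <- rbind(
    make_segments("P1", "R1", list(list("chr1", 1, 15e6, 2, 1),
                                   list("chr1", 15e6 + 1, 30e6, 2, 1))),
    make_segments("P1", "R2", list(list("chr1", 10e6, 20e6, 1, 0))))
  expect_equal(compute_fga(whole, toy_genome()),
               compute_fga(split2, toy_genome()))
  expect_equal(scna_heterogeneous_fraction(whole),
               scna_heterogeneous_fraction(split2))
})

test_that("whole-genome doubling calls and patient flags", {
  wgd <- make_segments("P1", "R1", list(list("chr1", 1, 2e9, 2, 2)))
  no <- make_segments("P1", "R2", list(list("chr1", 1, 2e9, 1, 1)))
  expect_true(call_wgd(wgd))
  expect_false(call_wgd(no))
  het <- patient_wgd(rbind(
    wgd, make_segments("P1", "R2", list(list("chr1", 1, 2e9, 2, 2))),
    make_segments("P1", "R3", list(list("chr1", 1, 2e9, 1, 1)))))
  expect_equal(het$status, "heterogeneous")
  expect_equal(patient_wgd(rbind(wgd[0, ], no))$status, "none")
})

test_that("ITH correlation matches a direct formula evaluation", {
  expect_equal(correlate_ith(1:10 / 10, 1:10 / 10)$r, 1)
  x <- c(0.1, 0.4, 0.35, 0.8, 0.6)
  y <- c(0.2, 0.3, 0.5, 0.7, 0.4)
  out <- correlate_ith(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$r, r_hand)
  expect_equal(out$p.value, 2 * pt(-abs(t_hand), df = 3))
  expect_error(correlate_ith(rep(0.5, 5), y),
               class = "undefined_correlation")
})

test_that("independent metrics give small correlations under the null", {
  set.seed(17)
  small <- replicate(1000, abs(cor(rnorm(50), rnorm(50))) < 0.3)
  expect_gte(mean(small), 0.95)
})

test_that("group comparison: exact path, ties, degenerate input", {
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$p.value, 0.1)
  expect_warning(tied <- compare_groups(rep(1, 4), rep(1, 5)),
                 class = "all_tied")
  expect_equal(tied$p.value, 1)
  expect_error(compare_groups(numeric(0), 1:3), class = "invalid_input")
  # tie-free exact path agrees with the distribution-based reference
  set.seed(4)
  x <- rnorm(5); y <- rnorm(7) + 0.5
  expect_equal(compare_groups(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("exact and approximate group tests agree at moderate samples", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(13) + 0.8
  exact <- compare_groups(x, y, exact_max = 13)$p.value
  approx <- compare_groups(x, y, exact_max = 8)$p.value
  expect_lt(abs(exact - approx) / exact, 0.1)
})
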