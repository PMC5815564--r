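test_that("INIF summaries implement the extensive and eligibility rules", {
  out <- summarize_inif(c(5, 25))
  expect_equal(out$max, 25)
  expect_true(out$extensive)
  expect_true(out$digital_eligible)

  low <- summarize_inif(c(5, 7), eligibility_threshold = 8)
  expect_false(low$digital_eligible)
  expect_false(low$extensive)

  multi <- summarize_inif(c(5, 10, 15, 25))
  expect_equal(multi$mean, 13.75)
  expect_equal(multi$range, c(5, 25))

  expect_error(summarize_inif(c(5, 120)), class = "validation_error")
  expect_equal(inif_eligibility_threshold(c(2, 8, 8, 30)), 8)
})

test_that("CD8/FOXP3 pooling is sum-then-divide with per-region ratios reported", {
  one <- cd8_foxp3_ratio(100, 50)
  expect_equal(one$ratio, 2.0)

  two <- cd8_foxp3_ratio(c(100, 200), c(50, 50))
  expect_equal(two$ratio, 3.0)
  expect_equal(two$per_region, c(2, 4))

  # pooling is distinguishable from mean-of-ratios on unbalanced counts
  unb <- cd8_foxp3_ratio(c(100, 30), c(50, 10))
  expect_equal(unb$ratio, 130 / 60)
  expect_equal(mean(unb$per_region), 2.5)
  expect_false(isTRUE(all.equal(unb$ratio, mean(unb$per_region))))

  expect_warning(zero <- cd8_foxp3_ratio(c(10, 5), c(0, 0)),
                 class = "undefined_ratio")
  expect_true(is.na(zero$ratio))
  expect_error(cd8_foxp3_ratio(-1, 5), class = "validation_error")
})

make_wnt_variant <- function(pc = "p.T41A", gene = "CTNNB1") {
  data.frame(patient_id = "P1", region_id = "R1", chrom = "chr3",
             pos = 41260000, ref = "C", alt = "T", ref_count = 60,
             alt_count = 40, gene = gene, effect = "missense",
             context = "A[C>T]G", germline_flag = FALSE,
             protein_change = pc, stringsAsFactors = FALSE)
}

neutral_segs <- function() {
  rbind(make_segments("P1", "R1", list(list("chr3", 1, 198e6, 1, 1),
                                       list("chr5", 1, 181e6, 1, 1),
                                       list("chr8", 1, 146e6, 1, 1))))
}

test_that("Wnt activation flags each configured evidence route", {
  v <- make_wnt_variant()
  out <- flag_wnt_activation(v, neutral_segs())
  expect_true(out$wnt_activated)
  expect_match(out$evidence[1], "p.T41A")

  none <- flag_wnt_activation(v[0, ], neutral_segs())
  expect_false(none$wnt_activated)

  # a CTNNB1 variant outside the GOF list does not qualify
  other <- flag_wnt_activation(make_wnt_variant(pc = "p.D32Y"),
                               neutral_segs())
  expect_false(other$wnt_activated)

  # APC heterozygous loss is not enough; homozygous deletion is
  apc_het <- make_segments("P1", "R1", list(list("chr5", 112e6, 112.3e6, 1, 0)))
  expect_false(flag_wnt_activation(v[0, ], apc_het)$wnt_activated)
  apc_hom <- make_segments("P1", "R1", list(list("chr5", 112e6, 112.3e6, 0, 0)))
  expect_true(flag_wnt_activation(v[0, ], apc_hom)$wnt_activated)

  # RSPO2 amplification at >= 2x baseline
  rspo <- make_segments("P1", "R1", list(list("chr8", 108e6, 110e6, 3, 1)))
  expect_true(flag_wnt_activation(v[0, ], rspo)$wnt_activated)
  rspo3 <- make_segments("P1", "R1", list(list("chr8", 108e6, 110e6, 2, 1)))
  expect_false(flag_wnt_activation(v[0, ], rspo3)$wnt_activated)

  expect_error(flag_wnt_activation(v, neutral_segs(),
                                   gene_coords = data.frame(
                                     gene = "CTNNB1", chrom = "chr3",
                                     start = 1, end = 2)),
               class = "invalid_parameter")
})

test_that("adding qualifying events never turns the Wnt flag off", {
  v <- make_wnt_variant()
  base <- flag_wnt_activation(v, neutral_segs())
  more <- flag_wnt_activation(
    v, rbind(make_segments("P1", "R1", list(list("chr5", 112e6, 112.3e6, 0, 0)))))
  expect_true(base$wnt_activated)
  expect_true(more$wnt_activated)
  expect_gte(length(more$evidence), 1)
})

mmr_variant <- function(gene, germline, effect = "nonsense", pos = 48020000) {
  data.frame(patient_id = "P1", region_id = "R1", chrom = "chr2",
             pos = pos, ref = "C", alt = "T", ref_count = 50,
             alt_count = 50, gene = gene, effect = effect,
             context = "A[C>T]G", germline_flag = germline,
             protein_change = "", stringsAsFactors = FALSE)
}

test_that("MMRD requires biallelic evidence; monoallelic cases are surfaced", {
  # germline MSH6 variant + heterozygous deletion spanning MSH6 -> MMRD
  del_het <- make_segments("P1", "R1", list(list("chr2", 47e6, 49e6, 1, 0)))
  out <- flag_mmrd(mmr_variant("MSH6", TRUE), del_het)
  expect_true(out$mmrd)

  # homozygous deletion over MSH2 (two lost copies) -> MMRD
  del_hom <- make_segments("P1", "R1", list(list("chr2", 47.6e6, 47.72e6, 0, 0)))
  out2 <- flag_mmrd(mmr_variant("MSH6", TRUE)[0, ], del_hom)
  expect_true(out2$mmrd)

  # heterozygous deletion alone -> monoallelic, not MMRD
  out3 <- flag_mmrd(mmr_variant("MSH6", TRUE)[0, ], del_het)
  expect_false(out3$mmrd)
  expect_true(all(c("MSH2", "MSH6") %in% out3$monoallelic))
})

test_that("neoantigen-INIF association is rank-based and needs 3 patients", {
  inif <- c(5, 10, 15, 20, 25)
  burden <- c(10, 20, 30, 40, 50)
  out <- associate_neoantigen_inif(burden, burden * 0.6, inif)
  expect_equal(out$rho, c(1, 1))
  expect_equal(out$rho[1], out$rho[2])  # scaling leaves ranks unchanged
  expect_error(associate_neoantigen_inif(1:2, 1:2, 1:2),
               class = "invalid_input")
})

test_that("independent burden and INIF give small rank correlations", {
  set.seed(3)
  small <- replicate(1000, {
    abs(cor(rnorm(25), rnorm(25), method = "spearman")) < 0.4
  })
  # the asymptotic null rate P(|rho| < 0.4) at n = 25 is ~0.95 exactly
  # (sd = 1/sqrt(24)); allow 3 SE of Monte-Carlo noise around it
  expect_gte(mean(small), 0.95 - 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("ratio comparison restricts to eligible patients and ties give p 1", {
  ratio <- c(2, 2, 2, 2, 2, 2)
  wnt <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  out <- suppressWarnings(compare_ratio_by_wnt(ratio, wnt))
  expect_equal(out$p.value, 1)

  elig <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  out2 <- suppressWarnings(compare_ratio_by_wnt(ratio, wnt, elig))
  expect_equal(out2$n_wnt + out2$n_wt, sum(elig))
  expect_error(compare_ratio_by_wnt(ratio, rep(FALSE, 6)),
               class = "invalid_input")
})
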