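test_that("single-cluster and trunkless inputs", {
  ccf <- matrix(c(1, 1), 1, 2, dimnames = list("cluster1", NULL))
  ts <- build_clone_tree(ccf)
  expect_equal(ts$n_trees, 1L)
  expect_equal(ts$trees[[1]], 0L)
  expect_error(build_clone_tree(matrix(c(0.5, 0.4), 1, 2)),
               class = "no_trunk")
})

test_that("chain versus sibling resolution matches exhaustive search", {
  # 0.6 + 0.3 <= 1 in region 1 admits both chain and siblings; region 2
  # gives no information; the deepest-parent rule prefers the chain
  ccf <- rbind(c(1, 1), c(0.6, 0.0), c(0.3, 0.0))
  ts <- build_clone_tree(ccf, tolerance = 0.05)
  oracle <- admissible_trees_oracle(ccf, tolerance = 0.05, root = 1L)
  for (tree in ts$trees) {
    expect_true(any(vapply(oracle, identical, logical(1), tree)))
    expect_true(tree_constraints_ok(tree, ccf, 0.05))
  }
  expect_true(identical(ts$trees[[1]], c(0L, 1L, 2L)))
})

test_that("mutually exclusive subclones attach as siblings of the trunk", {
  ccf <- rbind(c(1, 1, 1), c(0.6, 0, 0), c(0, 0.7, 0), c(0, 0, 0.5))
  ts <- build_clone_tree(ccf)
  tree <- ts$trees[[1]]
  expect_equal(tree, c(0L, 1L, 1L, 1L))
})

test_that("unattachable clusters raise a named constraint error", {
  ccf <- rbind(c(1, 1), c(0.9, 0.1), c(0.2, 0.9))
  expect_error(build_clone_tree(ccf, tolerance = 0.05),
               class = "unattachable_cluster")
})

test_that("greedy reconstruction lands in the admissible set on random instances", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:60) {
    k <- sample(2:5, 1)
    tt <- simulate_clone_tree(k, n_regions = 3)
    ts <- build_clone_tree(tt$clone_ccf, tolerance = 1e-9)
    oracle <- admissible_trees_oracle(tt$clone_ccf, tolerance = 1e-9,
                                      root = 1L)
    expect_gt(length(oracle), 0)
    for (tree in ts$trees) {
      expect_true(any(vapply(oracle, identical, logical(1), tree)))
    }
    n_checked <- n_checked + length(ts$trees)
  }
  expect_gt(n_checked, 0)
})

test_that("newick output is well-formed and parseable", {
  ccf <- rbind(c(1, 1), c(0.5, 0.3), c(0.3, 0.2))
  rownames(ccf) <- paste0("C", 1:3)
  parent <- c(0L, 1L, 1L)
  nk <- tree_newick(parent, ccf, mutation_counts = c(10, 5, 3))
  expect_equal(nk, "(C2_n5,C3_n3)C1_n10;")
  tr <- ape::read.tree(text = nk)
  expect_equal(sort(tr$tip.label), c("C2_n5", "C3_n3"))
})

test_that("parallel evolution requires distinct non-ancestral clones", {
  ccf <- rbind(c(1, 1), c(0.5, 0.4), c(0.3, 0.1))
  sib <- c(0L, 1L, 1L)     # 2 and 3 are siblings
  chain <- c(0L, 1L, 2L)   # 3 descends from 2

  two_truncal <- data.frame(mutation_id = c("m1", "m2"), gene = "CTNNB1",
                            effect = "missense", cluster = c(1L, 1L))
  expect_equal(nrow(detect_parallel_evolution(two_truncal, sib, ccf)), 0L)

  sibs <- data.frame(mutation_id = c("m1", "m2"), gene = "CTNNB1",
                     effect = "missense", cluster = c(2L, 3L))
  ev <- detect_parallel_evolution(sibs, sib, ccf)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_variants, 2L)

  expect_equal(nrow(detect_parallel_evolution(sibs, chain, ccf)), 0L)

  # silent variants never count
  silent <- transform(sibs, effect = "silent")
  expect_equal(nrow(detect_parallel_evolution(silent, sib, ccf)), 0L)
})

test_that("three sibling variants yield one event with all three variants", {
  ccf <- rbind(c(1, 1, 1), c(0.6, 0, 0), c(0, 0.7, 0), c(0, 0, 0.5))
  parent <- c(0L, 1L, 1L, 1L)
  mut <- data.frame(mutation_id = c("mA", "mB", "mC"), gene = "CTNNB1",
                    effect = "missense", cluster = 2:4)
  ev <- detect_parallel_evolution(mut, parent, ccf)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_variants, 3L)
  expect_equal(ev$clusters, "2,3,4")
})

test_that("pathway-level detection pools genes from the configured set", {
  ccf <- rbind(c(1, 1), c(0.5, 0.1), c(0.2, 0.5))
  parent <- c(0L, 1L, 1L)
  mut <- data.frame(mutation_id = c("m1", "m2"),
                    gene = c("APC", "RNF43"), effect = "missense",
                    cluster = c(2L, 3L))
  no_sets <- detect_parallel_evolution(mut, parent, ccf)
  expect_equal(nrow(no_sets), 0L)
  with_sets <- detect_parallel_evolution(
    mut, parent, ccf, gene_sets = list(Wnt = default_wnt_gene_set()))
  expect_equal(nrow(with_sets), 1L)
  expect_equal(with_sets$level, "pathway")
})

test_that("driver timing fractions aggregate SNV and SCNA events", {
  snv <- data.frame(gene = rep("PTEN", 3),
                    clonality = c("clonal", "clonal", "subclonal"))
  scna <- data.frame(gene = rep("PTEN", 2),
                     status = c("ubiquitous", "heterogeneous"))
  out <- time_driver_events(snv, scna)
  expect_equal(out$n_events, 5L)
  expect_equal(out$fraction_clonal, 0.6)

  single <- time_driver_events(data.frame(gene = "TP53",
                                          clonality = "clonal"))
  expect_equal(single$fraction_clonal, 1.0)
  none <- time_driver_events(snv[0, ], scna[0, ])
  expect_equal(nrow(none), 0L)
})

test_that("configured per-gene timing is recovered from a simulated cohort", {
  set.seed(6)
  frac_true <- c(TP53 = 0.9, PTEN = 0.6, KMT2C = 0.2)
  events <- do.call(rbind, lapply(names(frac_true), function(g) {
    n <- 60
    data.frame(gene = g,
               clonality = ifelse(runif(n) < frac_true[[g]],
                                  "clonal", "subclonal"))
  }))
  out <- time_driver_events(events)
  for (g in names(frac_true)) {
    est <- out$fraction_clonal[out$gene == g]
    ci <- qbinom(c(0.0005, 0.9995), 60, frac_true[[g]]) / 60
    expect_gte(est, ci[1])
    expect_lte(est, ci[2])
  }
})
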