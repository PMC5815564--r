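test_that("multiplicity estimation follows the rounding formula and bounds", {
  expect_equal(estimate_multiplicity(0.25, 0.5, 2, 1), 1L)
  expect_equal(estimate_multiplicity(0.5, 1.0, 2, 2), 1L)
  expect_equal(estimate_multiplicity(0.9, 1.0, 2, 2), 2L)
  # clip from below: tiny VAF still gets multiplicity 1
  expect_equal(estimate_multiplicity(0.01, 0.8, 3, 2), 1L)
  expect_error(estimate_multiplicity(0.3, 0.5, 2, 0),
               class = "inconsistency_error")
})

test_that("CCF point estimates and intervals behave at hand-checked points", {
  est <- compute_ccf(25, 75, purity = 0.5, cn_total = 2, multiplicity = 1)
  expect_equal(est$ccf, 1.0)
  expect_true(est$ccf_lower <= est$ccf && est$ccf <= est$ccf_upper)

  zero <- compute_ccf(0, 100, purity = 0.5, cn_total = 2)
  expect_equal(zero$ccf, 0)
  expect_equal(zero$ccf_lower, 0)

  # VAF incompatible with the copy-number state flags inconsistency
  odd <- compute_ccf(90, 10, purity = 0.5, cn_total = 2)
  expect_true(odd$inconsistent)
  expect_lte(odd$ccf, 1.5)
  expect_error(compute_ccf(5, 5, purity = 0), class = "invalid_purity")
})

test_that("CCF estimator is nearly unbiased on simulated clonal sites", {
  set.seed(21)
  n <- 3000
  depth <- rpois(n, 100)
  alt <- rbinom(n, depth, 0.25)
  est <- compute_ccf(alt, depth - alt, purity = 0.5, cn_total = 2)
  expect_lt(abs(mean(est$ccf) - 1), 0.02)
})

test_that("single-region identical counts collapse to one cluster", {
  alt <- matrix(rep(30L, 20), ncol = 1)
  depth <- matrix(rep(100L, 20), ncol = 1)
  cl <- cluster_mutations(alt, depth, purity = 1, max_clusters = 3, seed = 1)
  expect_equal(cl$K, 1L)
})

test_that("K_max = 1 equals the pooled single-cluster maximum likelihood fit", {
  set.seed(31)
  depth <- matrix(rpois(60, 80), 30, 2)
  alt <- matrix(rbinom(60, depth, 0.2), 30, 2)
  cl <- cluster_mutations(alt, depth, purity = c(0.5, 0.5), max_clusters = 1,
                          seed = 1)
  # oracle: directly maximise the pooled binomial likelihood per region
  for (r in 1:2) {
    obj <- function(f) {
      p <- min(max(0.25 * f, 1e-9), 1 - 1e-9)
      -sum(dbinom(alt[, r], depth[, r], p, log = TRUE))
    }
    f_star <- optimize(obj, c(0, 1), tol = 1e-9)$minimum
    expect_equal(unname(cl$ccf[1, r]), f_star, tolerance = 1e-4)
  }
})

test_that("EM log-likelihood is non-decreasing and refits are deterministic", {
  set.seed(8)
  truth <- rep(1:2, each = 40)
  f <- rbind(c(1, 1), c(0.5, 0.1))
  depth <- matrix(rpois(160, 100), 80, 2)
  alt <- matrix(rbinom(160, depth, 0.25 * f[truth, ]), 80, 2)
  a <- cluster_mutations(alt, depth, purity = c(0.5, 0.5), max_clusters = 4,
                         seed = 42)
  expect_true(all(diff(a$loglik) >= -1e-6))
  b <- cluster_mutations(alt, depth, purity = c(0.5, 0.5), max_clusters = 4,
                         seed = 42)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$ccf, b$ccf)
})

test_that("well-separated two-cluster structure is recovered", {
  set.seed(14)
  truth <- rep(1:2, each = 50)
  f <- rbind(c(1, 1), c(0.6, 0.05))
  depth <- matrix(rpois(200, 100), 100, 2)
  alt <- matrix(rbinom(200, depth, 0.25 * f[truth, ]), 100, 2)
  cl <- cluster_mutations(alt, depth, purity = c(0.5, 0.5), max_clusters = 4,
                          seed = 5)
  expect_equal(cl$K, 2L)
  expect_gte(ari_oracle(cl$assignment, truth), 0.9)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, truth),
               ari_oracle(cl$assignment, truth))
})

test_that("region-disjoint subclones are recovered with CCF sums within bounds", {
  set.seed(77)
  # trunk + three mutually exclusive subclones, each confined to one region
  f <- rbind(c(1, 1, 1), c(0.6, 0, 0), c(0, 0.7, 0), c(0, 0, 0.5))
  truth <- rep(1:4, each = 30)
  depth <- matrix(rpois(120 * 3, 120), 120, 3)
  alt <- matrix(rbinom(120 * 3, depth, 0.25 * f[truth, ]), 120, 3)
  cl <- cluster_mutations(alt, depth, purity = c(0.5, 0.5, 0.5),
                          max_clusters = 6, seed = 9)
  expect_equal(cl$K, 4L)
  sub <- cl$ccf[cl$clonality == "subclonal", , drop = FALSE]
  expect_true(all(colSums(sub) <= 1 + 0.05))
})

test_that("clonality calls follow the every-region threshold rule", {
  expect_equal(classify_clonality(c(1, 1, 1)), "clonal")
  expect_equal(classify_clonality(c(1.0, 0.3)), "subclonal")
  expect_equal(classify_clonality(c(0.91, 0.95), clonal_threshold = 0.9),
               "clonal")
  expect_equal(classify_clonality(c(0.89, 0.95), clonal_threshold = 0.9),
               "subclonal")
})

test_that("clonality classification is accurate across thresholds on simulated truth", {
  set.seed(55)
  n_rep <- 200
  n_sites <- 20  # clusters are classified on averaged CCFs, not single sites
  correct <- 0
  for (i in seq_len(n_rep)) {
    clonal <- i %% 2 == 0
    f <- if (clonal) c(1, 1) else c(runif(1, 0.2, 0.7), runif(1, 0, 0.7))
    est <- vapply(1:2, function(r) {
      depth <- rpois(n_sites, 100)
      alt <- rbinom(n_sites, depth, 0.5 * f[r])  # purity 1, diploid
      min(mean(compute_ccf(alt, depth - alt, purity = 1, cn_total = 2)$ccf),
          1)
    }, numeric(1))
    for (thr in c(0.8, 0.85, 0.9, 0.95)) {
      call <- classify_clonality(est, thr) == "clonal"
      if (call == clonal) correct <- correct + 1
    }
  }
  expect_gte(correct / (n_rep * 4), 0.95)
})
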