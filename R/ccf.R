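#' Cancer cell fraction estimation and mutation clustering
#'
#' The cancer cell fraction (CCF) of a mutation is the fraction of tumour
#' cells that carry it. For a mutation with variant allele fraction `vaf` at a
#' locus with tumour total copy number `CN_t`, mutation multiplicity `m` and
#' sample purity `rho`, `ccf = vaf * (rho * CN_t + 2 (1 - rho)) / (rho * m)`.
#' Mutations are clustered across regions with a finite multi-region binomial
#' mixture fitted by EM, with the number of clusters chosen by BIC — a
#' deterministic, seed-controlled alternative to Dirichlet-process MCMC
#' clustering.
#'
#' @name ccf_clustering
NULL

#' Estimate mutation multiplicity
#'
#' `m = clip(round(vaf * (rho * CN_t + 2 (1 - rho)) / rho), 1, cn_major)`:
#' the integer number of mutated copies most consistent with the observed VAF,
#' bounded by the major allele copy number.
#'
#' @param vaf observed variant allele fraction
#' @param purity sample purity in (0, 1]
#' @param cn_total tumour total copy number at the locus (>= 1)
#' @param cn_major tumour major allele copy number (>= 1 at a mutated site)
#' @return integer multiplicity
#' @export
estimate_multiplicity <- function(vaf, purity, cn_total, cn_major) {
  assert_scalar_in(purity, 0, 1, "purity", lo_open = TRUE)
  if (any(cn_major == 0)) {
    msq_stop("cn_major = 0 at a mutated site is inconsistent",
             "inconsistency_error")
  }
  raw <- round(vaf * (purity * cn_total + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(raw, 1), cn_major))
}

#' Compute a CCF estimate with a binomial credible interval
#'
#' The point estimate transforms the VAF by the purity/copy-number factor;
#' the interval applies the same transformation to a Jeffreys binomial
#' interval on the success probability of the alt count. Estimates are
#' clipped to `[0, 1.5]`; values above 1 indicate copy-number or purity
#' inconsistency and are flagged.
#'
#' @param alt_count,ref_count read counts (depth must be positive)
#' @param purity sample purity in (0, 1]
#' @param cn_total tumour total copy number
#' @param multiplicity mutated copies (from [estimate_multiplicity()])
#' @param level credible level for the interval (default 0.95)
#' @return data.frame with `vaf, ccf, ccf_lower, ccf_upper, inconsistent`
#' @export
compute_ccf <- function(alt_count, ref_count, purity, cn_total,
                        multiplicity = 1, level = 0.95) {
  if (any(purity <= 0)) msq_stop("purity must be > 0", "invalid_purity")
  depth <- alt_count + ref_count
  if (any(depth <= 0)) msq_stop("depth must be > 0 at every site",
                                "invalid_parameter")
  vaf <- alt_count / depth
  fac <- (purity * cn_total + 2 * (1 - purity)) / (purity * multiplicity)
  alpha <- (1 - level) / 2
  p_lo <- qbeta(alpha, alt_count + 0.5, ref_count + 0.5)
  p_hi <- qbeta(1 - alpha, alt_count + 0.5, ref_count + 0.5)
  p_lo[alt_count == 0] <- 0
  p_hi[ref_count == 0] <- 1
  ccf_raw <- vaf * fac
  data.frame(
    vaf = vaf,
    ccf = pmin(pmax(ccf_raw, 0), 1.5),
    ccf_lower = pmin(p_lo * fac, 1.5),
    ccf_upper = pmin(p_hi * fac, 1.5),
    inconsistent = ccf_raw > 1
  )
}

# M-step update of one cluster CCF in one region: maximises the weighted
# binomial log-likelihood sum_i w_i [a_i log(c_i f) + (d_i - a_i) log(1 - c_i f)]
# over f in [0, 1]. The objective is concave, so a bracketed Newton search on
# the gradient converges fast; boundary optima (all-ref -> 0, gradient still
# positive at 1 -> 1) are handled exactly.
mstep_ccf <- function(a, d, cc, w, eps = 1e-6) {
  swa <- sum(w * a)
  if (swa <= 0) return(0)
  grad <- function(x) {
    q <- 1 - pmin(cc * x, 1 - eps)
    swa / x - sum(w * (d - a) * cc / q)
  }
  if (grad(1) >= 0) return(1)
  lo <- 1e-12; hi <- 1
  x <- min(max(swa / sum(w * d * cc), 1e-8), 1 - 1e-8)
  for (it in 1:50) {
    q <- 1 - pmin(cc * x, 1 - eps)
    g1 <- swa / x - sum(w * (d - a) * cc / q)
    if (g1 > 0) lo <- x else hi <- x
    g2 <- -swa / x^2 - sum(w * (d - a) * cc^2 / q^2)
    x_new <- x - g1 / g2
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      x_new <- (lo + hi) / 2
    }
    if (abs(x_new - x) < 1e-10) return(x_new)
    x <- x_new
  }
  x
}

# one EM run for fixed K; alt/depth/fac are n x R matrices.
# expected vaf for cluster k in region r at site i = fac[i,r] * f[k,r]
em_binomial_mixture <- function(alt, depth, fac, K, f_init,
                                max_iter = 150, tol = 1e-4) {
  n <- nrow(alt); R <- ncol(alt)
  eps <- 1e-6
  f <- f_init                     # K x R cluster CCF parameters
  pi_k <- rep(1 / K, K)
  loglik_trace <- numeric(0)
  ll_site_cluster <- function(f) {
    # n x K matrix of summed binomial log-likelihoods
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      p <- pmin(pmax(fac * matrix(f[k, ], n, R, byrow = TRUE), eps), 1 - eps)
      out[, k] <- rowSums(dbinom(alt, depth, p, log = TRUE))
    }
    out
  }
  prev_ll <- -Inf
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    lls <- ll_site_cluster(f)
    lw <- sweep(lls, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    loglik_trace <- c(loglik_trace, ll)
    gamma <- exp(lw - mx - log(rowSums(exp(lw - mx))))
    # M step
    pi_k <- pmax(colMeans(gamma), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      w <- gamma[, k]
      for (r in seq_len(R)) {
        f[k, r] <- mstep_ccf(alt[, r], depth[, r], fac[, r], w, eps)
      }
    }
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) break
    prev_ll <- ll
  }
  converged <- iter < max_iter
  list(f = f, pi = pi_k, gamma = gamma, loglik = loglik_trace,
       converged = converged, K = K)
}

#' Cluster mutations across regions into subclones
#'
#' Fits multi-region binomial mixtures for `K = 1..max_clusters` by EM with
#' seed-controlled multi-start, selects `K` by BIC, and assigns each mutation
#' to the cluster with maximal posterior responsibility (ties broken towards
#' the lowest cluster index). A mutation with 0 alt reads in a region still
#' contributes a binomial term there: absence is informative. Read counts are
#' transformed to the CCF scale through the purity/copy-number/multiplicity
#' factor, and cluster CCF parameters are optimised on `[0, 1]`.
#'
#' @param alt,depth n x R matrices of alt and total read counts (mutations x
#'   regions)
#' @param purity length-R purity vector
#' @param cn_total n x R matrix of local total copy number (default all 2)
#' @param multiplicity n x R matrix of multiplicities (default all 1)
#' @param max_clusters maximum number of clusters tried (>= 1)
#' @param n_starts EM restarts per K
#' @param seed integer seed controlling the restarts
#' @param clonal_threshold per-region CCF at or above which a cluster is
#'   called clonal (default 0.9)
#' @return object of class `ccf_clusters`: `assignment` (integer per
#'   mutation), `ccf` (K x R matrix), `clonality` (per cluster), `K`, `bic`
#'   (per K tried), `loglik` trace of the selected fit, `converged`
#' @export
cluster_mutations <- function(alt, depth, purity,
                              cn_total = NULL, multiplicity = NULL,
                              max_clusters = 6, n_starts = 10, seed = 1,
                              clonal_threshold = 0.9) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt); R <- ncol(alt)
  if (n < 1L || R < 1L) msq_stop("need >= 1 mutation and >= 1 region",
                                 "invalid_parameter")
  if (max_clusters < 1) msq_stop("max_clusters must be >= 1",
                                 "invalid_parameter")
  if (is.null(cn_total)) cn_total <- matrix(2, n, R)
  if (is.null(multiplicity)) multiplicity <- matrix(1, n, R)
  fac <- sweep(multiplicity, 2, purity, "*") /
    (sweep(cn_total, 2, purity, "*") + matrix(2 * (1 - purity), n, R,
                                              byrow = TRUE))
  # raw per-site CCF estimates seed the starts
  ccf_raw <- pmin(pmax((alt / pmax(depth, 1)) / fac, 0), 1)
  set.seed(as.integer(seed))
  kmax <- min(max_clusters, n)
  fits <- vector("list", kmax)
  bic <- rep(NA_real_, kmax)
  for (K in seq_len(kmax)) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, K)
      f0 <- ccf_raw[idx, , drop = FALSE] +
        matrix(runif(K * R, -0.05, 0.05), K, R)
      f0 <- pmin(pmax(f0, 0), 1)
      fit <- em_binomial_mixture(alt, depth, fac, K, f0)
      if (is.null(best) || max(fit$loglik) > max(best$loglik)) best <- fit
      if (K == 1L) break  # single-cluster fit does not depend on the start
    }
    ll <- max(best$loglik)
    bic[K] <- -2 * ll + (K * R + (K - 1)) * log(n)
    fits[[K]] <- best
  }
  K_sel <- which.min(bic)
  fit <- fits[[K_sel]]
  if (!fit$converged) {
    msq_warn(sprintf("EM did not converge for K = %d; best solution returned",
                     K_sel), "em_nonconvergence")
  }
  # assignment: max responsibility, lowest index on ties
  assignment <- apply(fit$gamma, 1, function(g) which(g >= max(g) - 1e-12)[1])
  # drop empty clusters, order by decreasing mean CCF for stable labels
  used <- sort(unique(assignment))
  f <- fit$f[used, , drop = FALSE]
  assignment <- match(assignment, used)
  ord <- order(-rowMeans(f))
  f <- f[ord, , drop = FALSE]
  assignment <- match(assignment, ord)
  f <- pmin(pmax(f, 0), 1)
  rownames(f) <- paste0("cluster", seq_len(nrow(f)))
  colnames(f) <- colnames(alt) %||% paste0("R", seq_len(R))
  clon <- apply(f, 1, function(v) classify_clonality(v, clonal_threshold))
  structure(list(
    assignment = assignment, ccf = f, clonality = clon,
    K = nrow(f), bic = bic, loglik = fit$loglik,
    converged = fit$converged, n_mutations = n, n_regions = R,
    clonal_threshold = clonal_threshold
  ), class = "ccf_clusters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a cluster as clonal or subclonal
#'
#' Clonal iff the CCF is at or above the threshold in every region.
#'
#' @param ccf_vector per-region CCF vector of one cluster
#' @param clonal_threshold CCF threshold (default 0.9)
#' @return `"clonal"` or `"subclonal"`
#' @export
classify_clonality <- function(ccf_vector, clonal_threshold = 0.9) {
  if (all(ccf_vector >= clonal_threshold)) "clonal" else "subclonal"
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat(sprintf("Multi-region binomial mixture: %d mutations, %d regions, K = %d\n",
              x$n_mutations, x$n_regions, x$K))
  tab <- cbind(round(x$ccf, 3), n = as.integer(table(factor(
    x$assignment, levels = seq_len(x$K)))))
  print(data.frame(tab, clonality = x$clonality))
  invisible(x)
}

#' @export
summary.ccf_clusters <- function(object, ...) {
  cat("BIC by number of clusters:\n")
  print(round(setNames(object$bic, seq_along(object$bic)), 1))
  print(object)
  invisible(object)
}
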