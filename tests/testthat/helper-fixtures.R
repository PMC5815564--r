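# Small programmatic fixtures shared across test files.

# minimal variant table: one patient, mutations x regions grid
make_variant_table <- function(alt, depth, patient_id = "P1",
                               regions = paste0("R", seq_len(ncol(alt))),
                               gene = "", effect = "missense",
                               context = "A[C>T]G") {
  n <- nrow(alt)
  do.call(rbind, lapply(seq_along(regions), function(r) {
    data.frame(
      patient_id = patient_id, region_id = regions[r],
      chrom = "chr1", pos = seq_len(n), ref = "C", alt = "T",
      ref_count = depth[, r] - alt[, r], alt_count = alt[, r],
      gene = rep_len(gene, n), effect = rep_len(effect, n),
      context = rep_len(context, n), germline_flag = FALSE,
      stringsAsFactors = FALSE
    )
  }))
}

# segment rows for one patient/region from a compact spec list
make_segments <- function(patient_id, region_id, rows) {
  do.call(rbind, lapply(rows, function(x) {
    data.frame(patient_id = patient_id, region_id = region_id,
               chrom = x[[1]], start = as.numeric(x[[2]]),
               end = as.numeric(x[[3]]), major_cn = as.numeric(x[[4]]),
               minor_cn = as.numeric(x[[5]]), stringsAsFactors = FALSE)
  }))
}

# a tiny two-chromosome genome used by interval hand cases
toy_genome <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(2e9, 1e9),
             stringsAsFactors = FALSE)
}

# brute-force adjusted Rand index (oracle-independent of mclust)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# enumerate all rooted trees on K nodes with fixed root as parent vectors
enumerate_parent_vectors <- function(K, root = 1L) {
  rest <- setdiff(seq_len(K), root)
  if (length(rest) == 0L) return(list(integer(1)))
  choices <- lapply(rest, function(v) setdiff(seq_len(K), v))
  grids <- expand.grid(choices)
  out <- list()
  for (i in seq_len(nrow(grids))) {
    parent <- integer(K)
    parent[rest] <- as.integer(unlist(grids[i, ]))
    # reject cyclic assignments (must reach root from every node)
    ok <- TRUE
    for (v in rest) {
      seen <- integer(0)
      p <- v
      while (p != root) {
        if (p %in% seen || length(seen) > K) { ok <- FALSE; break }
        seen <- c(seen, p)
        p <- parent[p]
        if (p == 0L) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- parent
  }
  out
}

# all admissible trees for a CCF matrix by exhaustive search
admissible_trees_oracle <- function(ccf, tolerance = 0.05, root = NULL) {
  K <- nrow(ccf)
  if (is.null(root)) root <- which.max(rowMeans(ccf))
  Filter(function(parent) tree_constraints_ok(parent, ccf, tolerance),
         enumerate_parent_vectors(K, root))
}
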