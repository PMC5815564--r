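#' Clone trees, driver timing and parallel evolution
#'
#' Reconstructs the clonal evolutionary history of one patient from mutation
#' clusters with per-region CCF vectors, using the standard constraints: a
#' child clone cannot exceed its parent's CCF in any region (pigeonhole /
#' crossing rule) and the children of one parent cannot jointly exceed it
#' (sum rule). Detects parallel evolution — independent subclones converging
#' on the same gene or pathway — and tallies the clonal/ubiquitous versus
#' subclonal/heterogeneous timing of driver events across a cohort.
#'
#' @name phylogeny_parallel
NULL

# is `a` an ancestor of `b` (strict) in a parent-vector tree?
is_ancestor <- function(parent, a, b) {
  p <- parent[b]
  while (p != 0L) {
    if (p == a) return(TRUE)
    p <- parent[p]
  }
  FALSE
}

node_depth <- function(parent, v) {
  d <- 0L
  while (parent[v] != 0L) {
    v <- parent[v]
    d <- d + 1L
  }
  d
}

# can `v` attach under `p` given the partial parent vector?
attach_ok <- function(ccf, parent, placed, v, p, tol) {
  if (any(ccf[p, ] < ccf[v, ] - tol)) return(FALSE)
  sibs <- placed[parent[placed] == p]
  sib_sum <- ccf[v, ] + if (length(sibs)) colSums(ccf[sibs, , drop = FALSE])
                        else 0
  all(sib_sum <= ccf[p, ] + tol)
}

#' Reconstruct clone tree(s) from mutation clusters
#'
#' Clusters are attached greedily in order of decreasing mean CCF. Each
#' subclonal cluster attaches to the deepest already-placed cluster that
#' satisfies, in every region, parent CCF >= cluster CCF - tolerance and
#' sibling-sum <= parent CCF + tolerance; when several deepest parents tie,
#' every choice is explored and all admissible trees are returned. The search
#' backtracks, so an attachment that would strand a later cluster is undone;
#' if the depth-preferring search fails entirely, all feasible parents (not
#' only deepest) are explored before giving up.
#'
#' @param ccf K x R matrix of per-region cluster CCFs
#' @param tolerance CCF slack absorbing read-sampling noise (default 0.05)
#' @param max_trees cap on the number of admissible trees returned
#' @return object of class `clone_tree_set`: `trees` (list of integer parent
#'   vectors, 0 = root), `root`, `ccf`, `tolerance`, `n_trees`
#' @export
build_clone_tree <- function(ccf, tolerance = 0.05, max_trees = 64) {
  ccf <- as.matrix(ccf)
  K <- nrow(ccf)
  clonal <- which(apply(ccf, 1, function(v) all(v >= 1 - tolerance)))
  if (length(clonal) == 0L) {
    msq_stop("no trunk: no cluster has CCF ~1 in every region", "no_trunk")
  }
  root <- clonal[which.max(rowMeans(ccf[clonal, , drop = FALSE]))]
  rest <- setdiff(seq_len(K), root)
  rest <- rest[order(-rowMeans(ccf[rest, , drop = FALSE]))]

  results <- list()
  search <- function(parent, placed, i, deepest_only) {
    if (length(results) >= max_trees) return()
    if (i > length(rest)) {
      results[[length(results) + 1L]] <<- parent
      return()
    }
    v <- rest[i]
    feas <- placed[vapply(placed, function(p) {
      attach_ok(ccf, parent, placed, v, p, tolerance)
    }, logical(1))]
    if (length(feas) == 0L) return()
    if (deepest_only) {
      depths <- vapply(feas, function(p) node_depth(parent, p), integer(1))
      feas <- feas[depths == max(depths)]
    }
    for (p in feas) {
      parent[v] <- p
      search(parent, c(placed, v), i + 1L, deepest_only)
      parent[v] <- 0L
      if (length(results) >= max_trees) return()
    }
  }
  parent0 <- integer(K)
  search(parent0, root, 1L, deepest_only = TRUE)
  if (length(results) == 0L) {
    search(parent0, root, 1L, deepest_only = FALSE)
  }
  if (length(results) == 0L) {
    # name one violated constraint for the error message
    v <- rest[1]
    bad_r <- which(ccf[root, ] < ccf[v, ] - tolerance)[1]
    msq_stop(sprintf(
      "cluster %d cannot be attached: CCF exceeds every candidate parent (e.g. region %s)",
      v, if (is.na(bad_r)) "sum rule" else colnames(ccf)[bad_r] %||% bad_r),
      "unattachable_cluster")
  }
  structure(list(trees = unique(results), root = root, ccf = ccf,
                 tolerance = tolerance,
                 n_trees = length(unique(results))),
            class = "clone_tree_set")
}

#' Verify the sum and crossing rules on one tree
#' @param parent integer parent vector (0 = root)
#' @param ccf K x R CCF matrix
#' @param tolerance slack
#' @return TRUE if every node satisfies both rules
#' @export
tree_constraints_ok <- function(parent, ccf, tolerance = 0.05) {
  K <- nrow(ccf)
  for (v in seq_len(K)) {
    p <- parent[v]
    if (p == 0L) next
    if (any(ccf[p, ] < ccf[v, ] - tolerance)) return(FALSE)
  }
  for (p in seq_len(K)) {
    ch <- which(parent == p)
    if (length(ch) == 0L) next
    if (any(colSums(ccf[ch, , drop = FALSE]) > ccf[p, ] + tolerance)) {
      return(FALSE)
    }
  }
  sum(parent == 0L) == 1L
}

#' @export
print.clone_tree_set <- function(x, ...) {
  cat(sprintf("Clone tree set: %d cluster(s), %d admissible tree(s), root = cluster %d\n",
              nrow(x$ccf), x$n_trees, x$root))
  cat("First tree (newick):", tree_newick(x$trees[[1]], x$ccf), "\n")
  invisible(x)
}

#' Newick string for one clone tree
#'
#' Cluster ids become node labels; unary chains are emitted as singleton
#' clades, which is legal newick.
#'
#' @param parent integer parent vector (0 = root)
#' @param ccf CCF matrix whose rownames label the nodes
#' @param mutation_counts optional per-cluster mutation counts appended to
#'   labels as `:n`
#' @return newick string, semicolon-terminated
#' @export
tree_newick <- function(parent, ccf, mutation_counts = NULL) {
  labels <- rownames(ccf) %||% paste0("C", seq_along(parent))
  if (!is.null(mutation_counts)) {
    labels <- paste0(labels, "_n", mutation_counts)
  }
  emit <- function(v) {
    ch <- which(parent == v)
    if (length(ch) == 0L) return(labels[v])
    paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")",
           labels[v])
  }
  paste0(emit(which(parent == 0L)), ";")
}

#' Detect parallel evolution of genes or pathways
#'
#' Reports every gene (or configured gene set) with at least two distinct
#' non-silent variants assigned to pairwise non-ancestral clusters whose
#' per-region CCF sums stay within 1 + tolerance — i.e. mutually exclusive
#' subclones independently converging on the same target.
#'
#' @param mut_df data.frame with one row per mutation: `mutation_id`, `gene`,
#'   `effect`, `cluster` (cluster index from [cluster_mutations()])
#' @param parent integer parent vector of the clone tree
#' @param ccf K x R cluster CCF matrix
#' @param gene_sets optional named list of gene vectors (e.g. a Wnt pathway
#'   set); when given, detection also runs at the set level
#' @param tolerance CCF slack for the mutual-exclusivity check
#' @return data.frame of events: `target`, `level`, `n_variants`,
#'   `variants`, `clusters` (comma-separated); zero rows when none
#' @export
detect_parallel_evolution <- function(mut_df, parent, ccf,
                                      gene_sets = NULL, tolerance = 0.05) {
  nonsilent <- mut_df[!mut_df$effect %in% c("silent") & mut_df$gene != "", ,
                      drop = FALSE]
  scan_target <- function(rows, target, level) {
    rows <- rows[!duplicated(rows$mutation_id), , drop = FALSE]
    if (nrow(rows) < 2L) return(NULL)
    cl <- unique(rows$cluster)
    if (length(cl) < 2L) return(NULL)
    # keep clusters that are pairwise non-ancestral
    pairs_ok <- outer(cl, cl, Vectorize(function(a, b) {
      a == b || (!is_ancestor(parent, a, b) && !is_ancestor(parent, b, a))
    }))
    if (!all(pairs_ok)) {
      # drop variants in ancestrally-related clusters; require >= 2 left
      keep <- cl[vapply(seq_along(cl), function(i) all(pairs_ok[i, ]),
                        logical(1))]
      cl <- keep
      rows <- rows[rows$cluster %in% cl, , drop = FALSE]
      if (length(cl) < 2L || nrow(rows) < 2L) return(NULL)
    }
    if (any(colSums(ccf[cl, , drop = FALSE]) > 1 + tolerance)) return(NULL)
    data.frame(target = target, level = level,
               n_variants = nrow(rows),
               variants = paste(rows$mutation_id, collapse = ","),
               clusters = paste(sort(cl), collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- lapply(split(nonsilent, nonsilent$gene), function(rows) {
    scan_target(rows, rows$gene[1], "gene")
  })
  if (!is.null(gene_sets)) {
    out <- c(out, lapply(names(gene_sets), function(nm) {
      rows <- nonsilent[nonsilent$gene %in% gene_sets[[nm]], , drop = FALSE]
      scan_target(rows, nm, "pathway")
    }))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(target = character(0), level = character(0),
                      n_variants = integer(0), variants = character(0),
                      clusters = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Timing tally of driver events across a cohort
#'
#' For each driver gene, the fraction of its events that are early: SNV
#' events count as early when their cluster is clonal, SCNA events when
#' their locus status is ubiquitous.
#'
#' @param snv_events data.frame with `gene` and `clonality`
#'   (`"clonal"`/`"subclonal"`), one row per SNV event per patient
#' @param scna_events optional data.frame with `gene` and `status`
#'   (`"ubiquitous"`/`"heterogeneous"`), one row per SCNA event per patient
#' @param driver_genes optional restriction to a gene list
#' @return data.frame: `gene`, `n_events`, `n_early`, `fraction_clonal`,
#'   sorted by decreasing fraction; genes with no events are omitted
#' @export
time_driver_events <- function(snv_events, scna_events = NULL,
                               driver_genes = NULL) {
  ev <- rbind(
    if (!is.null(snv_events) && nrow(snv_events))
      data.frame(gene = snv_events$gene,
                 early = snv_events$clonality == "clonal"),
    if (!is.null(scna_events) && nrow(scna_events))
      data.frame(gene = scna_events$gene,
                 early = scna_events$status == "ubiquitous")
  )
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(gene = character(0), n_events = integer(0),
                      n_early = integer(0), fraction_clonal = numeric(0)))
  }
  if (!is.null(driver_genes)) ev <- ev[ev$gene %in% driver_genes, ,
                                       drop = FALSE]
  agg <- do.call(rbind, lapply(split(ev, ev$gene), function(g) {
    data.frame(gene = g$gene[1], n_events = nrow(g),
               n_early = sum(g$early),
               fraction_clonal = mean(g$early), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$fraction_clonal, agg$gene), ]
  rownames(agg) <- NULL
  agg
}

#' Default Wnt pathway gene set
#' @return character vector
#' @export
default_wnt_gene_set <- function() {
  c("CTNNB1", "APC", "RSPO2", "RNF43", "ZNRF3")
}
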