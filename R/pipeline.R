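#' Run the full cohort analysis
#'
#' Ties the stages together for a cohort on disk or in memory: per-patient
#' heterogeneity profiles, cohort summaries and group comparisons, SNV/SCNA
#' heterogeneity correlation, genotype flags (Wnt, MMRD), immune summaries
#' and genotype-immune tests, locus enrichment, and (optionally) per-patient
#' mutation clustering with clone trees and parallel-evolution calls.
#'
#' @param variants cohort variant table
#' @param segments cohort segment table
#' @param sheet sample sheet list (`patients`, `regions`)
#' @param genome chromosome length table
#' @param target_mb sequenced target size (Mb) for mutation burden
#' @param locus_catalogue loci tested for group enrichment
#' @param catalogue signature catalogue for clonality attribution
#' @param cluster also run mutation clustering, clone trees and
#'   parallel-evolution detection per patient (slower)
#' @param max_clusters,seed clustering controls
#' @return nested results list (serialisable with [write_results()])
#' @export
run_cohort_analysis <- function(variants, segments, sheet,
                                genome = default_genome(), target_mb = 30,
                                locus_catalogue = default_locus_catalogue(),
                                catalogue = signature_catalogue_synthetic(),
                                cluster = FALSE, max_clusters = 6, seed = 1) {
  profiles <- build_patient_profiles(variants, segments, sheet, genome,
                                     target_mb)
  ids <- profiles$patient_id
  groups <- setNames(profiles$group, ids)
  g_levels <- unique(profiles$group)

  grp_test <- function(metric) {
    if (length(g_levels) != 2L) return(NULL)
    x <- profiles[[metric]][profiles$group == g_levels[1]]
    y <- profiles[[metric]][profiles$group == g_levels[2]]
    cmp <- compare_groups(x, y)
    list(groups = g_levels, mean = c(mean(x), mean(y)),
         sd = c(sd(x), sd(y)), U = cmp$U, p.value = cmp$p.value)
  }
  cohort <- list(
    n_patients = nrow(profiles),
    n_regions = sum(profiles$n_regions),
    total_snvs = sum(profiles$n_snv),
    snv_classes = c(ubiquitous = sum(profiles$n_ubiquitous),
                    shared = sum(profiles$n_shared),
                    private = sum(profiles$n_private)),
    burden_median = median(profiles$burden_per_mb),
    burden_range = range(profiles$burden_per_mb),
    fga_median = median(profiles$fga),
    fga_range = range(profiles$fga),
    het_scna_median = median(profiles$het_scna_fraction, na.rm = TRUE),
    het_scna_range = range(profiles$het_scna_fraction, na.rm = TRUE),
    fga_by_group = grp_test("fga"),
    burden_by_group = grp_test("burden_per_mb"),
    het_scna_by_group = grp_test("het_scna_fraction"),
    ith_correlation = tryCatch(
      correlate_ith(profiles$prop_nonubiquitous,
                    profiles$het_scna_fraction),
      mseqith_error = function(e) NULL)
  )

  # genotype flags + immune summaries per patient
  elig_thr <- inif_eligibility_threshold(sheet$regions$inif)
  per_patient <- lapply(ids, function(pid) {
    v <- variants[variants$patient_id == pid, , drop = FALSE]
    s <- segments[segments$patient_id == pid, , drop = FALSE]
    regs <- sheet$regions[sheet$regions$patient_id == pid, , drop = FALSE]
    wgd <- patient_wgd(s)
    wnt <- flag_wnt_activation(v, s, wgd_by_region = wgd$by_region)
    mmrd <- flag_mmrd(v, s, wgd_by_region = wgd$by_region)
    inif <- summarize_inif(regs$inif, eligibility_threshold = elig_thr)
    ratio <- suppressWarnings(cd8_foxp3_ratio(regs$cd8, regs$foxp3))
    list(wnt = wnt, mmrd = mmrd, inif = inif, ratio = ratio$ratio)
  })
  names(per_patient) <- ids

  wnt_flags <- vapply(per_patient, function(p) p$wnt$wnt_activated,
                      logical(1))
  eligible <- vapply(per_patient, function(p) p$inif$digital_eligible,
                     logical(1))
  ratios <- vapply(per_patient, function(p) p$ratio, numeric(1))
  immune <- list(
    eligibility_threshold = elig_thr,
    n_eligible = sum(eligible),
    n_extensive = sum(vapply(per_patient, function(p) p$inif$extensive,
                             logical(1))),
    ratio_by_wnt = tryCatch(
      compare_ratio_by_wnt(ratios, wnt_flags, eligible),
      mseqith_error = function(e) NULL),
    neoantigen_inif = tryCatch(
      associate_neoantigen_inif(
        sheet$patients$neoantigen_total,
        sheet$patients$neoantigen_clonal,
        vapply(per_patient, function(p) p$inif$max, numeric(1))),
      mseqith_error = function(e) NULL)
  )

  enrichment <- NULL
  if (length(g_levels) == 2L && nrow(locus_catalogue) > 0) {
    enrichment <- lapply(seq_len(nrow(locus_catalogue)), function(i) {
      locus <- locus_catalogue[i, ]
      status <- vapply(ids, function(pid) {
        s <- segments[segments$patient_id == pid, , drop = FALSE]
        call_locus_event(s, locus, locus$direction, genome = genome)
      }, character(1))
      ft <- enrichment_test(status, groups[ids])
      list(locus = locus$locus, direction = locus$direction,
           n_present = sum(status != "absent"),
           odds_ratio = ft$odds_ratio, p.value = ft$p.value)
    })
    names(enrichment) <- locus_catalogue$locus
  }

  clustering <- NULL
  if (cluster) {
    clustering <- lapply(ids, function(pid) {
      v <- variants[variants$patient_id == pid, , drop = FALSE]
      regs <- sheet$regions[sheet$regions$patient_id == pid, , drop = FALSE]
      cl <- cluster_patient(v, setNames(regs$purity, regs$region_id),
                            max_clusters = max_clusters, seed = seed)
      tree <- tryCatch(build_clone_tree(cl$clusters$ccf),
                       mseqith_error = function(e) NULL)
      events <- if (!is.null(tree)) {
        detect_parallel_evolution(cl$mut_df, tree$trees[[1]],
                                  tree$ccf,
                                  gene_sets = list(Wnt = default_wnt_gene_set()))
      } else NULL
      list(K = cl$clusters$K,
           clonality = cl$clusters$clonality,
           newick = if (!is.null(tree))
             tree_newick(tree$trees[[1]], tree$ccf) else NA_character_,
           n_admissible_trees = if (!is.null(tree)) tree$n_trees else 0L,
           parallel_events = events)
    })
    names(clustering) <- ids
  }

  list(profiles = profiles, cohort = cohort, immune = immune,
       enrichment = enrichment, per_patient = per_patient,
       clustering = clustering)
}

#' Cluster one patient's mutations from a variant table
#'
#' Reshapes the long variant table into mutation x region count matrices
#' (using local copy number and multiplicity columns when present) and runs
#' [cluster_mutations()].
#'
#' @param variants variant table for one patient
#' @param purity named purity vector (region id -> purity)
#' @param ... passed to [cluster_mutations()]
#' @return list: `clusters` (a `ccf_clusters`), `mut_df` (mutation-level
#'   data.frame with gene/effect/cluster for parallel-evolution detection)
#' @export
cluster_patient <- function(variants, purity, ...) {
  mid <- mutation_key(variants)
  regions <- sort(unique(variants$region_id))
  mids <- unique(mid)
  shape <- function(col, default) {
    m <- matrix(default, length(mids), length(regions),
                dimnames = list(mids, regions))
    m[cbind(match(mid, mids), match(variants$region_id, regions))] <-
      variants[[col]]
    m
  }
  alt <- shape("alt_count", 0)
  depth <- alt + shape("ref_count", 0)
  depth[depth == 0] <- 1  # unassayed cells contribute a vacuous term
  cn <- if ("cn_total" %in% names(variants)) shape("cn_total", 2)
        else matrix(2, length(mids), length(regions))
  mult <- if ("multiplicity" %in% names(variants)) shape("multiplicity", 1)
          else matrix(1, length(mids), length(regions))
  cl <- cluster_mutations(alt, depth, purity[regions], cn, mult, ...)
  first <- variants[!duplicated(mid), , drop = FALSE]
  mut_df <- data.frame(
    mutation_id = mids,
    gene = first$gene[match(mids, mid[!duplicated(mid)])],
    effect = first$effect[match(mids, mid[!duplicated(mid)])],
    cluster = cl$assignment,
    stringsAsFactors = FALSE
  )
  list(clusters = cl, mut_df = mut_df)
}
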