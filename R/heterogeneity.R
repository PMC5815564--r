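#' SNV and SCNA intratumoural heterogeneity metrics
#'
#' Per-patient quantification of heterogeneity across tumour regions:
#' classification of each mutation as ubiquitous (present in every assessable
#' region), shared (more than one but not all) or private (exactly one);
#' exonic mutation burden per Mb; fraction of genome altered (FGA) by copy
#' number in any region; the fraction of altered bases whose alteration is
#' heterogeneous across regions; whole-genome doubling calls; and the
#' cohort-level correlation and group-comparison statistics.
#'
#' @name heterogeneity
NULL

#' Presence call for one observation
#'
#' A mutation is called present in a region when it has at least `min_alt`
#' alt reads and VAF at least `min_vaf`. Naive absence calls inflate the
#' private class at low depth, so absence is only accepted in regions that
#' are assessable: the local depth must give at least `power_threshold`
#' probability of detection were the mutation clonal there.
#'
#' @param alt,depth vectors of alt and total read counts across regions
#' @param clonal_vaf expected VAF of a clonal mutation in each region
#'   (typically purity/2 at a diploid locus)
#' @param min_alt,min_vaf detection thresholds
#' @param power_threshold required detection power for absence calls
#' @return list with logical vectors `present` and `assessable`
#' @export
presence_call <- function(alt, depth, clonal_vaf, min_alt = 2,
                          min_vaf = 0.02, power_threshold = 0.95) {
  vaf <- ifelse(depth > 0, alt / depth, 0)
  present <- alt >= min_alt & vaf >= min_vaf
  k <- pmax(min_alt, ceiling(min_vaf * depth))
  power <- 1 - pbinom(k - 1, depth, pmin(clonal_vaf, 1))
  assessable <- present | power >= power_threshold
  list(present = present, assessable = assessable)
}

#' Classify a mutation as ubiquitous, shared or private
#'
#' Uses only assessable regions: present in all of them is ubiquitous, in
#' at least two but not all is shared, in exactly one is private.
#'
#' @inheritParams presence_call
#' @return one of `"ubiquitous"`, `"shared"`, `"private"`
#' @export
classify_presence <- function(alt, depth, clonal_vaf, min_alt = 2,
                              min_vaf = 0.02, power_threshold = 0.95) {
  pc <- presence_call(alt, depth, clonal_vaf, min_alt, min_vaf,
                      power_threshold)
  n_present <- sum(pc$present)
  if (n_present == 0L) {
    msq_stop("mutation present in no region", "invalid_input")
  }
  n_assessable <- sum(pc$assessable)
  if (n_present == n_assessable) "ubiquitous"
  else if (n_present >= 2L) "shared"
  else "private"
}

#' Classify every mutation of one patient
#'
#' @param variants variant table restricted to one patient (one row per
#'   mutation x region; absent assays have 0 alt reads)
#' @param purity named purity vector (names = region ids)
#' @param ... thresholds passed to [classify_presence()]
#' @return data.frame with one row per mutation: `mutation_id`, `class`,
#'   `n_regions_present`
#' @export
classify_patient_presence <- function(variants, purity, ...) {
  mid <- mutation_key(variants)
  regions <- sort(unique(variants$region_id))
  clonal_vaf <- purity[regions] / 2
  out <- lapply(split(seq_len(nrow(variants)), mid), function(idx) {
    v <- variants[idx, ]
    v <- v[match(regions, v$region_id), ]
    alt <- ifelse(is.na(v$alt_count), 0L, v$alt_count)
    depth <- ifelse(is.na(v$alt_count), 0L, v$alt_count + v$ref_count)
    pc <- presence_call(alt, depth, clonal_vaf, ...)
    # a mutation detected in no region was never called: not part of the set
    if (sum(pc$present) == 0L) return(NULL)
    cls <- classify_presence(alt, depth, clonal_vaf, ...)
    data.frame(class = cls, n_regions_present = sum(pc$present))
  })
  out <- Filter(Negate(is.null), out)
  data.frame(mutation_id = names(out),
             class = vapply(out, `[[`, "", "class"),
             n_regions_present = vapply(out, `[[`, 0, "n_regions_present"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canonical mutation identifier within a patient
#' @param variants variant table
#' @return character vector `chrom:pos:ref:alt`
#' @export
mutation_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Exonic SNV burden per megabase
#'
#' @param n_mutations number of distinct exonic SNVs in the patient's
#'   region union
#' @param target_mb size of the sequenced target in Mb (> 0)
#' @return mutations per Mb
#' @export
snv_burden <- function(n_mutations, target_mb) {
  assert_scalar_in(target_mb, 0, Inf, "target_mb", lo_open = TRUE)
  n_mutations / target_mb
}

# neutral total copy number for a region: 2, or 4 under whole-genome doubling
neutral_cn_for <- function(region_id, wgd_by_region) {
  if (!is.null(wgd_by_region) && isTRUE(wgd_by_region[region_id])) 4 else 2
}

# altered intervals of one region with direction, as a plain data.frame
altered_df <- function(seg_region, neutral) {
  tot <- seg_region$major_cn + seg_region$minor_cn
  altered <- seg_region[tot != neutral, , drop = FALSE]
  data.frame(
    chrom = altered$chrom, start = altered$start, end = altered$end,
    direction = ifelse(altered$major_cn + altered$minor_cn > neutral,
                       "gain", "loss"),
    region_id = altered$region_id, stringsAsFactors = FALSE
  )
}

# altered intervals across all regions of one patient, as one GRanges
patient_altered_granges <- function(segments, wgd_by_region) {
  dfs <- lapply(split(segments, segments$region_id), function(seg_r) {
    altered_df(seg_r, neutral_cn_for(seg_r$region_id[1], wgd_by_region))
  })
  df <- do.call(rbind, dfs)
  gr <- segments_to_granges(df)
  S4Vectors::mcols(gr)$direction <- df$direction
  S4Vectors::mcols(gr)$region_id <- df$region_id
  gr
}

#' Fraction of genome altered (FGA)
#'
#' Union across all of a patient's regions of the bases whose total copy
#' number differs from the neutral baseline (2, or 4 in regions called
#' whole-genome doubled), divided by the assessable genome length. Sex
#' chromosomes are excluded from the denominator by default.
#'
#' @param segments segment table for one patient (all regions)
#' @param genome data.frame of chromosome lengths (denominator)
#' @param wgd_by_region optional named logical vector of per-region WGD calls
#' @param exclude_sex drop chrX/chrY from numerator and denominator
#' @return fraction in `[0, 1]`
#' @export
compute_fga <- function(segments, genome = default_genome(),
                        wgd_by_region = NULL, exclude_sex = TRUE) {
  if (is.null(segments) || nrow(segments) == 0L) {
    msq_stop("empty segment set: cannot distinguish neutral from missing",
             "invalid_input")
  }
  if (exclude_sex) {
    genome <- genome[!genome$chrom %in% c("chrX", "chrY", "X", "Y"), ]
    segments <- segments[segments$chrom %in% genome$chrom, , drop = FALSE]
  }
  union_gr <- GenomicRanges::reduce(
    patient_altered_granges(segments, wgd_by_region))
  total_width(union_gr) / sum(as.numeric(genome$length))
}

#' Heterogeneous fraction of the SCNA burden
#'
#' Builds breakpoint-union intervals over all regions and classifies every
#' altered base: an altered base is homogeneous only when all regions carry
#' an alteration of the same direction (gain or loss) there; gain in one
#' region with loss in another, or alteration in only some regions, is
#' heterogeneous. Returns heterogeneous bases / altered-in-any-region bases.
#'
#' @inheritParams compute_fga
#' @return fraction in `[0, 1]`, or `NA` with a warning for single-region
#'   patients
#' @export
scna_heterogeneous_fraction <- function(segments, wgd_by_region = NULL,
                                        exclude_sex = TRUE) {
  if (exclude_sex) {
    segments <- segments[!segments$chrom %in% c("chrX", "chrY", "X", "Y"), ,
                         drop = FALSE]
  }
  regions <- unique(segments$region_id)
  if (length(regions) < 2L) {
    msq_warn("heterogeneous SCNA fraction undefined for a single region",
             "single_region")
    return(NA_real_)
  }
  all_alt <- patient_altered_granges(segments, wgd_by_region)
  if (length(all_alt) == 0L) return(0)
  pieces <- GenomicRanges::disjoin(all_alt)
  # per piece, the direction seen in each region ("" = not altered there)
  dir_mat <- vapply(regions, function(r) {
    gr <- all_alt[S4Vectors::mcols(all_alt)$region_id == r]
    d <- rep("", length(pieces))
    hits <- GenomicRanges::findOverlaps(pieces, gr)
    # pieces derive from the breakpoint union, so each piece meets at most
    # one altered interval per region over its full width
    d[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(gr)$direction[S4Vectors::subjectHits(hits)]
    d
  }, character(length(pieces)))
  dir_mat <- matrix(dir_mat, nrow = length(pieces))
  homogeneous <- apply(dir_mat, 1, function(d) {
    all(d != "") && length(unique(d)) == 1L
  })
  w <- as.numeric(IRanges::width(pieces))
  sum(w[!homogeneous]) / sum(w)
}

#' Call whole-genome doubling for one region
#'
#' A region is WGD when more than half of its segmented genome has major
#' allele copy number of at least 2.
#'
#' @param seg_region segment table for one region
#' @return logical
#' @export
call_wgd <- function(seg_region) {
  w <- as.numeric(seg_region$end - seg_region$start + 1)
  sum(w[seg_region$major_cn >= 2]) / sum(w) > 0.5
}

#' Patient-level whole-genome doubling status
#'
#' @param segments segment table for one patient
#' @return list with named logical `by_region` and `status`
#'   (`"none"`, `"homogeneous"` or `"heterogeneous"`)
#' @export
patient_wgd <- function(segments) {
  by_region <- vapply(split(segments, segments$region_id), call_wgd,
                      logical(1))
  status <- if (all(by_region)) "homogeneous"
            else if (any(by_region)) "heterogeneous"
            else "none"
  list(by_region = by_region, status = status)
}

#' Correlation between SNV and SCNA heterogeneity across patients
#'
#' Pearson correlation (with the t-distribution p-value) between the
#' proportion of non-ubiquitous SNVs and the heterogeneous SCNA fraction.
#'
#' @param prop_nonubiquitous,het_scna_fraction per-patient metric vectors
#' @return list with `r`, `p.value`, `n`
#' @export
correlate_ith <- function(prop_nonubiquitous, het_scna_fraction) {
  keep <- stats::complete.cases(prop_nonubiquitous, het_scna_fraction)
  x <- prop_nonubiquitous[keep]; y <- het_scna_fraction[keep]
  if (length(x) < 3L) msq_stop("need >= 3 patients with both metrics",
                               "invalid_input")
  if (sd(x) == 0 || sd(y) == 0) {
    msq_stop("zero variance in a heterogeneity metric: correlation undefined",
             "undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Mann-Whitney U comparison of two clinical groups
#'
#' Exact two-sided p by full enumeration of all rank assignments when
#' `min(n1, n2) <= exact_max` (ties handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction. The exact
#' two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))` over the
#' enumerated permutation distribution of U.
#'
#' @param x,y numeric vectors for the two groups
#' @param exact_max largest smaller-group size for which the exact path runs
#' @return list with `U` (statistic for `x`), `p.value`, `method`
#' @export
compare_groups <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) msq_stop("both groups must be non-empty",
                                     "invalid_input")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    msq_warn("all values tied across groups", "all_tied")
    return(list(U = U, p.value = 1, method = "degenerate"))
  }
  if (min(n1, n2) <= exact_max) {
    # exact permutation distribution of the rank sum over all
    # choose(n1+n2, n1) group assignments, counted by dynamic programming
    # over doubled ranks (so midranks from ties stay integral)
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    counts <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
    counts[1, 1] <- 1
    for (v in r2) {
      kmax <- n1
      for (k in kmax:1) {
        nz <- which(counts[k, ] > 0)
        nz <- nz[nz + v <= smax + 1]
        counts[k + 1, nz + v] <- counts[k + 1, nz + v] + counts[k, nz]
      }
    }
    dist_s <- counts[n1 + 1, ]
    total <- sum(dist_s)
    s_obs <- as.integer(round(2 * (U + n1 * (n1 + 1) / 2)))
    sums <- seq_len(smax + 1) - 1L
    p_le <- sum(dist_s[sums <= s_obs]) / total
    p_ge <- sum(dist_s[sums >= s_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(U = U, p.value = p, method = "exact enumeration")
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation with tie correction")
  }
}

#' Build per-patient heterogeneity profiles for a cohort
#'
#' Runs presence classification, burden, FGA, heterogeneous SCNA fraction
#' and WGD calling for every patient and joins the clinical annotations.
#'
#' @param variants cohort variant table
#' @param segments cohort segment table
#' @param sheet sample sheet (list of `patients` and `regions` data frames)
#' @param genome chromosome length table for the FGA denominator
#' @param target_mb sequenced target size in Mb for the burden
#' @return data.frame, one row per patient
#' @export
build_patient_profiles <- function(variants, segments, sheet,
                                   genome = default_genome(),
                                   target_mb = 30) {
  validate_cohort(variants, segments, sheet)
  ids <- sheet$patients$patient_id
  rows <- lapply(ids, function(pid) {
    v <- variants[variants$patient_id == pid, , drop = FALSE]
    s <- segments[segments$patient_id == pid, , drop = FALSE]
    regs <- sheet$regions[sheet$regions$patient_id == pid, , drop = FALSE]
    purity <- setNames(regs$purity, regs$region_id)
    cls <- classify_patient_presence(v, purity)
    tab <- table(factor(cls$class,
                        levels = c("ubiquitous", "shared", "private")))
    wgd <- patient_wgd(s)
    data.frame(
      patient_id = pid,
      n_regions = nrow(regs),
      n_snv = nrow(cls),
      n_ubiquitous = as.integer(tab["ubiquitous"]),
      n_shared = as.integer(tab["shared"]),
      n_private = as.integer(tab["private"]),
      prop_nonubiquitous = 1 - as.integer(tab["ubiquitous"]) / nrow(cls),
      burden_per_mb = snv_burden(nrow(cls), target_mb),
      fga = compute_fga(s, genome, wgd_by_region = wgd$by_region),
      het_scna_fraction = scna_heterogeneous_fraction(
        s, wgd_by_region = wgd$by_region),
      wgd_status = wgd$status,
      group = sheet$patients$group[sheet$patients$patient_id == pid],
      gleason = sheet$patients$gleason[sheet$patients$patient_id == pid],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
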