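#' Genotype-immune associations
#'
#' Summarises per-region inflammatory infiltrate (INIF, percent of nucleated
#' cells) and T-cell counts into patient-level immune profiles, derives
#' genotype flags (Wnt-pathway activation, mismatch-repair deficiency) from
#' variants and copy-number segments, and tests genotype-immune associations:
#' the CD8+/FOXP3+ ratio contrast between Wnt-activated and wild-type
#' tumours, and neoantigen-burden/INIF correlations.
#'
#' @name immune_genomics
NULL

#' Summarise INIF across the regions of one patient
#'
#' @param inif vector of per-region INIF percentages (0-100)
#' @param extensive_threshold maximal-infiltrate percent above which the
#'   patient is flagged extensive (default 20)
#' @param eligibility_threshold INIF percent at or above which any one
#'   region makes the patient eligible for digital image analysis (default
#'   8, the cohort median; see [inif_eligibility_threshold()])
#' @return list: `max`, `mean`, `range`, `extensive`, `digital_eligible`
#' @export
summarize_inif <- function(inif, extensive_threshold = 20,
                           eligibility_threshold = 8) {
  if (length(inif) == 0L || any(is.na(inif))) {
    msq_stop("need at least one region with a non-missing INIF",
             "invalid_input")
  }
  if (any(inif < 0 | inif > 100)) {
    msq_stop("INIF must lie in [0, 100]", "validation_error")
  }
  list(max = max(inif), mean = mean(inif), range = range(inif),
       extensive = max(inif) > extensive_threshold,
       digital_eligible = any(inif >= eligibility_threshold))
}

#' Cohort-median INIF eligibility threshold
#'
#' The digital-analysis eligibility cut is the median INIF over all regions
#' of the cohort; recomputing it on the cohort reproduces a fixed threshold
#' when the cohort median equals it.
#'
#' @param inif_all vector of all per-region INIF values in the cohort
#' @return the median
#' @export
inif_eligibility_threshold <- function(inif_all) {
  median(inif_all, na.rm = TRUE)
}

#' Patient-level CD8+/FOXP3+ ratio
#'
#' Default pooling sums counts across the supplied regions and then divides
#' (robust to zero FOXP3 counts in single regions); per-region ratios are
#' reported alongside. A patient with zero total FOXP3 has no defined ratio.
#'
#' @param cd8,foxp3 per-region cell counts
#' @return list: `ratio` (pooled; NA with a warning when FOXP3 total is 0),
#'   `per_region`
#' @export
cd8_foxp3_ratio <- function(cd8, foxp3) {
  if (any(cd8 < 0 | foxp3 < 0)) {
    msq_stop("cell counts must be nonnegative", "validation_error")
  }
  per_region <- ifelse(foxp3 > 0, cd8 / foxp3, NA_real_)
  if (sum(foxp3) == 0) {
    msq_warn("total FOXP3 count is 0: ratio undefined", "undefined_ratio")
    return(list(ratio = NA_real_, per_region = per_region))
  }
  list(ratio = sum(cd8) / sum(foxp3), per_region = per_region)
}

#' Flag somatic Wnt-pathway activation for one patient
#'
#' True when any region carries: a CTNNB1 variant whose protein change is in
#' the configured exon-3 gain-of-function list; or RSPO2 amplification
#' (total copy number at least `amp_factor` times the region's neutral
#' baseline); or a homozygous deletion (total copy number 0) overlapping
#' APC, RNF43 or ZNRF3. Evidence strings are recorded for every qualifying
#' event, so adding events can never turn a true flag false.
#'
#' @param variants patient variant table (uses `gene`, `effect`,
#'   `protein_change` if present)
#' @param segments patient segment table
#' @param gene_coords gene coordinate table (see [default_gene_coords()])
#' @param gof_variants CTNNB1 gain-of-function protein changes
#' @param amp_factor RSPO2 amplification threshold as a multiple of the
#'   neutral baseline (default 2)
#' @param wgd_by_region optional per-region WGD calls (baseline 4)
#' @return list: `wnt_activated` (logical), `evidence` (character vector)
#' @export
flag_wnt_activation <- function(variants, segments,
                                gene_coords = default_gene_coords(),
                                gof_variants = default_wnt_gof_variants(),
                                amp_factor = 2, wgd_by_region = NULL) {
  evidence <- character(0)
  need <- c("CTNNB1", "RSPO2", "APC", "RNF43", "ZNRF3")
  missing <- setdiff(need, gene_coords$gene)
  if (length(missing) > 0L) {
    msq_stop(sprintf("gene coordinates missing for: %s",
                     paste(missing, collapse = ", ")), "invalid_parameter")
  }
  pc <- variants$protein_change
  if (!is.null(pc) && nrow(variants) > 0) {
    hit <- variants$gene == "CTNNB1" & pc %in% gof_variants &
      variants$effect != "silent" & variants$alt_count > 0
    if (any(hit)) {
      v <- variants[hit, , drop = FALSE]
      evidence <- c(evidence, unique(sprintf(
        "CTNNB1 %s (%s)", v$protein_change, mutation_key(v))))
    }
  }
  gene_hits <- function(gene, test) {
    gc <- gene_coords[gene_coords$gene == gene, ]
    on_gene <- segments$chrom == gc$chrom & segments$start <= gc$end &
      segments$end >= gc$start
    seg <- segments[on_gene, , drop = FALSE]
    if (nrow(seg) == 0L) return(character(0))
    neutral <- vapply(seg$region_id, function(r) {
      neutral_cn_for(r, wgd_by_region)
    }, numeric(1))
    tot <- seg$major_cn + seg$minor_cn
    sel <- test(tot, neutral)
    if (!any(sel)) return(character(0))
    sprintf("%s %s total_cn=%g in %s", gene,
            ifelse(tot[sel] > neutral[sel], "amplification", "deletion"),
            tot[sel], seg$region_id[sel])
  }
  evidence <- c(evidence,
                gene_hits("RSPO2", function(tot, neutral)
                  tot >= amp_factor * neutral))
  for (g in c("APC", "RNF43", "ZNRF3")) {
    evidence <- c(evidence, gene_hits(g, function(tot, neutral) tot == 0))
  }
  list(wnt_activated = length(evidence) > 0L, evidence = evidence)
}

#' Flag mismatch-repair deficiency for one patient
#'
#' An MMR gene is biallelically inactivated when it accumulates two hits,
#' where a hit is a deleterious variant (germline or somatic; missense,
#' nonsense or frameshift) or a deletion overlapping the gene (a homozygous
#' deletion, total copy number 0, counts as two hits; a heterozygous loss
#' counts as one). Single-hit genes are reported as monoallelic, not MMRD.
#'
#' @param variants patient variant table including germline rows
#'   (`germline_flag`)
#' @param segments patient segment table
#' @param gene_coords gene coordinate table
#' @param mmr_genes MMR gene set (default MLH1, MSH2, MSH6, PMS2)
#' @param wgd_by_region optional per-region WGD calls
#' @return list: `mmrd` (logical), `evidence`, `monoallelic` (genes with
#'   exactly one hit)
#' @export
flag_mmrd <- function(variants, segments,
                      gene_coords = default_gene_coords(),
                      mmr_genes = default_mmr_genes(),
                      wgd_by_region = NULL) {
  evidence <- character(0)
  mono <- character(0)
  mmrd <- FALSE
  for (g in mmr_genes) {
    gc <- gene_coords[gene_coords$gene == g, ]
    if (nrow(gc) == 0L) next
    hits <- 0
    ev_g <- character(0)
    if (nrow(variants) > 0) {
      del_var <- variants$gene == g &
        variants$effect %in% c("missense", "nonsense", "frameshift") &
        variants$alt_count > 0
      vv <- variants[del_var, , drop = FALSE]
      vv <- vv[!duplicated(mutation_key(vv)), , drop = FALSE]
      hits <- hits + nrow(vv)
      if (nrow(vv) > 0) {
        ev_g <- c(ev_g, sprintf("%s %s %s variant (%s)", g, vv$effect,
                                ifelse(vv$germline_flag, "germline",
                                       "somatic"),
                                mutation_key(vv)))
      }
    }
    on_gene <- segments$chrom == gc$chrom & segments$start <= gc$end &
      segments$end >= gc$start
    seg <- segments[on_gene, , drop = FALSE]
    if (nrow(seg) > 0) {
      neutral <- vapply(seg$region_id, function(r) {
        neutral_cn_for(r, wgd_by_region)
      }, numeric(1))
      tot <- seg$major_cn + seg$minor_cn
      # one deletion event per distinct interval, not per region
      dels <- unique(data.frame(start = seg$start, end = seg$end,
                                tot = tot)[tot < neutral, , drop = FALSE])
      if (nrow(dels) > 0) {
        n_del_hits <- sum(ifelse(dels$tot == 0, 2, 1))
        hits <- hits + n_del_hits
        ev_g <- c(ev_g, sprintf("%s %s deletion %g-%g", g,
                                ifelse(dels$tot == 0, "homozygous",
                                       "heterozygous"),
                                dels$start, dels$end))
      }
    }
    if (hits >= 2) {
      mmrd <- TRUE
      evidence <- c(evidence, ev_g)
    } else if (hits == 1) {
      mono <- c(mono, g)
    }
  }
  list(mmrd = mmrd, evidence = evidence, monoallelic = mono)
}

#' Neoantigen burden vs INIF association
#'
#' Spearman correlations of total and clonal neoantigen burden against the
#' per-patient maximal INIF.
#'
#' @param total_burden,clonal_burden per-patient neoantigen counts
#' @param max_inif per-patient maximal INIF percent
#' @return data.frame with one row per burden type: `rho`, `p.value`, `n`
#' @export
associate_neoantigen_inif <- function(total_burden, clonal_burden, max_inif) {
  if (sum(complete.cases(total_burden, max_inif)) < 3L) {
    msq_stop("need >= 3 patients", "invalid_input")
  }
  one <- function(burden, label) {
    keep <- complete.cases(burden, max_inif)
    ct <- suppressWarnings(cor.test(burden[keep], max_inif[keep],
                                    method = "spearman"))
    data.frame(burden = label, rho = unname(ct$estimate),
               p.value = ct$p.value, n = sum(keep),
               stringsAsFactors = FALSE)
  }
  rbind(one(total_burden, "total"), one(clonal_burden, "clonal"))
}

#' Compare CD8+/FOXP3+ ratios between Wnt-activated and wild-type patients
#'
#' Restricted to digital-analysis-eligible patients (INIF at or above the
#' cohort-median threshold in at least one region) with a defined pooled
#' ratio; the comparison itself routes through [compare_groups()].
#'
#' @param ratio per-patient pooled CD8/FOXP3 ratios
#' @param wnt per-patient logical Wnt-activation flags
#' @param eligible per-patient logical digital-eligibility flags
#' @return list: `n_wnt`, `n_wt`, `mean_wnt`, `mean_wt`, `U`, `p.value`
#' @export
compare_ratio_by_wnt <- function(ratio, wnt, eligible = NULL) {
  if (is.null(eligible)) eligible <- rep(TRUE, length(ratio))
  keep <- eligible & !is.na(ratio)
  x <- ratio[keep & wnt]
  y <- ratio[keep & !wnt]
  if (length(x) == 0L || length(y) == 0L) {
    msq_stop("a Wnt group is empty among eligible patients", "invalid_input")
  }
  cmp <- compare_groups(x, y)
  list(n_wnt = length(x), n_wt = length(y),
       mean_wnt = mean(x), mean_wt = mean(y),
       U = cmp$U, p.value = cmp$p.value)
}
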