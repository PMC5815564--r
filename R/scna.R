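#' Recurrent SCNA locus calling and group enrichment
#'
#' Calls previously identified focal/arm-level copy-number events per patient
#' (a region carries the event when at least half the locus is altered in the
#' event's direction) and tests enrichment between clinical groups with a
#' Fisher exact test, plus a permutation test that controls for each
#' patient's genome-wide copy-number burden by randomly re-placing their
#' altered segments (lengths preserved) and re-calling the locus.
#'
#' @name scna_enrichment
NULL

# bases of `locus` covered by qualifying segments in one region
locus_covered_bases <- function(seg_region, locus, direction, neutral) {
  tot <- seg_region$major_cn + seg_region$minor_cn
  qual <- if (direction == "gain") seg_region[tot > neutral, , drop = FALSE]
          else seg_region[tot < neutral, , drop = FALSE]
  qual <- qual[qual$chrom == locus$chrom, , drop = FALSE]
  if (nrow(qual) == 0L) return(0)
  ir <- IRanges::IRanges(qual$start, qual$end)
  hit <- IRanges::intersect(IRanges::reduce(ir),
                            IRanges::IRanges(locus$start, locus$end))
  sum(as.numeric(IRanges::width(hit)))
}

#' Call a locus-level SCNA event for one patient
#'
#' A region carries the event when qualifying segments (total copy number
#' above neutral for gains, below for losses) cover at least
#' `overlap_threshold` of the locus. Patient status is `"ubiquitous"` (all
#' regions), `"heterogeneous"` (some), or `"absent"` (none).
#'
#' @param segments segment table for one patient
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`
#' @param direction `"gain"` or `"loss"`
#' @param wgd_by_region optional named per-region WGD calls (neutral = 4)
#' @param overlap_threshold fraction of the locus that must be covered
#' @param genome genome table used to verify the locus lies on a configured
#'   chromosome
#' @return one of `"ubiquitous"`, `"heterogeneous"`, `"absent"`
#' @export
call_locus_event <- function(segments, locus, direction = "gain",
                             wgd_by_region = NULL, overlap_threshold = 0.5,
                             genome = default_genome()) {
  if (!locus$chrom %in% genome$chrom) {
    msq_stop(sprintf("locus chromosome %s is not in the configured genome",
                     locus$chrom), "invalid_parameter")
  }
  locus_len <- locus$end - locus$start + 1
  carries <- vapply(split(segments, segments$region_id), function(seg_r) {
    neutral <- neutral_cn_for(seg_r$region_id[1], wgd_by_region)
    locus_covered_bases(seg_r, locus, direction, neutral) >=
      overlap_threshold * locus_len
  }, logical(1))
  if (all(carries)) "ubiquitous"
  else if (any(carries)) "heterogeneous"
  else "absent"
}

#' Fisher exact enrichment test for one locus
#'
#' Collapses per-patient status to present (ubiquitous or heterogeneous) vs
#' absent and tests the 2x2 table of status by clinical group.
#'
#' @param status character vector of per-patient locus status
#' @param group character vector of clinical groups (2 levels)
#' @return list with `table`, `odds_ratio`, `p.value`
#' @export
enrichment_test <- function(status, group) {
  levels_g <- unique(group)
  if (length(levels_g) != 2L || any(table(group) == 0)) {
    msq_stop("need two non-empty groups", "invalid_input")
  }
  present <- factor(status != "absent", levels = c(TRUE, FALSE))
  tab <- table(present, factor(group, levels = levels_g))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p.value = ft$p.value)
}

# union length of intervals [starts, ends] (1-based inclusive)
union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

#' Burden-controlled permutation test for locus enrichment
#'
#' The Fisher test conflates locus-specific enrichment with genome-wide SCNA
#' burden differences between groups. This test conditions on each patient's
#' altered-segment length spectrum: in every permutation, each patient's
#' altered segments are re-placed uniformly at random on the genome (lengths
#' and copy numbers preserved, independently per region), the locus is
#' re-called, and the group difference in locus frequency is recomputed.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param segments cohort segment table
#' @param group named character vector: patient id -> clinical group
#' @param locus locus definition (`chrom`, `start`, `end`)
#' @param direction `"gain"` or `"loss"`
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @param wgd_by_patient optional list of per-region WGD calls by patient
#' @param genome genome table for re-placement
#' @param overlap_threshold locus coverage threshold
#' @return list with `observed_diff`, `p.value`, `null_diffs`,
#'   `freq_by_group`
#' @export
burden_controlled_enrichment <- function(segments, group, locus,
                                         direction = "gain", n_perm = 1000,
                                         seed = 1, wgd_by_patient = NULL,
                                         genome = default_genome(),
                                         overlap_threshold = 0.5) {
  if (n_perm < 100) msq_stop("n_perm must be >= 100", "invalid_parameter")
  set.seed(as.integer(seed))
  ids <- names(group)
  g_levels <- unique(group)
  seg_by_pat <- split(segments, segments$patient_id)[ids]

  locus_freq_diff <- function(status_by_pat) {
    present <- status_by_pat != "absent"
    f1 <- mean(present[group == g_levels[1]])
    f2 <- mean(present[group == g_levels[2]])
    f1 - f2
  }
  call_all <- function(segs_list) {
    vapply(ids, function(pid) {
      call_locus_event(segs_list[[pid]], locus, direction,
                       wgd_by_region = wgd_by_patient[[pid]],
                       overlap_threshold = overlap_threshold,
                       genome = genome)
    }, character(1))
  }
  obs_status <- call_all(seg_by_pat)
  obs <- locus_freq_diff(obs_status)

  # flatten every direction-qualifying altered segment across the cohort:
  # only these can cover the locus after re-placement
  qual <- do.call(rbind, lapply(ids, function(pid) {
    seg_p <- seg_by_pat[[pid]]
    do.call(rbind, lapply(split(seg_p, seg_p$region_id), function(seg_r) {
      neutral <- neutral_cn_for(seg_r$region_id[1],
                                wgd_by_patient[[pid]])
      tot <- seg_r$major_cn + seg_r$minor_cn
      keep <- if (direction == "gain") tot > neutral else tot < neutral
      if (!any(keep)) return(NULL)
      data.frame(pid = pid, rid = seg_r$region_id[1],
                 len = seg_r$end[keep] - seg_r$start[keep] + 1,
                 stringsAsFactors = FALSE)
    }))
  }))
  locus_len <- locus$end - locus$start + 1
  need <- overlap_threshold * locus_len
  locus_ci <- match(locus$chrom, genome$chrom)
  null_diffs <- numeric(n_perm)

  if (is.null(qual) || nrow(qual) == 0L) {
    null_diffs[] <- locus_freq_diff(setNames(rep("absent", length(ids)), ids))
  } else {
    # per segment: cumulative placement room over chromosomes, so a single
    # uniform draw maps to (chromosome, start) with length preserved
    room <- outer(qual$len, genome$length,
                  function(l, L) pmax(L - l + 1, 0))
    cumroom <- t(apply(room, 1, cumsum))
    total_room <- cumroom[, ncol(cumroom)]
    region_key <- paste(qual$pid, qual$rid, sep = "\r")
    region_f <- factor(region_key)
    pid_of_region <- qual$pid[!duplicated(region_key)]
    names(pid_of_region) <- region_key[!duplicated(region_key)]
    nq <- nrow(qual)
    for (b in seq_len(n_perm)) {
      u <- runif(nq) * total_room
      ci <- rowSums(cumroom < u) + 1L
      prev <- ifelse(ci > 1L, cumroom[cbind(seq_len(nq), pmax(ci - 1L, 1L))],
                     0)
      start <- floor(u - prev) + 1
      end <- start + qual$len - 1
      on_locus <- ci == locus_ci
      inter <- pmax(0, pmin(end, locus$end) - pmax(start, locus$start) + 1) *
        on_locus
      cov <- tapply(inter, region_f, sum)
      # exact union where multiple placed segments hit the locus together
      multi <- names(cov)[cov >= need]
      for (k in multi) {
        sel <- which(region_key == k & inter > 0)
        if (length(sel) > 1L) {
          cov[k] <- union_length(pmax(start[sel], locus$start),
                                 pmin(end[sel], locus$end))
        }
      }
      carries_region <- cov >= need
      present_pid <- tapply(carries_region, pid_of_region[names(cov)], any)
      present <- setNames(rep(FALSE, length(ids)), ids)
      present[names(present_pid)] <- present_pid
      f1 <- mean(present[ids[group == g_levels[1]]])
      f2 <- mean(present[ids[group == g_levels[2]]])
      null_diffs[b] <- f1 - f2
    }
  }
  p <- (1 + sum(null_diffs >= obs)) / (1 + n_perm)
  list(observed_diff = obs, p.value = p, null_diffs = null_diffs,
       freq_by_group = tapply(obs_status != "absent", group[ids], mean))
}
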