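#' Synthetic multi-region cohort generation
#'
#' Generates cohorts of multi-region tumour sequencing data with fully known
#' ground truth: a random clone tree per patient, per-region clone mixtures
#' obtained by stick-breaking down the tree (so the subclonal sum constraint
#' holds by construction), binomial read sampling at configurable depth and
#' purity, copy-number segments with truncal and region-private events,
#' signature-structured trinucleotide contexts, and immune counts linked to
#' genotype flags with configurable effect sizes.
#'
#' @name synthetic_data
NULL

#' Default synthetic genome (22 autosomes, GRCh37-like lengths)
#' @return data.frame with columns `chrom` and `length` (bp)
#' @export
default_genome <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6,
               141e6, 136e6, 135e6, 134e6, 115e6, 107e6, 103e6, 90e6,
               81e6, 78e6, 59e6, 63e6, 48e6, 51e6),
    stringsAsFactors = FALSE
  )
}

#' The 96 trinucleotide context keys (pyrimidine-strand convention)
#'
#' Keys have the form `"A[C>T]G"`: 5' flank, bracketed substitution with a
#' pyrimidine reference (C or T), 3' flank. Order: substitution class major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base.
#'
#' @return character vector of length 96
#' @export
context_keys <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  keys <- character(0)
  for (s in subs) for (f5 in bases) for (f3 in bases) {
    keys <- c(keys, paste0(f5, "[", s, "]", f3))
  }
  keys
}

#' Built-in synthetic signature catalogue
#'
#' Three 96-context probability columns for testing and simulation:
#' `SBS_flat` (uniform), `SBS1_like` (concentrated on `N[C>T]G`, emulating a
#' deamination/age-like process) and `SBS6_like` (concentrated on `G[C>T]N`
#' with a `A[T>C]N` component, emulating a mismatch-repair-deficiency-like
#' process). These are synthetic stand-ins for testing signature attribution,
#' not reproductions of any reference catalogue.
#'
#' @return 96 x 3 matrix; rows named by [context_keys()], columns by signature
#' @export
signature_catalogue_synthetic <- function() {
  keys <- context_keys()
  flat <- rep(1 / 96, 96)
  sig1 <- rep(0.2 / 92, 96)
  idx1 <- grep("\\[C>T\\]G$", keys)
  sig1[idx1] <- 0.8 / length(idx1)
  sig6 <- rep(0.15 / 88, 96)
  idx6a <- grep("^G\\[C>T\\]", keys)
  idx6b <- grep("^A\\[T>C\\]", keys)
  sig6[idx6a] <- 0.6 / length(idx6a)
  sig6[idx6b] <- 0.25 / length(idx6b)
  m <- cbind(SBS_flat = flat, SBS1_like = sig1 / sum(sig1),
             SBS6_like = sig6 / sum(sig6))
  rownames(m) <- keys
  m
}

#' Default immune generative model parameters
#'
#' INIF (%) per region is Beta-distributed; its mean shifts upward for MMRD
#' patients. The patient-level CD8+/FOXP3+ ratio is log-normal with group
#' means set to the configured Wnt-activated and wild-type values, so
#' genotype-immune association analyses can be validated against known
#' effect sizes.
#'
#' @return named list of parameters
#' @export
immune_model_defaults <- function() {
  list(
    inif_mean = 8,            # baseline mean INIF percent
    inif_concentration = 4,   # Beta concentration (a + b)
    mmrd_inif_mean = 30,      # mean INIF percent for MMRD patients
    cd8_meanlog = log(300), cd8_sdlog = 0.3,
    cd4_meanlog = log(200), cd4_sdlog = 0.3,
    ratio_mean_wt = 6.08, ratio_sdlog_wt = 0.65,
    ratio_mean_wnt = 2.65, ratio_sdlog_wnt = 0.45,
    region_ratio_sdlog = 0.15,
    neoantigen_per_mut = 0.15
  )
}

#' Simulation configuration
#'
#' @param n_patients number of patients
#' @param regions_per_patient integer range `c(min, max)`
#' @param clones_per_patient integer range `c(min, max)`
#' @param depth mean sequencing depth (per-site depth is Poisson, floored at 1)
#' @param purity_range purity interval within (0, 1]
#' @param mutations_per_clone integer range `c(min, max)`
#' @param genome data.frame of chromosome lengths (see [default_genome()])
#' @param frac_mhnpc fraction of patients in the metastatic-at-presentation
#'   (mHNPC) arm; the rest are high-risk localised (hrlPC)
#' @param fga_mean named vector of target fraction-of-genome-altered means by
#'   clinical group
#' @param fga_sd patient-to-patient standard deviation of the altered
#'   fraction (default 0.09, matching the observed within-group spread of
#'   roughly 9-11 percentage points)
#' @param truncal_fga_share share of altered bases carried by truncal events
#' @param wgd_rate probability a patient has whole-genome doubling
#' @param wnt_rate probability a patient carries a planted Wnt-activating
#'   CTNNB1 gain-of-function mutation
#' @param mmrd_rate probability a patient is mismatch-repair deficient
#'   (biallelic MSH2 deletion planted; hypermutator with MMRD-like signature)
#' @param mmrd_mut_factor multiplier on mutation load for MMRD patients
#' @param clone_absent_prob probability a child clone is absent from a region
#' @param signature_catalogue 96 x k signature probability matrix
#' @param trunk_sig_weights,branch_sig_weights signature mixing weights for
#'   truncal and branch clones (default age-like trunk, flat branches)
#' @param immune_model list of immune model parameters
#'   (see [immune_model_defaults()])
#' @param planted_locus optional list(chrom, start, end, rate_mhnpc,
#'   rate_hrlpc): a gain spanning this locus is planted per patient at the
#'   group-specific rate
#' @param seed integer seed; all sub-streams derive deterministically from it
#' @return a `sim_config` list, validated
#' @export
sim_config <- function(n_patients = 25,
                       regions_per_patient = c(2, 4),
                       clones_per_patient = c(2, 6),
                       depth = 100,
                       purity_range = c(0.4, 0.8),
                       mutations_per_clone = c(10, 40),
                       genome = default_genome(),
                       frac_mhnpc = 12 / 25,
                       fga_mean = c(mHNPC = 0.30, hrlPC = 0.12),
                       fga_sd = 0.09,
                       truncal_fga_share = 0.6,
                       wgd_rate = 0.15,
                       wnt_rate = 0.28,
                       mmrd_rate = 0.08,
                       mmrd_mut_factor = 10,
                       clone_absent_prob = 0.25,
                       signature_catalogue = signature_catalogue_synthetic(),
                       trunk_sig_weights = NULL,
                       branch_sig_weights = NULL,
                       immune_model = immune_model_defaults(),
                       planted_locus = NULL,
                       seed = 1L) {
  assert_scalar_in(depth, 0, Inf, "depth", lo_open = TRUE)
  assert_scalar_in(purity_range[1], 0, 1, "purity lower bound", lo_open = TRUE)
  assert_scalar_in(purity_range[2], purity_range[1], 1, "purity upper bound")
  if (n_patients < 0) msq_stop("n_patients must be >= 0", "invalid_parameter")
  k <- ncol(signature_catalogue)
  colsums <- colSums(signature_catalogue)
  if (any(signature_catalogue < 0) || any(abs(colsums - 1) > 1e-8)) {
    msq_stop("each signature column must be nonnegative and sum to 1",
             "invalid_parameter")
  }
  if (is.null(trunk_sig_weights)) {
    trunk_sig_weights <- setNames(rep(0, k), colnames(signature_catalogue))
    trunk_sig_weights["SBS1_like"] <- 0.7
    trunk_sig_weights["SBS_flat"] <- 0.3
  }
  if (is.null(branch_sig_weights)) {
    branch_sig_weights <- setNames(rep(0, k), colnames(signature_catalogue))
    branch_sig_weights["SBS_flat"] <- 1
  }
  structure(list(
    n_patients = as.integer(n_patients),
    regions_per_patient = as.integer(regions_per_patient),
    clones_per_patient = as.integer(clones_per_patient),
    depth = depth, purity_range = purity_range,
    mutations_per_clone = as.integer(mutations_per_clone),
    genome = genome, frac_mhnpc = frac_mhnpc,
    fga_mean = fga_mean, fga_sd = fga_sd,
    truncal_fga_share = truncal_fga_share,
    wgd_rate = wgd_rate, wnt_rate = wnt_rate, mmrd_rate = mmrd_rate,
    mmrd_mut_factor = mmrd_mut_factor,
    clone_absent_prob = clone_absent_prob,
    signature_catalogue = signature_catalogue,
    trunk_sig_weights = trunk_sig_weights,
    branch_sig_weights = branch_sig_weights,
    immune_model = immune_model, planted_locus = planted_locus,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a random clone tree with per-region CCFs
#'
#' Builds a random rooted tree (node 1 is the trunk) and assigns each clone a
#' cancer cell fraction per region by stick-breaking down the tree: the trunk
#' has CCF 1 everywhere and each parent's CCF is divided among its children
#' (plus an unallocated remainder), so that in every region the CCFs of the
#' children of one parent sum to at most the parent's CCF, exactly.
#'
#' @param n_clones number of clones (>= 1)
#' @param n_regions number of tumour regions
#' @param seed optional integer seed (omit to use the current RNG stream)
#' @param clone_absent_prob probability a child clone is absent (CCF 0) from
#'   any given region
#' @return a `clone_tree_truth` list: `parent` (integer vector, 0 for the
#'   trunk), `clone_ccf` (clones x regions matrix), plus slots filled by
#'   [simulate_patient()]
#' @export
simulate_clone_tree <- function(n_clones, n_regions = 3, seed = NULL,
                                clone_absent_prob = 0.25) {
  if (!is.numeric(n_clones) || length(n_clones) != 1L || n_clones < 1) {
    msq_stop("n_clones must be a single integer >= 1", "invalid_parameter")
  }
  n_clones <- as.integer(n_clones)
  if (!is.null(seed)) set.seed(as.integer(seed))
  parent <- integer(n_clones)
  if (n_clones > 1L) {
    for (i in 2:n_clones) {
      parent[i] <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
    }
  }
  ccf <- matrix(0, nrow = n_clones, ncol = n_regions,
                dimnames = list(paste0("C", seq_len(n_clones)),
                                paste0("R", seq_len(n_regions))))
  ccf[1, ] <- 1
  if (n_clones > 1L) {
    for (p in seq_len(n_clones)) {
      children <- which(parent == p)
      if (length(children) == 0L) next
      for (r in seq_len(n_regions)) {
        remaining <- ccf[p, r]
        for (ch in children) {
          if (remaining <= 0) { ccf[ch, r] <- 0; next }
          absent <- runif(1) < clone_absent_prob
          take <- if (absent) 0 else remaining * rbeta(1, 1.2, 1.5)
          ccf[ch, r] <- take
          remaining <- remaining - take
        }
      }
      # guarantee every child is present somewhere: re-seat a vanished clone
      for (ch in children) {
        if (all(ccf[ch, ] < 0.02)) {
          r <- which.max(ccf[p, ] - colsum_children(ccf, parent, p))
          room <- ccf[p, r] - colsum_children(ccf, parent, p)[r]
          ccf[ch, r] <- room * 0.8
        }
      }
    }
  }
  structure(list(
    patient_id = NA_character_,
    n_clones = n_clones, n_regions = n_regions,
    parent = parent, clone_ccf = ccf,
    mutation_assignment = integer(0),
    signature_weights_by_clone = NULL
  ), class = "clone_tree_truth")
}

# draw one integer uniformly from an inclusive range (safe for min == max,
# where sample() would misread the scalar as 1:n)
sample_range <- function(rng) {
  if (rng[1] == rng[2]) return(rng[1])
  sample(seq(rng[1], rng[2]), 1L)
}

# per-region sum of CCF over the children of parent p
colsum_children <- function(ccf, parent, p) {
  children <- which(parent == p)
  if (length(children) == 0L) return(rep(0, ncol(ccf)))
  colSums(ccf[children, , drop = FALSE])
}

#' Check the structural invariants of a clone tree truth object
#'
#' Verifies the trunk has CCF 1 in every region and, for every parent and
#' region, that the children's CCFs sum to at most the parent's CCF.
#'
#' @param truth a `clone_tree_truth`
#' @param tol numeric slack for the comparisons
#' @return TRUE invisibly; stops on violation
#' @export
validate_tree_truth <- function(truth, tol = 1e-9) {
  if (any(abs(truth$clone_ccf[1, ] - 1) > tol)) {
    msq_stop("trunk CCF must be 1 in every region", "invariant_violation")
  }
  for (p in seq_len(truth$n_clones)) {
    s <- colsum_children(truth$clone_ccf, truth$parent, p)
    if (any(s > truth$clone_ccf[p, ] + tol)) {
      msq_stop(sprintf("children of clone %d exceed its CCF", p),
               "invariant_violation")
    }
  }
  invisible(TRUE)
}

# draw segment event intervals totalling about `target_bases`, non-overlapping
draw_event_intervals <- function(genome, target_bases, min_len = 5e6,
                                 mean_len = 2.5e7) {
  events <- list()
  pl_chrom <- character(0); pl_start <- numeric(0); pl_end <- numeric(0)
  got <- 0
  tries <- 0
  while (got < target_bases && tries < 500) {
    tries <- tries + 1
    len <- round(min(max(rlnorm(1, log(mean_len), 0.5), min_len),
                     target_bases - got + min_len))
    ci <- sample.int(nrow(genome), 1L,
                     prob = pmax(genome$length - len, 0))
    if (genome$length[ci] <= len) next
    start <- floor(runif(1, 1, genome$length[ci] - len))
    end <- start + len - 1
    if (any(pl_chrom == genome$chrom[ci] & pl_start <= end &
              pl_end >= start)) next
    pl_chrom <- c(pl_chrom, genome$chrom[ci])
    pl_start <- c(pl_start, start); pl_end <- c(pl_end, end)
    events[[length(events) + 1L]] <-
      list(chrom = genome$chrom[ci], start = start, end = end)
    got <- got + len
  }
  events
}

# complement of event intervals per chromosome, as baseline segments
baseline_segments <- function(genome, event_df, major, minor) {
  out <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    evs <- event_df[event_df$chrom == chrom, , drop = FALSE]
    gaps <- IRanges::gaps(IRanges::IRanges(evs$start, evs$end),
                          start = 1, end = genome$length[i])
    if (length(gaps) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, start = IRanges::start(gaps), end = IRanges::end(gaps),
      major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one multi-region patient
#'
#' Draws a clone tree, per-region purities, a copy-number landscape with
#' truncal and region-private events, mutations with signature-structured
#' trinucleotide contexts and binomially sampled read counts, and
#' genotype-linked immune counts. For a mutation of clone c in region r at a
#' locus with total copy number CN and multiplicity m, the expected variant
#' allele fraction is `purity * CCF(r,c) * m / (purity * CN + 2 (1-purity))`;
#' alt read counts are Binomial(depth, expected VAF) with per-site Poisson
#' depth.
#'
#' @param config a [sim_config()]
#' @param patient_id identifier string
#' @param group clinical group, `"mHNPC"` or `"hrlPC"`
#' @param seed integer seed for this patient
#' @return list with `variants`, `segments`, `sheet_patient`, `sheet_regions`
#'   data frames and the `truth` (`clone_tree_truth` augmented with flags)
#' @export
simulate_patient <- function(config, patient_id = "P001", group = "hrlPC",
                             seed = 1L) {
  set.seed(as.integer(seed))
  genome <- config$genome
  genome_len <- sum(as.numeric(genome$length))
  n_regions <- sample_range(config$regions_per_patient)
  n_clones <- sample_range(config$clones_per_patient)
  tree <- simulate_clone_tree(n_clones, n_regions,
                              clone_absent_prob = config$clone_absent_prob)
  tree$patient_id <- patient_id
  region_ids <- paste0("R", seq_len(n_regions))
  purity <- runif(n_regions, config$purity_range[1], config$purity_range[2])

  is_wgd <- runif(1) < config$wgd_rate
  is_wnt <- runif(1) < config$wnt_rate
  is_mmrd <- runif(1) < config$mmrd_rate
  base_major <- if (is_wgd) 2 else 1
  base_minor <- if (is_wgd) 2 else 1
  neutral_cn <- base_major + base_minor

  # --- copy-number landscape -------------------------------------------------
  fga_target <- min(max(rnorm(1, config$fga_mean[[group]], config$fga_sd),
                        0), 0.6)
  events <- draw_event_intervals(genome, fga_target * genome_len)
  n_ev <- length(events)
  truncal <- if (n_ev > 0) runif(n_ev) < config$truncal_fga_share else logical(0)
  ev_dir <- if (n_ev > 0) sample(c("gain", "loss"), n_ev, TRUE) else character(0)
  # region-private events belong to non-trunk clones; manifest where that
  # clone is most abundant. With a single clone all events are truncal.
  ev_clone <- rep(1L, n_ev)
  ev_region <- rep(NA_integer_, n_ev)
  for (i in seq_len(n_ev)) {
    if (!truncal[i] && n_clones > 1L) {
      ev_clone[i] <- sample(2:n_clones, 1L)
      ev_region[i] <- which.max(tree$clone_ccf[ev_clone[i], ])
    }
  }
  ev_df <- if (n_ev > 0) data.frame(
    chrom = vapply(events, `[[`, "", "chrom"),
    start = vapply(events, `[[`, 0, "start"),
    end = vapply(events, `[[`, 0, "end"),
    dir = ev_dir, truncal = truncal, region = ev_region,
    stringsAsFactors = FALSE
  ) else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    dir = character(0), truncal = logical(0),
                    region = integer(0))

  # planted intervals take precedence over randomly drawn events
  planted <- config$planted_locus
  planted_row <- NULL
  if (!is.null(planted)) {
    rate <- if (group == "mHNPC") planted$rate_mhnpc else planted$rate_hrlpc
    if (runif(1) < rate) {
      planted_row <- data.frame(
        chrom = planted$chrom, start = planted$start, end = planted$end,
        dir = "gain", truncal = TRUE, region = NA_integer_)
    }
  }
  # MMRD: truncal homozygous deletion over MSH2 (two lost copies = two hits)
  mmrd_del <- NULL
  if (is_mmrd) {
    gc <- default_gene_coords()
    msh2 <- gc[gc$gene == "MSH2", ]
    mmrd_del <- data.frame(chrom = msh2$chrom, start = msh2$start - 2e6,
                           end = msh2$end + 2e6, dir = "homdel",
                           truncal = TRUE, region = NA_integer_)
  }
  specials <- rbind(planted_row, mmrd_del)
  if (!is.null(specials) && nrow(ev_df) > 0L) {
    gr_ev <- GenomicRanges::GRanges(ev_df$chrom,
                                    IRanges::IRanges(ev_df$start, ev_df$end))
    gr_sp <- GenomicRanges::GRanges(specials$chrom,
                                    IRanges::IRanges(specials$start,
                                                     specials$end))
    # the two sets may live on disjoint chromosomes; that is expected here
    clash <- unique(S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(gr_ev, gr_sp))))
    if (length(clash) > 0L) ev_df <- ev_df[-clash, , drop = FALSE]
  }
  if (!is.null(planted_row)) ev_df <- rbind(ev_df, planted_row)

  seg_rows <- list()
  for (r in seq_len(n_regions)) {
    evs_r <- ev_df[ev_df$truncal | (!is.na(ev_df$region) & ev_df$region == r), ,
                   drop = FALSE]
    if (!is.null(mmrd_del)) evs_r <- rbind(evs_r, mmrd_del)
    if (nrow(evs_r) > 0L) {
      cn <- t(vapply(evs_r$dir, function(d) {
        switch(d,
               gain = c(base_major + 1, base_minor),
               loss = c(base_major, max(base_minor - 1, 0)),
               homdel = c(0, 0))
      }, numeric(2)))
      ev_out <- data.frame(chrom = evs_r$chrom, start = evs_r$start,
                           end = evs_r$end, major_cn = cn[, 1],
                           minor_cn = cn[, 2], stringsAsFactors = FALSE)
    } else {
      ev_out <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), major_cn = numeric(0),
                           minor_cn = numeric(0))
    }
    base_out <- baseline_segments(genome, ev_out, base_major, base_minor)
    both <- rbind(ev_out, base_out)
    both <- both[order(match(both$chrom, genome$chrom), both$start), ]
    seg_rows[[r]] <- data.frame(patient_id = patient_id,
                                region_id = region_ids[r], both,
                                stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  # --- mutations -------------------------------------------------------------
  catalogue <- config$signature_catalogue
  keys <- rownames(catalogue)
  mut_factor <- if (is_mmrd) config$mmrd_mut_factor else 1
  sigw <- vector("list", n_clones)
  n_mut <- integer(n_clones)
  for (cl in seq_len(n_clones)) {
    n_mut[cl] <- round(mut_factor * sample_range(config$mutations_per_clone))
    w <- if (cl == 1L) config$trunk_sig_weights else config$branch_sig_weights
    if (is_mmrd) {
      w <- setNames(rep(0, ncol(catalogue)), colnames(catalogue))
      w["SBS6_like"] <- 0.8
      w["SBS_flat"] <- 0.2
    }
    sigw[[cl]] <- w / sum(w)
  }
  tree$signature_weights_by_clone <- do.call(rbind, sigw)
  rownames(tree$signature_weights_by_clone) <- rownames(tree$clone_ccf)

  total_mut <- sum(n_mut)
  assignment <- rep(seq_len(n_clones), n_mut)
  # Wnt: plant a CTNNB1 gain-of-function missense in a subclone if possible
  wnt_mut_idx <- NA_integer_
  if (is_wnt) {
    target_clone <- if (n_clones > 1L) sample(2:n_clones, 1L) else 1L
    wnt_mut_idx <- total_mut + 1L
    assignment <- c(assignment, target_clone)
    total_mut <- total_mut + 1L
  }

  chrom_i <- sample.int(nrow(genome), total_mut, replace = TRUE,
                        prob = genome$length)
  pos <- floor(runif(total_mut, 1, genome$length[chrom_i]))
  chrom <- genome$chrom[chrom_i]
  sig_pick <- vapply(assignment, function(cl) {
    sample.int(ncol(catalogue), 1L, prob = sigw[[cl]])
  }, integer(1))
  context <- vapply(sig_pick, function(s) {
    keys[sample.int(96, 1L, prob = catalogue[, s])]
  }, character(1))
  ref <- substr(context, 3, 3)
  alt <- substr(context, 5, 5)
  gene <- rep("", total_mut)
  effect <- sample(c("missense", "silent", "nonsense", "other"), total_mut,
                   replace = TRUE, prob = c(0.55, 0.25, 0.1, 0.1))
  protein_change <- rep("", total_mut)
  if (is_wnt) {
    gc <- default_gene_coords()
    ct <- gc[gc$gene == "CTNNB1", ]
    chrom[wnt_mut_idx] <- ct$chrom
    pos[wnt_mut_idx] <- floor((ct$start + ct$end) / 2)
    context[wnt_mut_idx] <- "A[C>T]G"
    ref[wnt_mut_idx] <- "C"
    alt[wnt_mut_idx] <- "T"
    gene[wnt_mut_idx] <- "CTNNB1"
    effect[wnt_mut_idx] <- "missense"
    protein_change[wnt_mut_idx] <- sample(c("p.S33P", "p.S33C", "p.T41A"), 1L)
  }
  tree$mutation_assignment <- assignment

  # local total copy number per (mutation, region) from the region's segments
  var_rows <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    seg_r <- segments[segments$region_id == region_ids[r], , drop = FALSE]
    cn_t <- rep(neutral_cn, total_mut)
    gr_m <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    gr_s <- segments_to_granges(seg_r)
    hits <- GenomicRanges::findOverlaps(gr_m, gr_s)
    cn_t[S4Vectors::queryHits(hits)] <-
      seg_r$major_cn[S4Vectors::subjectHits(hits)] +
      seg_r$minor_cn[S4Vectors::subjectHits(hits)]
    m <- rep(1, total_mut)
    exp_vaf <- ifelse(cn_t >= 1,
                      purity[r] * tree$clone_ccf[assignment, r] * m /
                        (purity[r] * cn_t + 2 * (1 - purity[r])),
                      0)
    if (any(exp_vaf > 1 + 1e-12)) {
      msq_stop("internal inconsistency: expected VAF > 1", "internal_error")
    }
    depth <- pmax(1L, rpois(total_mut, config$depth))
    alt_count <- rbinom(total_mut, depth, pmin(exp_vaf, 1))
    var_rows[[r]] <- data.frame(
      patient_id = patient_id, region_id = region_ids[r],
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      ref_count = depth - alt_count, alt_count = alt_count,
      gene = gene, effect = effect, context = context,
      germline_flag = FALSE, protein_change = protein_change,
      cn_total = cn_t, multiplicity = m,
      stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL

  # --- immune counts ---------------------------------------------------------
  im <- config$immune_model
  inif_mu <- if (is_mmrd) im$mmrd_inif_mean else im$inif_mean
  a <- im$inif_concentration * inif_mu / 100
  b <- im$inif_concentration * (1 - inif_mu / 100)
  inif <- round(100 * rbeta(n_regions, a, b), 1)
  ratio_pat <- if (is_wnt) {
    rlnorm(1, log(im$ratio_mean_wnt) - im$ratio_sdlog_wnt^2 / 2,
           im$ratio_sdlog_wnt)
  } else {
    rlnorm(1, log(im$ratio_mean_wt) - im$ratio_sdlog_wt^2 / 2,
           im$ratio_sdlog_wt)
  }
  cd8 <- round(rlnorm(n_regions, im$cd8_meanlog, im$cd8_sdlog))
  cd4 <- round(rlnorm(n_regions, im$cd4_meanlog, im$cd4_sdlog))
  ratio_reg <- ratio_pat * rlnorm(n_regions, -im$region_ratio_sdlog^2 / 2,
                                  im$region_ratio_sdlog)
  foxp3 <- pmax(1, round(cd8 / ratio_reg))
  neo_total <- round(im$neoantigen_per_mut * total_mut *
                       rlnorm(1, 0, 0.3))
  neo_clonal <- round(neo_total * n_mut[1] / max(total_mut, 1))

  sheet_patient <- data.frame(
    patient_id = patient_id, group = group,
    gleason = sample(7:10, 1L),
    neoantigen_total = neo_total, neoantigen_clonal = neo_clonal,
    stringsAsFactors = FALSE
  )
  sheet_regions <- data.frame(
    patient_id = patient_id, region_id = region_ids,
    purity = round(purity, 3), inif = inif, cd8 = cd8, cd4 = cd4,
    foxp3 = foxp3, stringsAsFactors = FALSE
  )
  tree$flags <- list(wgd = is_wgd, wnt = is_wnt, mmrd = is_mmrd)
  tree$fga_target <- fga_target
  tree$group <- group
  list(variants = variants, segments = segments,
       sheet_patient = sheet_patient, sheet_regions = sheet_regions,
       truth = tree)
}

#' Simulate a full cohort
#'
#' Patients are independent; group labels are assigned so that
#' `round(n_patients * frac_mhnpc)` patients are mHNPC. The returned truth
#' bundle contains each patient's clone tree, mutation assignment, planted
#' genotype flags and target altered fraction, sufficient to score cluster
#' recovery, tree recovery, FGA, signature weights and group comparisons.
#'
#' @param config a [sim_config()]
#' @return list with `variants`, `segments`, `sheet` and `truth` (named list
#'   of per-patient `clone_tree_truth`)
#' @export
simulate_cohort <- function(config) {
  n <- config$n_patients
  if (n == 0L) {
    return(list(variants = NULL, segments = NULL,
                sheet = list(patients = NULL, regions = NULL),
                truth = list()))
  }
  n_m <- round(n * config$frac_mhnpc)
  groups <- c(rep("mHNPC", n_m), rep("hrlPC", n - n_m))
  ids <- sprintf("P%03d", seq_len(n))
  pats <- lapply(seq_len(n), function(i) {
    simulate_patient(config, ids[i], groups[i],
                     seed = derive_seed(config$seed, i))
  })
  truth <- lapply(pats, `[[`, "truth")
  names(truth) <- ids
  list(
    variants = do.call(rbind, lapply(pats, `[[`, "variants")),
    segments = do.call(rbind, lapply(pats, `[[`, "segments")),
    sheet = list(
      patients = do.call(rbind, lapply(pats, `[[`, "sheet_patient")),
      regions = do.call(rbind, lapply(pats, `[[`, "sheet_regions"))
    ),
    truth = truth
  )
}

#' Write a simulated cohort to a directory
#'
#' Emits `variants.tsv`, `segments.tsv` and `sheet.yaml` in the formats the
#' readers consume, plus `truth.json` with the per-patient clone-tree truth.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(cohort$variants)) {
    write_variants(cohort$variants, file.path(dir, "variants.tsv"))
    write_segments(cohort$segments, file.path(dir, "segments.tsv"))
    write_sheet(cohort$sheet, file.path(dir, "sheet.yaml"))
  }
  truth_json <- lapply(cohort$truth, function(tt) {
    list(patient_id = tt$patient_id, n_clones = tt$n_clones,
         n_regions = tt$n_regions, parent = tt$parent,
         clone_ccf = apply(tt$clone_ccf, 1, as.list),
         mutation_assignment = tt$mutation_assignment,
         flags = tt$flags, group = tt$group, fga_target = tt$fga_target)
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
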