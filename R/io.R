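#' File formats
#'
#' All on-disk artefacts are plain text. Variant and segment tables are
#' tab-separated with a fixed header and 1-based inclusive coordinates (SEG
#' convention); the sample sheet is YAML; results are JSON. Columns beyond the
#' required set are preserved verbatim on read and write.
#'
#' @name io_formats
NULL

.variant_cols <- c("patient_id", "region_id", "chrom", "pos", "ref", "alt",
                   "ref_count", "alt_count", "gene", "effect", "context",
                   "germline_flag")
.segment_cols <- c("patient_id", "region_id", "chrom", "start", "end",
                   "major_cn", "minor_cn")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    msq_stop(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")),
             "schema_error")
  }
  invisible(df)
}

#' Read a per-region somatic variant table
#'
#' @param path path to a tab-separated variant file with columns
#'   `patient_id, region_id, chrom, pos, ref, alt, ref_count, alt_count,
#'   gene, effect, context, germline_flag` (extra columns preserved).
#' @return a `data.frame`, one row per (mutation, region) observation.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  check_columns(df, .variant_cols, basename(path))
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  df$germline_flag <- as.logical(df$germline_flag)
  if (any(df$ref_count < 0 | df$alt_count < 0, na.rm = TRUE)) {
    msq_stop("negative read counts in variant table", "validation_error")
  }
  df
}

#' Write a variant table
#' @param df variant table as returned by [read_variants()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_variants <- function(df, path) {
  check_columns(df, .variant_cols, "variant table")
  cols <- c(.variant_cols, setdiff(names(df), .variant_cols))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' Coordinates are 1-based inclusive. Within one (patient, region, chromosome)
#' the segments must be non-overlapping; violations raise a validation error
#' naming the offending intervals.
#'
#' @param path path to a tab-separated segment file with columns
#'   `patient_id, region_id, chrom, start, end, major_cn, minor_cn`.
#' @return a `data.frame` with an added `total_cn` column.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  check_columns(df, .segment_cols, basename(path))
  for (col in c("start", "end", "major_cn", "minor_cn")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_segments(df)
  df$total_cn <- df$major_cn + df$minor_cn
  df
}

#' Validate a segment table
#'
#' Checks `start <= end`, nonnegative integer copy numbers, and non-overlap
#' within each (patient, region, chromosome).
#'
#' @param seg segment `data.frame`
#' @return invisibly, `seg`
#' @export
validate_segments <- function(seg) {
  check_columns(seg, .segment_cols, "segment table")
  if (any(seg$start > seg$end)) {
    bad <- which(seg$start > seg$end)[1L]
    msq_stop(sprintf("segment with start > end: %s:%s-%s",
                     seg$chrom[bad], seg$start[bad], seg$end[bad]),
             "validation_error")
  }
  if (any(seg$major_cn < 0 | seg$minor_cn < 0)) {
    msq_stop("negative copy number in segment table", "validation_error")
  }
  key <- paste(seg$patient_id, seg$region_id, seg$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = seg$start[idx], end = seg$end[idx])
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0L) {
      i <- idx[S4Vectors::queryHits(hits)[1L]]
      j <- idx[S4Vectors::subjectHits(hits)[1L]]
      msq_stop(sprintf(
        "overlapping segments in %s/%s: %s:%g-%g overlaps %s:%g-%g",
        seg$patient_id[i], seg$region_id[i],
        seg$chrom[i], seg$start[i], seg$end[i],
        seg$chrom[j], seg$start[j], seg$end[j]),
        "validation_error")
    }
  }
  invisible(seg)
}

#' Write a segment table
#' @param df segment table
#' @param path output path
#' @return invisibly, `path`
#' @export
write_segments <- function(df, path) {
  check_columns(df, .segment_cols, "segment table")
  cols <- c(.segment_cols, setdiff(names(df), c(.segment_cols, "total_cn")))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' The sheet is a YAML file listing patients (clinical group, Gleason grade,
#' optional neoantigen burdens) and their regions (purity, INIF percent,
#' CD8/CD4/FOXP3 cell counts).
#'
#' @param path path to the YAML sample sheet
#' @return a list with `patients` and `regions` data frames
#' @export
read_sheet <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$patients)) {
    msq_stop("sample sheet has no 'patients' entry", "schema_error")
  }
  pat_rows <- lapply(raw$patients, function(p) {
    data.frame(
      patient_id = as.character(p$patient_id),
      group = as.character(p$group),
      gleason = if (is.null(p$gleason)) NA_integer_ else as.integer(p$gleason),
      neoantigen_total = if (is.null(p$neoantigen_total)) NA_real_
                         else as.numeric(p$neoantigen_total),
      neoantigen_clonal = if (is.null(p$neoantigen_clonal)) NA_real_
                          else as.numeric(p$neoantigen_clonal),
      stringsAsFactors = FALSE
    )
  })
  reg_rows <- lapply(raw$patients, function(p) {
    do.call(rbind, lapply(p$regions, function(r) {
      data.frame(
        patient_id = as.character(p$patient_id),
        region_id = as.character(r$region_id),
        purity = as.numeric(r$purity),
        inif = if (is.null(r$inif)) NA_real_ else as.numeric(r$inif),
        cd8 = if (is.null(r$cd8)) NA_real_ else as.numeric(r$cd8),
        cd4 = if (is.null(r$cd4)) NA_real_ else as.numeric(r$cd4),
        foxp3 = if (is.null(r$foxp3)) NA_real_ else as.numeric(r$foxp3),
        stringsAsFactors = FALSE
      )
    }))
  })
  sheet <- list(patients = do.call(rbind, pat_rows),
                regions = do.call(rbind, reg_rows))
  bad_purity <- with(sheet$regions, purity <= 0 | purity > 1)
  if (any(bad_purity)) {
    msq_stop("purity must lie in (0, 1] for every region", "validation_error")
  }
  sheet
}

#' Write a cohort sample sheet
#' @param sheet list with `patients` and `regions` data frames
#' @param path output YAML path
#' @return invisibly, `path`
#' @export
write_sheet <- function(sheet, path) {
  pats <- lapply(seq_len(nrow(sheet$patients)), function(i) {
    p <- sheet$patients[i, ]
    regs <- sheet$regions[sheet$regions$patient_id == p$patient_id, ,
                          drop = FALSE]
    entry <- list(patient_id = p$patient_id, group = p$group,
                  gleason = p$gleason)
    if (!is.na(p$neoantigen_total)) entry$neoantigen_total <- p$neoantigen_total
    if (!is.na(p$neoantigen_clonal)) {
      entry$neoantigen_clonal <- p$neoantigen_clonal
    }
    entry$regions <- lapply(seq_len(nrow(regs)), function(j) {
      r <- regs[j, ]
      list(region_id = r$region_id, purity = r$purity, inif = r$inif,
           cd8 = r$cd8, cd4 = r$cd4, foxp3 = r$foxp3)
    })
    entry
  })
  yaml::write_yaml(list(patients = pats), path)
  invisible(path)
}

#' Check that every region in the variant/segment tables is on the sheet
#'
#' @param variants variant table (or NULL)
#' @param segments segment table (or NULL)
#' @param sheet sample sheet as returned by [read_sheet()]
#' @return invisibly TRUE
#' @export
validate_cohort <- function(variants = NULL, segments = NULL, sheet) {
  known <- paste(sheet$regions$patient_id, sheet$regions$region_id)
  for (tab in list(variants, segments)) {
    if (is.null(tab) || nrow(tab) == 0L) next
    seen <- unique(paste(tab$patient_id, tab$region_id))
    missing <- setdiff(seen, known)
    if (length(missing) > 0L) {
      msq_stop(sprintf("region(s) absent from sample sheet: %s",
                       paste(missing, collapse = ", ")),
               "validation_error")
    }
  }
  invisible(TRUE)
}

#' Write analysis results as JSON
#' @param results a (possibly nested) list of results
#' @param path output path
#' @return invisibly, `path`
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
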