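# Shipped configuration tables. Coordinates are approximate GRCh37 values and
# are defaults only: both loaders accept a user path to override them.

#' Default gene coordinate table
#'
#' Approximate GRCh37 coordinates for the driver, Wnt-pathway and
#' mismatch-repair genes the pipeline flags by default. Override by supplying
#' your own tab-separated file with columns `gene, chrom, start, end`.
#'
#' @param path optional path to an alternative gene coordinate TSV
#' @return data.frame with columns `gene, chrom, start, end`
#' @export
default_gene_coords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_coords_grch37_approx.tsv",
                        package = "mseqith")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  check_columns(df, c("gene", "chrom", "start", "end"), basename(path))
  df
}

#' Default SCNA locus catalogue
#'
#' Cytoband-level loci tested for group enrichment (including the 3q26.2 and
#' 3q21.3 gain loci) plus a few arm-level definitions, with approximate
#' GRCh37 coordinates. Override with a BED-like TSV (1-based inclusive) with
#' columns `locus, chrom, start, end, direction`.
#'
#' @param path optional path to an alternative locus catalogue TSV
#' @return data.frame with columns `locus, chrom, start, end, direction`
#' @export
default_locus_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "locus_catalogue_grch37_approx.tsv",
                        package = "mseqith")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  check_columns(df, c("locus", "chrom", "start", "end", "direction"),
                basename(path))
  df
}

#' Default Wnt-activating CTNNB1 protein changes
#'
#' Exon-3 gain-of-function variants used by [flag_wnt_activation()];
#' extensible by concatenation.
#'
#' @return character vector of protein-change strings
#' @export
default_wnt_gof_variants <- function() {
  c("p.S33P", "p.S33C", "p.T41A")
}

#' Default mismatch-repair gene set
#' @return character vector of gene symbols
#' @export
default_mmr_genes <- function() {
  c("MLH1", "MSH2", "MSH6", "PMS2")
}
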