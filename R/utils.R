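#' @importFrom stats dbinom pbinom qbeta rbinom rpois runif rbeta rnorm rlnorm
#'   cor.test fisher.test median optimize sd setNames quantile ks.test pnorm
#'   complete.cases
NULL

# internal: stop with a classed condition so tests can assert on error class
msq_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "mseqith_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

msq_warn <- function(msg, class = "mseqith_warning") {
  warning(structure(
    class = c(class, "mseqith_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# check a numeric scalar lies in an interval
assert_scalar_in <- function(x, lo, hi, what, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    msq_stop(sprintf("%s must be a single number in %s%g, %g%s (got %s)",
                     what, if (lo_open) "(" else "[", lo, hi,
                     if (hi_open) ")" else "]",
                     paste(format(x), collapse = ",")),
             "invalid_parameter")
  }
  invisible(x)
}

# derive a deterministic sub-seed from a global seed; kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# variant allele fraction with 0/0 -> NA
vaf_of <- function(alt, ref) {
  depth <- alt + ref
  ifelse(depth > 0, alt / depth, NA_real_)
}

# expected VAF per unit CCF: vaf = ccf * ccf_to_vaf_factor
ccf_to_vaf_factor <- function(purity, cn_total, multiplicity) {
  purity * multiplicity / (purity * cn_total + 2 * (1 - purity))
}

# segments data.frame -> GRanges (1-based inclusive coordinates preserved)
segments_to_granges <- function(seg) {
  GenomicRanges::GRanges(
    seqnames = as.character(seg$chrom),
    ranges = IRanges::IRanges(start = seg$start, end = seg$end)
  )
}

total_width <- function(gr) {
  if (length(gr) == 0L) return(0)
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(gr))))
}
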