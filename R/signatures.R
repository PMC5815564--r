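#' Mutational signature counting and attribution
#'
#' Aggregates SNVs into the standard 96-class trinucleotide context spectrum
#' (pyrimidine-strand convention) and decomposes spectra into nonnegative
#' mixtures of catalogue signatures by nonnegative least squares, with the
#' option to fit the ubiquitous and non-ubiquitous mutation sets of a patient
#' separately to ask whether a mutational process acted early (truncal) or
#' late.
#'
#' @name signatures
NULL

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a 96-context key
#'
#' `"C[G>A]T"` becomes `"A[C>T]G"`. Applying the function twice returns the
#' original key (involution).
#'
#' @param key context key like `"A[C>T]G"`
#' @return the reverse-complemented key
#' @export
revcomp_context <- function(key) {
  f5 <- substr(key, 1, 1)
  ref <- substr(key, 3, 3)
  alt <- substr(key, 5, 5)
  f3 <- substr(key, 7, 7)
  paste0(.complement[f3], "[", .complement[ref], ">", .complement[alt], "]",
         .complement[f5])
}

#' Fold a context key to the pyrimidine-strand convention
#'
#' Keys whose central (reference) base is a purine (A or G) are
#' reverse-complemented; pyrimidine-centred keys pass through unchanged.
#'
#' @param key context key
#' @return pyrimidine-strand key
#' @export
fold_context <- function(key) {
  ref <- substr(key, 3, 3)
  ifelse(ref %in% c("A", "G"), revcomp_context(key), key)
}

#' Count the 96-context spectrum of a variant set
#'
#' Purine-strand records are folded to the pyrimidine convention; records
#' with malformed or empty context keys are dropped with a warning and
#' counted in the `n_dropped` attribute.
#'
#' @param variants variant table with a `context` column (one row per
#'   mutation; deduplicate across regions first if needed)
#' @return named integer vector of length 96 (a `context_spectrum`), with
#'   attribute `n_dropped`
#' @export
count_contexts <- function(variants) {
  keys <- context_keys()
  spectrum <- setNames(integer(96), keys)
  ctx <- variants$context
  ctx <- ctx[!is.na(ctx) & ctx != ""]
  if (length(ctx) > 0) {
    folded <- vapply(ctx, fold_context, character(1), USE.NAMES = FALSE)
    ok <- folded %in% keys
    if (any(!ok)) {
      msq_warn(sprintf("%d record(s) with malformed context dropped",
                       sum(!ok)), "malformed_context")
    }
    tab <- table(factor(folded[ok], levels = keys))
    spectrum[] <- as.integer(tab)
  }
  attr(spectrum, "n_dropped") <- length(variants$context) - sum(spectrum)
  class(spectrum) <- "context_spectrum"
  spectrum
}

#' Fit signature weights to a spectrum by nonnegative least squares
#'
#' The spectrum is normalised to proportions and projected onto the
#' catalogue columns under a nonnegativity constraint; weights are
#' renormalised to sum to 1. The reconstruction error is the cosine distance
#' between the observed and reconstructed spectra.
#'
#' @param spectrum 96-vector of context counts (see [count_contexts()])
#' @param catalogue 96 x k matrix of signature probability columns
#' @return list of class `signature_fit`: `weights` (named, sum 1),
#'   `cosine_distance`, `n_mutations`
#' @export
fit_signatures <- function(spectrum, catalogue = signature_catalogue_synthetic()) {
  spectrum <- as.numeric(spectrum)
  total <- sum(spectrum)
  if (total <= 0) msq_stop("zero-total spectrum", "invalid_input")
  if (nrow(catalogue) != length(spectrum)) {
    msq_stop("catalogue rows must match the 96 spectrum bins", "schema_error")
  }
  target <- spectrum / total
  w <- pracma::lsqnonneg(catalogue, target)$x
  if (sum(w) <= 0) msq_stop("degenerate NNLS solution", "fit_error")
  weights <- setNames(w / sum(w), colnames(catalogue))
  recon <- as.numeric(catalogue %*% w)
  cosine <- 1 - sum(recon * target) /
    (sqrt(sum(recon^2)) * sqrt(sum(target^2)))
  structure(list(weights = weights, cosine_distance = cosine,
                 n_mutations = total), class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("Signature fit over %d mutations (cosine distance %.4f)\n",
              x$n_mutations, x$cosine_distance))
  print(round(x$weights, 3))
  invisible(x)
}

#' Attribute signatures separately to ubiquitous and non-ubiquitous mutations
#'
#' Splits one patient's mutations by presence class and fits each set
#' independently, asking whether a process (e.g. a mismatch-repair-deficiency
#' signature) contributed early, truncally acquired mutations or only later
#' private ones. Sets smaller than `min_mutations` are fitted but flagged
#' low-confidence.
#'
#' @param variants one row per mutation with `context`
#' @param presence_class per-mutation class from
#'   [classify_patient_presence()] (`"ubiquitous"`/`"shared"`/`"private"`)
#' @param catalogue signature catalogue matrix
#' @param min_mutations low-confidence threshold (default 20)
#' @return list with `ubiquitous` and `non_ubiquitous` `signature_fit`s,
#'   each carrying a `low_confidence` flag
#' @export
attribute_by_clonality <- function(variants, presence_class,
                                   catalogue = signature_catalogue_synthetic(),
                                   min_mutations = 20) {
  stopifnot(length(presence_class) == nrow(variants))
  fit_set <- function(rows) {
    if (nrow(rows) == 0L) return(NULL)
    fit <- fit_signatures(count_contexts(rows), catalogue)
    fit$low_confidence <- fit$n_mutations < min_mutations
    fit
  }
  list(
    ubiquitous = fit_set(variants[presence_class == "ubiquitous", ,
                                  drop = FALSE]),
    non_ubiquitous = fit_set(variants[presence_class != "ubiquitous", ,
                                      drop = FALSE])
  )
}

#' Read a signature catalogue from TSV
#'
#' Expects 96 rows keyed by a `context` column plus one column per
#' signature; columns are validated as probability vectors.
#'
#' @param path catalogue TSV path
#' @return 96 x k matrix with context rownames
#' @export
read_catalogue <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  check_columns(df, "context", basename(path))
  m <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- df$context
  m <- m[match(context_keys(), rownames(m)), , drop = FALSE]
  if (any(is.na(m)) || any(m < 0) || any(abs(colSums(m) - 1) > 1e-6)) {
    msq_stop("catalogue columns must be 96-bin probability vectors",
             "validation_error")
  }
  m
}

#' Write a signature catalogue to TSV
#' @param catalogue 96 x k matrix with context rownames
#' @param path output path
#' @return invisibly, `path`
#' @export
write_catalogue <- function(catalogue, path) {
  df <- data.frame(context = rownames(catalogue), catalogue,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
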