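# Trinucleotide-context mutation spectra and complete-linkage clustering of
# samples under the distance 1 - cor(log(pseudocount + f)), with f the
# 96-class context frequencies.

#' Trinucleotide-context spectrum of a mutation set
#'
#' Counts mutations in the 96 pyrimidine-strand context classes
#' (substitution class x 5' base x 3' base). Purine-reference mutations are
#' reverse-complemented onto the pyrimidine strand. Sites at contig edges
#' (no flanking base) are skipped and their number reported via a message.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named character vector or DNAStringSet.
#' @return Named integer vector of length 96 (class `spectrum`).
#' @export
context_spectrum <- function(mutations, reference) {
  ref <- as_ref_strings(reference)
  classes <- context_classes()
  counts <- setNames(rep(0L, 96), classes)
  if (nrow(mutations) == 0) return(structure(counts, class = "spectrum"))
  len <- nchar(ref)[mutations$chrom]
  edge <- mutations$pos <= 1 | mutations$pos >= len
  if (any(edge))
    message("skipping ", sum(edge), " site(s) at contig edges")
  m <- mutations[!edge, , drop = FALSE]
  if (nrow(m)) {
    tri <- ref_window(ref, m$chrom, m$pos, 1L)
    lab <- collapse_context(tri, m$ref, m$alt)
    bad <- is.na(lab)
    if (any(bad))
      warning(sum(bad), " mutation(s) with invalid context skipped")
    tab <- table(factor(lab[!bad], levels = classes))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = "spectrum")
}

#' Context frequencies of a spectrum
#' @param counts 96-class count vector.
#' @return Frequencies summing to 1 (all zero if no counts).
#' @export
spectrum_frequencies <- function(counts) {
  s <- sum(counts)
  if (s == 0) return(setNames(rep(0, 96), names(counts)))
  counts / s
}

#' Log-correlation distance between two spectra
#'
#' d = 1 - Pearson correlation of log(pseudocount + f) across the 96
#' classes, with f the context frequencies; ranges from 0 to 2.
#'
#' @param a,b Spectra (96-class count vectors).
#' @param pseudocount Added to the frequencies before the log.
#' @return Distance, or `NA` (with a warning) when either log-vector has
#'   zero variance.
#' @export
spectrum_distance <- function(a, b, pseudocount = 0.01) {
  fa <- log(pseudocount + spectrum_frequencies(a))
  fb <- log(pseudocount + spectrum_frequencies(b))
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    warning("zero-variance log-spectrum: distance undefined")
    return(NA_real_)
  }
  1 - cor(fa, fb)
}

#' Build the 96 x samples spectrum matrix for a patient cohort
#'
#' One spectrum per CTC/WBC sample from its filtered called mutations,
#' excluding keys called in the patient's germline sample.
#'
#' @param calls Filtered call data.frame (with `patient_id`).
#' @param sheet Sample sheet.
#' @param reference Reference sequences.
#' @param classes Sample classes to include.
#' @return Matrix 96 x samples of context counts.
#' @export
sample_spectra <- function(calls, sheet, reference,
                           classes = c("ctc_single", "ctc_pool",
                                       "wbc_pool")) {
  ids <- sheet$sample_id[sheet$sample_class %in% classes]
  out <- matrix(0L, 96, length(ids),
                dimnames = list(context_classes(), ids))
  for (sid in ids) {
    pid <- sheet$patient_id[sheet$sample_id == sid]
    germ_id <- sheet$sample_id[sheet$patient_id == pid &
                                 sheet$sample_class == "germline_blood"]
    germ_keys <- calls$key[calls$sample_id %in% germ_id & calls$called]
    m <- calls[calls$sample_id == sid & calls$called &
                 !(calls$key %in% germ_keys), , drop = FALSE]
    out[, sid] <- suppressMessages(context_spectrum(m, reference))
  }
  out
}

#' Complete-linkage clustering of sample spectra
#'
#' Agglomerative clustering with complete linkage on the pairwise
#' log-correlation spectrum distances. Samples are ordered
#' lexicographically before clustering so that tie-breaking is input-order
#' invariant.
#'
#' @param spectra Matrix 96 x samples of context counts.
#' @param pseudocount Pseudocount for [spectrum_distance()].
#' @param k Optional number of flat clusters to cut.
#' @return List with `hclust`, `dist` (full matrix), `labels` (cut of size
#'   `k`, or `NULL`) and `newick` (serialized dendrogram).
#' @export
cluster_spectra <- function(spectra, pseudocount = 0.01, k = NULL) {
  if (ncol(spectra) < 2) stop("need at least 2 spectra")
  spectra <- spectra[, order(colnames(spectra)), drop = FALSE]
  n <- ncol(spectra)
  dm <- matrix(0, n, n, dimnames = list(colnames(spectra),
                                        colnames(spectra)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- spectrum_distance(spectra[, i], spectra[, j], pseudocount)
    if (is.na(d))
      stop("undefined spectrum distance between ", colnames(spectra)[i],
           " and ", colnames(spectra)[j])
    dm[i, j] <- dm[j, i] <- d
  }
  hc <- hclust(as.dist(dm), method = "complete")
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  nwk <- tryCatch(ape::write.tree(ape::as.phylo(hc)),
                  error = function(e) NA_character_)
  list(hclust = hc, dist = dm, labels = labels, newick = nwk)
}
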