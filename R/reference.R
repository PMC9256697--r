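# Reference-sequence helpers. Point mutations are 1-based (VCF convention);
# window/segment intervals everywhere else are 0-based half-open. The only
# place the two conventions meet is window_of_position().

#' Coerce a reference to named character sequences
#'
#' Accepts a `Biostrings::DNAStringSet` or a named character vector of
#' contig sequences and returns the latter (upper case).
#' @param reference DNAStringSet or named character vector.
#' @return Named character vector of contig sequences.
#' @export
as_ref_strings <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference)) {
    out <- toupper(reference)
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop("reference contigs must be named")
  out
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# clipped substring of contig `chrom` around 1-based pos
ref_window <- function(ref, chrom, pos, flank) {
  seqs <- ref[chrom]
  if (anyNA(seqs)) stop("unknown contig: ",
                        paste(unique(chrom[is.na(seqs)]), collapse = ", "))
  len <- nchar(seqs)
  if (any(pos < 1 | pos > len))
    stop("position outside reference on contig ",
         paste(unique(chrom[pos < 1 | pos > len]), collapse = ", "))
  unname(substr(seqs, pmax(1, pos - flank), pmin(len, pos + flank)))
}

# 1-based 0-based meeting point: window index (0-based) containing pos
window_of_position <- function(pos, window_size) {
  as.integer((pos - 1) %/% window_size)
}

#' The 96 canonical trinucleotide-context classes
#'
#' Pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with the 5' and 3' flanking bases, in fixed order.
#' @return Character vector of 96 labels like `"A[C>T]G"`.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f in bases) for (t in bases)
    out <- c(out, paste0(f, "[", s, "]", t))
  out
}

# collapse (trinucleotide, ref, alt) onto the pyrimidine strand.
# tri is the reference 3-mer centred on the site; returns NA for invalid
# bases or when tri is not 3 bases long (contig edge).
collapse_context <- function(tri, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(tri)
  out <- rep(NA_character_, n)
  ok <- !is.na(tri) & nchar(tri) == 3 &
    ref %in% names(comp) & alt %in% names(comp) & ref != alt
  if (!any(ok)) return(out)
  tri <- tri[ok]; ref1 <- ref[ok]; alt1 <- alt[ok]
  five <- substr(tri, 1, 1); mid <- substr(tri, 2, 2); three <- substr(tri, 3, 3)
  bad <- mid != ref1 | !(five %in% names(comp)) | !(three %in% names(comp))
  pyr <- ref1 %in% c("C", "T")
  lab <- ifelse(pyr,
                paste0(five, "[", ref1, ">", alt1, "]", three),
                paste0(comp[three], "[", comp[ref1], ">", comp[alt1], "]",
                       comp[five]))
  lab[bad] <- NA_character_
  out[ok] <- lab
  out
}

#' Generate a random synthetic reference genome
#'
#' @param n_chrom Number of contigs.
#' @param chrom_len Length of each contig in bp.
#' @param kmer Optional motif planted at `n_kmer_sites` random positions per
#'   genome (emulating loci whose sequence context matches the WGA artifact
#'   blacklist motif).
#' @param n_kmer_sites Number of planted motif copies.
#' @return List with `sequences` (named character), and `kmer_sites`
#'   (data.frame chrom/pos of planted motif starts, 1-based).
#' @export
random_reference <- function(n_chrom = 10, chrom_len = 1e6,
                             kmer = NULL, n_kmer_sites = 0) {
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  sites <- data.frame(chrom = character(0), pos = integer(0))
  if (!is.null(kmer) && n_kmer_sites > 0) {
    k <- nchar(kmer)
    sites <- data.frame(
      chrom = sample(chroms, n_kmer_sites, replace = TRUE),
      pos = sample.int(chrom_len - k - 1, n_kmer_sites) + 1L)
    for (i in seq_len(nrow(sites))) {
      ch <- sites$chrom[i]; p <- sites$pos[i]
      substr(seqs[ch], p, p + k - 1L) <- kmer
    }
  }
  list(sequences = seqs, kmer_sites = sites)
}
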