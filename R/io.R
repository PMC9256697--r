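# Readers/writers for the on-disk formats: sample sheet (TSV), somatic calls
# (VCF 4.2 with AD/DP or a TSV dialect), per-site depth tables (TSV),
# window read counts (BED-like TSV, 0-based half-open), segments (SEG-like
# TSV), gene intervals (BED) and COSMIC-count tables (TSV).

SAMPLE_CLASSES <- c("bulk_tumor", "germline_blood", "wbc_pool",
                    "ctc_single", "ctc_pool")

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with columns `sample_id`, `patient_id`,
#' `sample_class` (one of bulk_tumor, germline_blood, wbc_pool, ctc_single,
#' ctc_pool) and `n_cells`. Every patient must contribute exactly one bulk
#' tumor, one germline blood and one WBC pool sample, plus at least one CTC
#' sample.
#'
#' @param path TSV file path.
#' @return A validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate an in-memory sample sheet
#' @param df data.frame with the sample-sheet columns.
#' @return The validated data.frame with class `sample_sheet`.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "sample_class", "n_cells")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$sample_class), SAMPLE_CLASSES)
  if (length(bad)) stop("unknown sample_class: ", paste(bad, collapse = ", "))
  df$n_cells <- as.integer(df$n_cells)
  if (any(is.na(df$n_cells) | df$n_cells < 1))
    stop("n_cells must be a positive integer")
  if (any(df$sample_class %in% c("ctc_single") & df$n_cells != 1L))
    stop("ctc_single samples must have n_cells = 1: ",
         paste(df$sample_id[df$sample_class == "ctc_single" &
                              df$n_cells != 1L], collapse = ", "))
  for (pid in unique(df$patient_id)) {
    cls <- df$sample_class[df$patient_id == pid]
    for (req in c("bulk_tumor", "germline_blood", "wbc_pool")) {
      k <- sum(cls == req)
      if (k != 1L)
        stop("patient ", pid, " must have exactly one ", req,
             " sample (found ", k, ")")
    }
    if (!any(cls %in% c("ctc_single", "ctc_pool")))
      stop("patient ", pid, " has no CTC sample")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# columns every call table carries; gene/protein_change/mclass are optional
# annotations (NA when absent)
empty_calls <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             depth = integer(0), alt_reads = integer(0),
             vaf = numeric(0), called = logical(0),
             gene = character(0), protein_change = character(0),
             mclass = character(0), key = character(0),
             stringsAsFactors = FALSE)
}

mutation_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

finalize_calls <- function(df, sample_id) {
  for (col in c("gene", "protein_change", "mclass"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
  df$sample_id <- rep(sample_id, nrow(df))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_reads <- as.integer(df$alt_reads)
  if (any(df$alt_reads > df$depth, na.rm = TRUE))
    stop("alt_reads exceeds depth")
  df$vaf <- ifelse(df$depth > 0, df$alt_reads / df$depth, NA_real_)
  df$called <- as.logical(df$called)
  df$key <- mutation_key(df$chrom, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  df[, names(empty_calls())]
}

#' Read a somatic callset
#'
#' Accepts either a VCF 4.2 file with `AD` (ref,alt reads) and `DP` FORMAT
#' fields, or the TSV dialect with columns `chrom`, `pos`, `ref`, `alt`,
#' `depth`, `alt_reads`, `called` (optional annotation columns `gene`,
#' `protein_change`, `mclass`). Multi-allelic VCF records are split into one
#' call per alternate allele; indels are skipped (SNV-centric analysis) and
#' their count reported via a message.
#'
#' @param path File path (`.vcf` treated as VCF, anything else as TSV).
#' @param sample_id Sample identifier attached to every call.
#' @return Call data.frame (one row per substitution) with computed `vaf`
#'   (`NA` when depth is 0) and a `key` column `chrom:pos:ref:alt`.
#' @export
read_calls <- function(path, sample_id) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_calls_vcf(path, sample_id)
  } else {
    read_calls_tsv(path, sample_id)
  }
}

read_calls_tsv <- function(path, sample_id) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads", "called")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("call TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  indel <- nchar(df$ref) != 1 | nchar(df$alt) != 1
  if (any(indel)) {
    message("skipping ", sum(indel), " indel record(s) in ", basename(path))
    df <- df[!indel, , drop = FALSE]
  }
  if (nrow(df) == 0) return(finalize_calls(empty_calls(), sample_id))
  finalize_calls(df, sample_id)
}

read_calls_vcf <- function(path, sample_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0)
    return(finalize_calls(empty_calls(), sample_id))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF has no sample column with FORMAT data: ", basename(path))
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  dat <- strsplit(gt[, 2], ":", fixed = TRUE)
  info <- fix[, "INFO"]
  grab_info <- function(tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(tag, "="), info)
    out[hit] <- sub(paste0(".*", tag, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"),
                                             info)))
    out
  }
  gene <- grab_info("GENE"); pchg <- grab_info("AA"); mcls <- grab_info("CLS")
  rows <- vector("list", nrow(fix))
  n_indel <- 0L
  for (i in seq_len(nrow(fix))) {
    f <- fmt[[i]]; d <- dat[[i]]
    i_ad <- match("AD", f); i_dp <- match("DP", f)
    if (is.na(i_ad) || is.na(i_dp))
      stop("VCF record ", i, " lacks AD/DP FORMAT fields: ", basename(path))
    ad <- suppressWarnings(as.integer(strsplit(d[i_ad], ",")[[1]]))
    dp <- suppressWarnings(as.integer(d[i_dp]))
    if (anyNA(ad) || is.na(dp))
      stop("malformed AD/DP in VCF record ", i, " of ", basename(path))
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (nchar(ref) != 1 || nchar(alt) != 1) { n_indel <- n_indel + 1L; next }
      if (length(ad) < a + 1)
        stop("AD field too short in VCF record ", i, " of ", basename(path))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, depth = dp, alt_reads = ad[a + 1],
        called = TRUE, gene = gene[i], protein_change = pchg[i],
        mclass = mcls[i], stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_indel > 0)
    message("skipping ", n_indel, " indel allele(s) in ", basename(path))
  if (!length(rows)) return(finalize_calls(empty_calls(), sample_id))
  finalize_calls(do.call(rbind, rows), sample_id)
}

#' Write a callset as a plain-text VCF 4.2 file
#'
#' Emits one record per call with `AD` and `DP` FORMAT fields and optional
#' `GENE`/`AA`/`CLS` INFO annotations.
#' @param calls Call data.frame.
#' @param path Output path.
#' @param sample_id Sample column name in the VCF header.
#' @export
write_calls_vcf <- function(calls, path, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ctcconcord",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Protein change\">",
           "##INFO=<ID=CLS,Number=1,Type=String,Description=\"Functional class\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos, calls$alt)
    calls <- calls[o, , drop = FALSE]
    info <- rep("", nrow(calls))
    add <- function(info, tag, val) {
      has <- !is.na(val) & val != ""
      piece <- ifelse(has, paste0(tag, "=", val), "")
      ifelse(has, ifelse(info == "", piece, paste(info, piece, sep = ";")),
             info)
    }
    info <- add(info, "GENE", calls$gene)
    info <- add(info, "AA", calls$protein_change)
    info <- add(info, "CLS", calls$mclass)
    info[info == ""] <- "."
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "AD:DP",
                  paste0(calls$depth - calls$alt_reads, ",", calls$alt_reads,
                         ":", calls$depth),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write per-site depth tables
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_reads`:
#' read support of one sample at every site of the patient's mutation
#' universe (zero rows allowed).
#' @param path File path.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("depth table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_reads <- as.integer(df$alt_reads)
  df$key <- mutation_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' @rdname read_depth_table
#' @param depth Depth data.frame to write.
#' @export
write_depth_table <- function(depth, path) {
  cols <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads")
  write.table(depth[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read window read counts
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `count` where
#' intervals are 0-based half-open, sorted and non-overlapping within each
#' chromosome.
#' @param path File path.
#' @return data.frame of class `window_counts`.
#' @export
read_window_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("window counts lack column(s): ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$count <- as.integer(df$count)
  validate_windows(df)
}

#' @export
validate_windows <- function(df) {
  if (any(df$end <= df$start)) stop("window with end <= start")
  if (any(df$count < 0)) stop("negative window count")
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, ]
    if (is.unsorted(w$start, strictly = TRUE))
      stop("unsorted windows on ", ch)
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping windows on ", ch)
  }
  class(df) <- c("window_counts", "data.frame")
  df
}

#' @rdname read_window_counts
#' @param windows Window-count data.frame to write.
#' @export
write_window_counts <- function(windows, path) {
  write.table(windows[, c("chrom", "start", "end", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write segment tables (SEG-like TSV)
#'
#' Columns: `sample`, `chrom`, `start`, `end` (0-based half-open),
#' `n_windows`, `mean_log2`, `cn`, `category`.
#' @param path File path.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "n_windows", "mean_log2",
            "cn", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$n_windows <- as.integer(df$n_windows)
  df
}

#' @rdname read_segments
#' @param segments Segment data.frame to write.
#' @export
write_segments <- function(segments, path) {
  cols <- c("sample", "chrom", "start", "end", "n_windows", "mean_log2",
            "cn", "category")
  write.table(segments[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-style recurrence count table
#'
#' TSV with columns `gene`, `protein_change`, `count`; returns the table
#' plus per-gene aggregate counts.
#' @param path File path.
#' @return List with `variants` (data.frame) and `genes` (named numeric).
#' @export
read_cosmic_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "protein_change", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("COSMIC table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$count <- as.integer(df$count)
  if (any(df$count < 0)) stop("negative COSMIC count")
  genes <- tapply(df$count, df$gene, sum)
  list(variants = df, genes = genes)
}

#' Read gene intervals from a BED file
#'
#' BED3+1: `chrom`, `start`, `end`, `gene` (0-based half-open, no header).
#' @param path File path.
#' @return data.frame with chrom/start/end/gene.
#' @export
read_gene_intervals <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[, 1:4]
}

#' @export
write_gene_intervals <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a reference genome as FASTA
#' @param reference Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(as_ref_strings(reference))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_ref_strings(seqs)
}
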