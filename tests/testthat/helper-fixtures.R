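# Small in-code fixtures shared across test files.

# call-table builder
mk_calls <- function(sample_id, chrom, pos, ref = "C", alt = "T",
                     depth = 30L, alt_reads = 15L, called = TRUE,
                     gene = NA_character_,
                     protein_change = NA_character_,
                     mclass = NA_character_) {
  df <- data.frame(sample_id = sample_id, chrom = chrom,
                   pos = as.integer(pos), ref = ref, alt = alt,
                   depth = as.integer(depth),
                   alt_reads = as.integer(alt_reads), called = called,
                   gene = gene, protein_change = protein_change,
                   mclass = mclass, stringsAsFactors = FALSE)
  df$vaf <- ifelse(df$depth > 0, df$alt_reads / df$depth, NA_real_)
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}

# minimal valid sample sheet for one patient
mk_sheet <- function(pid = "P1", n_ctc = 3, n_pool = 0, pool_cells = 5) {
  data.frame(
    sample_id = c(paste0(pid, "_bulk"), paste0(pid, "_germline"),
                  paste0(pid, "_wbc"),
                  if (n_ctc) paste0(pid, "_ctc", seq_len(n_ctc)),
                  if (n_pool) paste0(pid, "_pool", seq_len(n_pool))),
    patient_id = pid,
    sample_class = c("bulk_tumor", "germline_blood", "wbc_pool",
                     rep("ctc_single", n_ctc), rep("ctc_pool", n_pool)),
    n_cells = c(1L, 1L, 1L, rep(1L, n_ctc), rep(pool_cells, n_pool)),
    stringsAsFactors = FALSE)
}

# random reference with optional planted motif
mk_ref <- function(n_chrom = 2, len = 5000, motif = NULL, motif_at = NULL) {
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  if (!is.null(motif))
    for (i in seq_len(nrow(motif_at))) {
      ch <- motif_at$chrom[i]; p <- motif_at$pos[i]
      substr(seqs[ch], p, p + nchar(motif) - 1L) <- motif
    }
  seqs
}

# a reduced scenario bundle (fewer mutations/artifacts) for faster tests
small_scenarios <- function() {
  sc <- default_scenarios()
  for (i in seq_along(sc)) {
    for (j in seq_along(sc[[i]]$clones))
      sc[[i]]$clones[[j]]$n_snvs <- max(10, sc[[i]]$clones[[j]]$n_snvs %/% 4)
    sc[[i]]$wga$ctc_single$fp_rate <- 150
    sc[[i]]$wga$ctc_pool$fp_rate <- 150
    sc[[i]]$wga$wbc_pool$fp_rate <- 15
  }
  sc
}
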