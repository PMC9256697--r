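# Driver-centric summary (oncoplot table): gene/variant selection by
# COSMIC recurrence, per-sample mutation status with read-level rescue,
# and copy-number category rows for selected driver genes.

cosmic_variant_count <- function(cosmic, gene, protein_change) {
  key <- paste(cosmic$variants$gene, cosmic$variants$protein_change)
  cnt <- setNames(cosmic$variants$count, key)
  out <- unname(cnt[paste(gene, protein_change)])
  out[is.na(out)] <- 0L
  out
}

#' Select genes for the oncoplot
#'
#' A gene is included when it carries at least `min_events` mutation events
#' across all samples whose variant-level COSMIC count is at least
#' `min_cosmic`, or when it belongs to `extra_genes` (ESR1 by default) or
#' to the configured driver-CNA gene list.
#'
#' @param mutation_events data.frame of mutation events (one row per
#'   mutation-in-sample) with `gene` and `protein_change` columns.
#' @param cosmic Output of [read_cosmic_counts()] (or a list with a
#'   `variants` data.frame).
#' @param extra_genes Genes always shown.
#' @param driver_cna_genes Genes shown for their copy-number state.
#' @param min_events,min_cosmic Selection thresholds.
#' @return Character vector of gene symbols (sorted, unique).
#' @export
select_oncoplot_genes <- function(mutation_events, cosmic,
                                  extra_genes = c("ESR1"),
                                  driver_cna_genes = character(0),
                                  min_events = 2L, min_cosmic = 20L) {
  if (!("gene" %in% names(mutation_events)))
    stop("mutation table lacks a gene column")
  ev <- mutation_events[!is.na(mutation_events$gene), , drop = FALSE]
  ev <- ev[cosmic_variant_count(cosmic, ev$gene,
                                ev$protein_change) >= min_cosmic, ,
           drop = FALSE]
  tab <- table(ev$gene)
  by_recurrence <- names(tab)[tab >= min_events]
  sort(unique(c(by_recurrence, extra_genes, driver_cna_genes)))
}

#' Select individual variants for the oncoplot
#'
#' A variant is shown when its COSMIC count is at least `min_cosmic`
#' (default 20), except for TP53 variants, for which the cutoff is
#' `tp53_cutoff` (default 5).
#'
#' @param variants data.frame with `gene` and `protein_change`.
#' @param cosmic Output of [read_cosmic_counts()].
#' @param min_cosmic,tp53_cutoff COSMIC-count cutoffs.
#' @param tp53_gene Gene symbol the relaxed cutoff applies to.
#' @return Logical vector: variant shown.
#' @export
select_oncoplot_variants <- function(variants, cosmic, min_cosmic = 20L,
                                     tp53_cutoff = 5L,
                                     tp53_gene = "TP53") {
  cnt <- cosmic_variant_count(cosmic, variants$gene,
                              variants$protein_change)
  cnt >= min_cosmic | (variants$gene %in% tp53_gene & cnt >= tp53_cutoff)
}

# category of the segment with the longest overlap with [start, end)
segment_category_at <- function(profile, chrom, start, end) {
  sg <- profile$segments
  ov <- pmin(sg$end, end) - pmax(sg$start, start)
  ov[sg$chrom != chrom] <- 0
  if (all(ov <= 0)) return(NA_character_)
  sg$category[which.max(ov)]
}

#' Build the oncoplot status grid
#'
#' One row per selected mutation (status from the call matrix with
#' read-level rescue: called / recovered / absent / no_coverage) and one
#' row per driver-CNA gene (copy-number category of the longest-overlap
#' segment), across all samples.
#'
#' @param variants data.frame of selected variants with `key`, `gene`,
#'   `protein_change`.
#' @param call_matrix A [build_call_matrix()] result covering the variant
#'   keys.
#' @param profiles Named list of `cn_profile` objects (by sample id), for
#'   the CNA rows.
#' @param gene_intervals Gene interval map (chrom/start/end/gene).
#' @param driver_cna_genes Genes to add as CNA rows.
#' @return data.frame: `feature`, `type`, one column per sample.
#' @export
oncoplot_table <- function(variants, call_matrix, profiles = list(),
                           gene_intervals = NULL,
                           driver_cna_genes = character(0)) {
  samples <- call_matrix$samples
  rows <- list()
  status_map <- c(called = "called", supported = "recovered",
                  covered_ref = "absent", no_coverage = "no_coverage")
  for (r in seq_len(nrow(variants))) {
    key <- variants$key[r]
    if (!(key %in% call_matrix$keys))
      stop("variant not in call matrix: ", key)
    st <- status_map[call_matrix$status[key, ]]
    rows[[length(rows) + 1]] <- c(
      feature = paste0(variants$gene[r], " ", variants$protein_change[r]),
      type = "mutation", st)
  }
  for (g in driver_cna_genes) {
    gi <- gene_intervals[gene_intervals$gene == g, , drop = FALSE]
    if (is.null(gene_intervals) || nrow(gi) != 1)
      stop("gene missing from interval map: ", g)
    st <- vapply(samples, function(sid) {
      pr <- profiles[[sid]]
      if (is.null(pr)) return(NA_character_)
      segment_category_at(pr, gi$chrom, gi$start, gi$end)
    }, character(1))
    rows[[length(rows) + 1]] <- c(feature = paste0(g, " CN"),
                                  type = "cna", st)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("feature", "type", samples)
  rownames(out) <- NULL
  out
}
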