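# End-to-end orchestration: filters, categorization, recovery, VAF
# statistics, spectra clustering, copy-number profiles and the driver
# summary for a whole cohort (simulated or loaded from disk).

stack_calls <- function(cohort) {
  out <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    for (sid in names(p$calls)) {
      cs <- p$calls[[sid]]
      if (nrow(cs)) { cs$patient_id <- pid; out[[length(out) + 1]] <- cs }
    }
  }
  do.call(rbind, out)
}

#' Analyze one patient
#'
#' Runs categorization, the call matrix, recovery analysis, low-coverage
#' accounting, and the VAF comparison/correlation statistics on a
#' patient's filtered calls.
#'
#' @param patient Patient entry of a cohort (list with `sheet`, `calls`,
#'   `depth`).
#' @param filtered_calls Filtered call data.frame for this patient.
#' @param cfg A [run_config()].
#' @return List of per-patient results.
#' @export
analyze_patient <- function(patient, filtered_calls, cfg = run_config()) {
  sheet <- patient$sheet
  pid <- sheet$patient_id[1]
  cats <- categorize(filtered_calls, sheet, pid)
  ctc_ids <- sheet$sample_id[sheet$sample_class %in%
                               c("ctc_single", "ctc_pool")]
  bulk_id <- sheet$sample_id[sheet$sample_class == "bulk_tumor"]
  universe <- unique(filtered_calls$key)
  cm <- build_call_matrix(universe, filtered_calls, patient$depth,
                          samples = sheet$sample_id)
  bulk_keys <- cats$categories$key[cats$categories$category %in%
                                     c("bulk_only", "ctc_bulk")]
  bulk_tab <- cats$categories[cats$categories$key %in% bulk_keys,
                              c("key", "mclass")]
  depth_ctc <- cm$depth[, ctc_ids, drop = FALSE]
  called_ctc <- cm$called[, ctc_ids, drop = FALSE]
  recovery <- if (length(bulk_keys))
    recovery_analysis(bulk_tab, called_ctc, depth_ctc, cfg) else NULL
  lowcov <- if (length(bulk_keys))
    low_coverage_fraction(bulk_keys, depth_ctc, cfg) else NULL
  selected <- if (length(bulk_keys))
    select_covered(bulk_keys, depth_ctc, cfg) else character(0)
  vafcmp <- vafcor <- NULL
  if (length(selected)) {
    bulk_calls <- filtered_calls[filtered_calls$sample_id == bulk_id, ]
    bvaf <- setNames(bulk_calls$vaf, bulk_calls$key)[selected]
    called_any <- rowSums(called_ctc[selected, , drop = FALSE]) > 0
    vafcmp <- vaf_called_vs_notcalled(bvaf, called_any)
    cvaf <- cm$alt_reads[selected, ctc_ids, drop = FALSE] /
      pmax(cm$depth[selected, ctc_ids, drop = FALSE], 1)
    cvaf[!called_ctc[selected, , drop = FALSE]] <- NA
    vafcor <- vaf_correlation(bvaf, cvaf)
  }
  list(patient_id = pid, categories = cats, call_matrix = cm,
       recovery = recovery, low_coverage = lowcov, selected = selected,
       vaf_comparison = vafcmp, vaf_correlation = vafcor)
}

#' Analyze a whole cohort
#'
#' Applies the three filters across patients, then runs the per-patient
#' mutation analyses, cohort-wide spectra clustering, per-sample
#' copy-number profiles with cross-sample concordance, and the oncoplot
#' selection.
#'
#' @param cohort A `ctc_cohort` (from [simulate_cohort()] or
#'   [load_cohort()]).
#' @param cfg A [run_config()].
#' @param cna Run the copy-number pipeline (slowest stage).
#' @param spectra_k Flat cluster count for the spectra dendrogram cut
#'   (default: number of patients).
#' @return List of class `ctc_analysis`.
#' @export
analyze_cohort <- function(cohort, cfg = run_config(), cna = TRUE,
                           spectra_k = NULL) {
  sheet <- cohort$sheet
  calls <- stack_calls(cohort)
  filt <- filter_calls(calls, cohort$reference, sheet, cfg)
  patients <- list()
  for (pid in names(cohort$patients)) {
    fc <- filt$kept[filt$kept$patient_id == pid, , drop = FALSE]
    patients[[pid]] <- analyze_patient(cohort$patients[[pid]], fc, cfg)
  }

  ## spectra over CTC samples (cohort-wide, by-patient clustering)
  ctc_sheet <- sheet[sheet$sample_class %in% c("ctc_single", "ctc_pool"), ]
  spec <- sample_spectra(filt$kept, sheet, cohort$reference,
                         classes = c("ctc_single", "ctc_pool"))
  k <- if (is.null(spectra_k)) length(unique(sheet$patient_id)) else
    spectra_k
  spec_clust <- if (ncol(spec) >= 2)
    cluster_spectra(spec, cfg$spectrum_pseudocount, k = k) else NULL

  ## copy-number profiles: CTC/pool vs WBC control, bulk vs germline
  profiles <- list(); concord <- NULL
  if (cna) {
    for (pid in names(cohort$patients)) {
      p <- cohort$patients[[pid]]
      ps <- p$sheet
      ctrl_wbc <- p$windows[[ps$sample_id[ps$sample_class == "wbc_pool"]]]
      ctrl_germ <- p$windows[[ps$sample_id[ps$sample_class ==
                                             "germline_blood"]]]
      for (i in seq_len(nrow(ps))) {
        sid <- ps$sample_id[i]; cls <- ps$sample_class[i]
        if (cls %in% c("germline_blood", "wbc_pool")) next
        ctrl <- if (cls == "bulk_tumor") ctrl_germ else ctrl_wbc
        profiles[[sid]] <- build_cn_profile(
          p$windows[[sid]], ctrl, sid,
          purity_correct = (cls == "bulk_tumor"), cfg,
          seed = derive_seed(cfg$rng_seed, i))
      }
    }
    concord <- cna_concordance(profiles)
  }

  ## driver summary
  called_events <- filt$kept[filt$kept$called, , drop = FALSE]
  onco <- NULL
  if (!is.null(cohort$cosmic)) {
    cosmic <- list(variants = cohort$cosmic)
    cna_genes <- intersect(c("MYC", "ERBB2", "CCND1", "PTEN", "RB1"),
                           cohort$genes$gene)
    genes_sel <- select_oncoplot_genes(called_events, cosmic,
                                       extra_genes = "ESR1",
                                       driver_cna_genes = cna_genes)
    vars <- called_events[!is.na(called_events$gene) &
                            called_events$gene %in% genes_sel &
                            !is.na(called_events$protein_change), ,
                          drop = FALSE]
    vars <- vars[!duplicated(vars$key),
                 c("key", "gene", "protein_change", "patient_id")]
    if (nrow(vars)) {
      vars <- vars[select_oncoplot_variants(vars, cosmic), , drop = FALSE]
      onco <- list()
      for (pid in unique(vars$patient_id)) {
        pv <- vars[vars$patient_id == pid, , drop = FALSE]
        cm <- patients[[pid]]$call_matrix
        pv <- pv[pv$key %in% cm$keys, , drop = FALSE]
        if (!nrow(pv) && !length(profiles)) next
        onco[[pid]] <- oncoplot_table(pv, cm,
                                      profiles = profiles,
                                      gene_intervals = cohort$genes,
                                      driver_cna_genes = if (cna)
                                        cna_genes else character(0))
      }
    }
  }

  structure(list(filtered = filt, patients = patients, spectra = spec,
                 spectra_clustering = spec_clust, profiles = profiles,
                 cna_concordance = concord, oncoplot = onco, cfg = cfg),
            class = "ctc_analysis")
}
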