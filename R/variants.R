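# Somatic-call filtering and the bulk/CTC mutation taxonomy.
#
# Three filters, operating on disjoint predicates so they commute and are
# idempotent:
#   1. artifact k-mer: remove calls whose flanking reference sequence
#      contains the blacklist motif (either strand),
#   2. cross-patient: remove mutation keys called in more than one patient,
#   3. VAF floor: remove calls below the VAF floor unless the mutation is
#      called in the patient's matched bulk sample.

#' Remove calls in blacklist-motif context
#'
#' A call is removed iff the artifact k-mer or its reverse complement occurs
#' in the reference window `pos +/- artifact_flank` (window clipped at
#' contig edges).
#'
#' @param calls Call data.frame.
#' @param reference Named character vector or DNAStringSet.
#' @param cfg A [run_config()].
#' @return List with `kept` and `removed` call data.frames.
#' @export
filter_artifact_kmer <- function(calls, reference, cfg = run_config()) {
  ref <- as_ref_strings(reference)
  if (nrow(calls) == 0) return(list(kept = calls, removed = calls))
  win <- ref_window(ref, calls$chrom, calls$pos, cfg$artifact_flank)
  motif <- cfg$artifact_kmer
  rc <- revcomp(motif)
  hit <- grepl(motif, win, fixed = TRUE) | grepl(rc, win, fixed = TRUE)
  list(kept = calls[!hit, , drop = FALSE],
       removed = calls[hit, , drop = FALSE])
}

#' Remove mutations recurring across patients
#'
#' Mutation keys present in the callsets of two or more distinct patients
#' are removed from every sample (recurrent cross-patient events on
#' amplified material are treated as systematic artifacts).
#'
#' @param calls Call data.frame covering all patients, with a `patient_id`
#'   column.
#' @return List with `kept` and `removed`.
#' @export
filter_cross_patient <- function(calls) {
  if (!("patient_id" %in% names(calls)))
    stop("calls need a patient_id column for the cross-patient filter")
  if (length(unique(calls$patient_id)) < 2) {
    warning("single-patient callset: cross-patient filter is a no-op")
    return(list(kept = calls, removed = calls[0, , drop = FALSE]))
  }
  npat <- tapply(calls$patient_id, calls$key,
                 function(p) length(unique(p)))
  bad <- names(npat)[npat >= 2]
  hit <- calls$key %in% bad
  list(kept = calls[!hit, , drop = FALSE],
       removed = calls[hit, , drop = FALSE])
}

#' VAF floor with bulk rescue
#'
#' A call is kept iff its VAF is at or above the floor, or its mutation key
#' is called in the patient's matched bulk sample. Calls with undefined VAF
#' (zero depth) count as below the floor.
#'
#' @param calls Call data.frame for one patient's samples.
#' @param bulk_calls The patient's bulk callset (called records).
#' @param cfg A [run_config()].
#' @return List with `kept` and `removed`.
#' @export
filter_vaf <- function(calls, bulk_calls, cfg = run_config()) {
  if (is.null(bulk_calls)) stop("bulk callset required for the VAF filter")
  in_bulk <- calls$key %in% bulk_calls$key[bulk_calls$called]
  ok <- (!is.na(calls$vaf) & calls$vaf >= cfg$vaf_floor) | in_bulk
  list(kept = calls[ok, , drop = FALSE],
       removed = calls[!ok, , drop = FALSE])
}

#' Apply all filters to a multi-patient callset
#'
#' Evaluates the artifact k-mer, cross-patient and VAF predicates on the
#' unfiltered input and removes their union, recording per removed call
#' which filter(s) hit. Because the k-mer and cross-patient predicates act
#' on whole mutation keys and the VAF rescue consults only the same key in
#' the matched bulk, this marking is identical to applying the filters
#' sequentially in the published order (k-mer, cross-patient, VAF) and is
#' independent of evaluation order.
#'
#' @param calls Call data.frame with `patient_id` column (all patients).
#' @param reference Reference sequences.
#' @param sheet Sample sheet (to locate each patient's bulk sample).
#' @param cfg A [run_config()].
#' @return List with `kept` and `removed` (the latter with a `reason`
#'   column).
#' @export
filter_calls <- function(calls, reference, sheet, cfg = run_config()) {
  if (nrow(calls) == 0) {
    out <- calls; out$reason <- character(0)
    return(list(kept = calls, removed = out))
  }
  hit_kmer <- rep(FALSE, nrow(calls))
  r1 <- filter_artifact_kmer(calls, reference, cfg)
  hit_kmer[match(rownames(r1$removed), rownames(calls))] <- TRUE
  hit_cross <- rep(FALSE, nrow(calls))
  if (length(unique(calls$patient_id)) >= 2) {
    r2 <- filter_cross_patient(calls)
    hit_cross[match(rownames(r2$removed), rownames(calls))] <- TRUE
  }
  hit_vaf <- rep(FALSE, nrow(calls))
  for (pid in unique(calls$patient_id)) {
    sel <- calls$patient_id == pid
    bulk_id <- sheet$sample_id[sheet$patient_id == pid &
                                 sheet$sample_class == "bulk_tumor"]
    sub <- calls[sel, , drop = FALSE]
    r3 <- filter_vaf(sub, sub[sub$sample_id == bulk_id, , drop = FALSE],
                     cfg)
    hit_vaf[which(sel)[match(rownames(r3$removed), rownames(sub))]] <- TRUE
  }
  hit <- hit_kmer | hit_cross | hit_vaf
  removed <- calls[hit, , drop = FALSE]
  removed$reason <- ifelse(hit_kmer[hit], "artifact_kmer",
                           ifelse(hit_cross[hit], "cross_patient",
                                  "vaf_floor"))
  list(kept = calls[!hit, , drop = FALSE], removed = removed)
}

#' Categorize a patient's mutations
#'
#' Applies the published set algebra: bulk mutations are called in the bulk
#' and absent from both the germline and the WBC pool; CTC mutations are
#' called in at least one CTC sample and absent from the WBC pool.
#' CTC mutations split into `ctc_bulk` (also bulk), `ctc_shared` (at least 2
#' CTC samples, not bulk) and `ctc_private` (exactly 1 CTC sample, not
#' bulk); bulk mutations absent from all CTCs are `bulk_only`; everything
#' else in the filtered universe is `excluded`. The labels are mutually
#' exclusive and exhaustive.
#'
#' @param calls Filtered call data.frame for one patient (all its samples).
#' @param sheet Sample sheet (the patient's rows are selected by
#'   `patient_id`).
#' @param patient_id Patient to categorize.
#' @return List with `categories` (key-level data.frame), `counts`
#'   (category totals), and `per_sample` (per-CTC-sample counts of the three
#'   CTC categories).
#' @export
categorize <- function(calls, sheet, patient_id) {
  ps <- sheet[sheet$patient_id == patient_id, ]
  if (nrow(ps) == 0) stop("unknown patient: ", patient_id)
  calls <- calls[calls$sample_id %in% ps$sample_id & calls$called, ,
                 drop = FALSE]
  id_of <- function(cls) ps$sample_id[ps$sample_class == cls]
  ctc_ids <- ps$sample_id[ps$sample_class %in% c("ctc_single", "ctc_pool")]
  keys_in <- function(ids) unique(calls$key[calls$sample_id %in% ids])
  bulk <- keys_in(id_of("bulk_tumor"))
  germ <- keys_in(id_of("germline_blood"))
  wbc <- keys_in(id_of("wbc_pool"))
  ctc_any <- keys_in(ctc_ids)
  n_ctc <- table(unique(calls[calls$sample_id %in% ctc_ids,
                              c("key", "sample_id")])$key)

  bulk_set <- setdiff(setdiff(bulk, germ), wbc)
  ctc_set <- setdiff(ctc_any, wbc)
  universe <- unique(calls$key)
  cat <- setNames(rep("excluded", length(universe)), universe)
  cat[intersect(ctc_set, bulk_set)] <- "ctc_bulk"
  sh <- setdiff(ctc_set, bulk_set)
  cat[intersect(sh, names(n_ctc)[n_ctc >= 2])] <- "ctc_shared"
  cat[intersect(sh, names(n_ctc)[n_ctc == 1])] <- "ctc_private"
  cat[setdiff(bulk_set, ctc_set)] <- "bulk_only"

  first <- calls[!duplicated(calls$key),
                 c("key", "chrom", "pos", "ref", "alt", "gene",
                   "protein_change", "mclass")]
  categories <- merge(first,
                      data.frame(key = names(cat), category = unname(cat),
                                 stringsAsFactors = FALSE), by = "key")
  categories <- categories[order(categories$chrom, categories$pos), ]
  rownames(categories) <- NULL

  lv <- c("bulk_only", "ctc_bulk", "ctc_shared", "ctc_private", "excluded")
  counts <- table(factor(categories$category, levels = lv))
  per_sample <- do.call(rbind, lapply(ctc_ids, function(sid) {
    k <- unique(calls$key[calls$sample_id == sid])
    data.frame(sample_id = sid,
               ctc_bulk = sum(cat[k] == "ctc_bulk"),
               ctc_shared = sum(cat[k] == "ctc_shared"),
               ctc_private = sum(cat[k] == "ctc_private"),
               stringsAsFactors = FALSE)
  }))
  list(categories = categories, counts = counts, per_sample = per_sample)
}

#' Per-cell evidence status with read-level rescue
#'
#' Reproduces the manual-recovery rule used for driver review: a mutation in
#' a sample is `called` when the caller flagged it, `supported` when at
#' least one read shows the alternative allele, `covered_ref` when reads
#' cover the site without alternative support, `no_coverage` otherwise.
#' Vectorized.
#'
#' @param depth,alt_reads Integer vectors.
#' @param called Logical vector (caller flag).
#' @return Character vector of statuses.
#' @export
rescue_status <- function(depth, alt_reads, called) {
  ifelse(called, "called",
         ifelse(alt_reads >= 1, "supported",
                ifelse(depth >= 1, "covered_ref", "no_coverage")))
}

#' Build a mutation-by-sample call matrix for one patient
#'
#' Combines callsets and depth tables into aligned depth / alt-read /
#' called / status matrices over a mutation universe.
#'
#' @param keys Character vector of mutation keys (rows), or a data.frame
#'   with a `key` column.
#' @param calls Call data.frame (the patient's samples).
#' @param depth_tables Named list (by sample) of depth tables.
#' @param samples Sample ids (columns); defaults to the depth table names.
#' @return List of class `call_matrix` with matrices `depth`, `alt_reads`,
#'   `called`, `status`.
#' @export
build_call_matrix <- function(keys, calls, depth_tables,
                              samples = names(depth_tables)) {
  if (is.data.frame(keys)) keys <- keys$key
  keys <- unique(keys)
  n <- length(keys); m <- length(samples)
  depth <- matrix(0L, n, m, dimnames = list(keys, samples))
  alt <- matrix(0L, n, m, dimnames = list(keys, samples))
  called <- matrix(FALSE, n, m, dimnames = list(keys, samples))
  for (sid in samples) {
    dt <- depth_tables[[sid]]
    if (!is.null(dt)) {
      i <- match(keys, dt$key)
      hit <- !is.na(i)
      depth[hit, sid] <- dt$depth[i[hit]]
      alt[hit, sid] <- dt$alt_reads[i[hit]]
    }
    cs <- calls[calls$sample_id == sid & calls$called, , drop = FALSE]
    called[, sid] <- keys %in% cs$key
    # calls may carry support at sites missing from the depth table
    j <- match(keys, cs$key); hit <- !is.na(j)
    depth[hit, sid] <- pmax(depth[hit, sid], cs$depth[j[hit]])
    alt[hit, sid] <- pmax(alt[hit, sid], cs$alt_reads[j[hit]])
  }
  status <- matrix(rescue_status(depth, alt, called), n, m,
                   dimnames = list(keys, samples))
  bad <- called & alt < 1
  if (any(bad))
    stop("inconsistent call matrix: called without alt support at ",
         paste(head(keys[row(bad)[bad]]), collapse = ", "))
  structure(list(keys = keys, samples = samples, depth = depth,
                 alt_reads = alt, called = called, status = status),
            class = "call_matrix")
}
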