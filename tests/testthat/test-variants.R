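# Filters and the mutation taxonomy: oracle equivalence, idempotence,
# commutation, rescue statuses.

test_that("artifact k-mer filter removes motif context on either strand", {
  cfg <- run_config()
  motif <- cfg$artifact_kmer
  set.seed(1)
  ref <- mk_ref(1, 4000, motif = motif,
                motif_at = data.frame(chrom = "chr1", pos = c(1000L, 2000L)))
  # plant the reverse complement as well
  substr(ref["chr1"], 3000, 3011) <- revcomp(motif)
  calls <- mk_calls("S1", "chr1", c(1005, 2011, 3004, 500))
  res <- filter_artifact_kmer(calls, ref, cfg)
  expect_setequal(res$removed$pos, c(1005, 2011, 3004))
  expect_equal(res$kept$pos, 500)
})

test_that("k-mer filter matches an exhaustive substring-scan oracle", {
  cfg <- run_config()
  set.seed(2)
  ref <- mk_ref(2, 6000, motif = cfg$artifact_kmer,
                motif_at = data.frame(chrom = c("chr1", "chr2"),
                                      pos = c(1500L, 4000L)))
  pos <- sample(20:5980, 300)
  calls <- mk_calls("S1", sample(c("chr1", "chr2"), 300, replace = TRUE), pos)
  calls <- calls[!duplicated(calls$key), ]
  res <- filter_artifact_kmer(calls, ref, cfg)
  oracle <- vapply(seq_len(nrow(calls)), function(i) {
    w <- substr(ref[calls$chrom[i]],
                max(1, calls$pos[i] - cfg$artifact_flank),
                min(nchar(ref[calls$chrom[i]]),
                    calls$pos[i] + cfg$artifact_flank))
    oracle_kmer_hit(w, cfg$artifact_kmer)
  }, logical(1))
  expect_setequal(res$removed$key, calls$key[oracle])
  # idempotence
  again <- filter_artifact_kmer(res$kept, ref, cfg)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$removed), 0)
})

test_that("cross-patient filter removes keys shared between patients", {
  a <- mk_calls("P1_bulk", "chr1", c(10, 20)); a$patient_id <- "P1"
  b <- mk_calls("P2_ctc1", "chr1", c(20, 30)); b$patient_id <- "P2"
  res <- filter_cross_patient(rbind(a, b))
  expect_setequal(res$removed$pos, 20)       # removed from both patients
  expect_equal(nrow(res$removed), 2)
  expect_setequal(res$kept$pos, c(10, 30))
  # same key in two samples of one patient is kept
  c1 <- mk_calls(c("P1_bulk", "P1_ctc1"), "chr1", c(40, 40))
  c1$patient_id <- "P1"
  d <- mk_calls("P2_bulk", "chr1", 50); d$patient_id <- "P2"
  res2 <- filter_cross_patient(rbind(c1, d))
  expect_equal(nrow(res2$removed), 0)
  expect_warning(filter_cross_patient(d), "single-patient")
})

test_that("cross-patient filter equals the set-intersection oracle", {
  set.seed(3)
  for (rep in 1:10) {
    calls <- do.call(rbind, lapply(c("P1", "P2", "P3"), function(pid) {
      cs <- mk_calls(paste0(pid, "_s", sample(3, 1)), "chr1",
                     sample(1:60, 25, replace = TRUE))
      cs <- cs[!duplicated(cs$key), ]; cs$patient_id <- pid; cs
    }))
    res <- filter_cross_patient(calls)
    keysets <- lapply(split(calls$key, calls$patient_id), unique)
    shared <- names(which(table(unlist(keysets)) >= 2))
    expect_setequal(unique(res$removed$key), shared)
    expect_setequal(unique(res$kept$key), setdiff(calls$key, shared))
  }
})

test_that("VAF filter keeps low-VAF calls only when present in bulk", {
  cfg <- run_config()
  bulk <- mk_calls("P1_bulk", "chr1", c(100, 200))
  calls <- mk_calls("P1_ctc1", "chr1", c(100, 300, 400, 500),
                    depth = 100L, alt_reads = c(15L, 15L, 20L, 60L))
  res <- filter_vaf(calls, bulk, cfg)
  expect_true(100 %in% res$kept$pos)    # vaf 0.15 but called in bulk
  expect_true(300 %in% res$removed$pos) # vaf 0.15, absent from bulk
  expect_true(400 %in% res$kept$pos)    # vaf exactly at the floor: kept
  expect_true(500 %in% res$kept$pos)
  expect_error(filter_vaf(calls, NULL, cfg), "bulk")
  # idempotence
  again <- filter_vaf(res$kept, bulk, cfg)
  expect_equal(again$kept, res$kept)
})

test_that("filters commute on randomized multi-patient callsets", {
  cfg <- run_config()
  set.seed(4)
  ref <- mk_ref(1, 8000, motif = cfg$artifact_kmer,
                motif_at = data.frame(chrom = "chr1", pos = 3000L))
  sheet <- rbind(mk_sheet("P1", 2), mk_sheet("P2", 2))
  for (rep in 1:5) {
    calls <- do.call(rbind, lapply(c("P1", "P2"), function(pid) {
      ids <- sheet$sample_id[sheet$patient_id == pid]
      cs <- do.call(rbind, lapply(ids, function(sid)
        mk_calls(sid, "chr1", sample(100:7900, 40),
                 depth = 100L,
                 alt_reads = as.integer(sample(c(10, 30, 60), 40, TRUE)))))
      cs <- cs[!duplicated(paste(cs$sample_id, cs$key)), ]
      cs$patient_id <- pid
      cs
    }))
    ab <- filter_calls(calls, ref, sheet, cfg)
    # sequential published order: k-mer, cross-patient, then VAF
    keep <- filter_artifact_kmer(calls, ref, cfg)$kept
    keep <- filter_cross_patient(keep)$kept
    keep <- do.call(rbind, lapply(unique(keep$patient_id), function(pid) {
      sub <- keep[keep$patient_id == pid, ]
      bulk <- sub[sub$sample_id == paste0(pid, "_bulk"), ]
      filter_vaf(sub, bulk, cfg)$kept
    }))
    expect_setequal(paste(ab$kept$sample_id, ab$kept$key),
                    paste(keep$sample_id, keep$key))
    # k-mer <-> cross-patient swap freely (both are key-level predicates)
    s1 <- filter_cross_patient(filter_artifact_kmer(calls, ref, cfg)$kept)
    s2 <- filter_artifact_kmer(filter_cross_patient(calls)$kept, ref, cfg)
    expect_setequal(paste(s1$kept$sample_id, s1$kept$key),
                    paste(s2$kept$sample_id, s2$kept$key))
    # k-mer <-> VAF swap freely (VAF never removes bulk calls, so the
    # rescue set is unaffected)
    p1 <- calls[calls$patient_id == "P1", ]
    bulk1 <- p1[p1$sample_id == "P1_bulk", ]
    a <- filter_vaf(filter_artifact_kmer(p1, ref, cfg)$kept, bulk1, cfg)
    bkept <- filter_vaf(p1, bulk1, cfg)$kept
    b <- filter_artifact_kmer(bkept, ref, cfg)
    expect_setequal(paste(a$kept$sample_id, a$kept$key),
                    paste(b$kept$sample_id, b$kept$key))
  }
})

test_that("categorize matches the brute-force set-algebra oracle", {
  set.seed(5)
  sheet <- mk_sheet("P1", n_ctc = 3, n_pool = 1)
  classes <- setNames(sheet$sample_class, sheet$sample_id)
  for (rep in 1:20) {
    called_sets <- lapply(sheet$sample_id, function(s)
      paste0("chr1:", sample(1:40, sample(5:25, 1)), ":C:T"))
    names(called_sets) <- sheet$sample_id
    calls <- do.call(rbind, lapply(sheet$sample_id, function(s) {
      pos <- as.integer(sub("chr1:(\\d+):C:T", "\\1", called_sets[[s]]))
      mk_calls(s, "chr1", pos)
    }))
    res <- categorize(calls, sheet, "P1")
    oracle <- oracle_categorize(called_sets, classes)
    got <- setNames(res$categories$category, res$categories$key)
    expect_equal(got[names(oracle)], oracle)
    # partition identity over CTC mutations
    n_ctc_mut <- sum(oracle %in% c("ctc_bulk", "ctc_shared", "ctc_private"))
    expect_equal(sum(res$counts[c("ctc_bulk", "ctc_shared", "ctc_private")]),
                 n_ctc_mut)
    # exhaustive and exclusive
    expect_equal(sum(res$counts), length(oracle))
  }
})

test_that("categorize honors the published category definitions", {
  sheet <- mk_sheet("P1", n_ctc = 3)
  # key A: bulk + 3 CTCs, absent WBC/germline -> ctc_bulk
  # key B: exactly 2 CTCs, absent bulk -> ctc_shared
  # key C: 1 CTC only -> ctc_private
  # key D: bulk + germline -> excluded
  calls <- rbind(
    mk_calls(c("P1_bulk", "P1_ctc1", "P1_ctc2", "P1_ctc3"), "chr1", 1),
    mk_calls(c("P1_ctc1", "P1_ctc2"), "chr1", 2),
    mk_calls("P1_ctc3", "chr1", 3),
    mk_calls(c("P1_bulk", "P1_germline"), "chr1", 4))
  res <- categorize(calls, sheet, "P1")
  got <- setNames(res$categories$category, res$categories$pos)
  expect_equal(unname(got[c("1", "2", "3", "4")]),
               c("ctc_bulk", "ctc_shared", "ctc_private", "excluded"))
})

test_that("rescue_status implements the recovery precedence rules", {
  expect_equal(rescue_status(10L, 2L, FALSE), "supported")   # recovered
  expect_equal(rescue_status(0L, 0L, FALSE), "no_coverage")  # stricken cell
  expect_equal(rescue_status(3L, 5L, TRUE), "called")        # caller wins
  expect_equal(rescue_status(8L, 0L, FALSE), "covered_ref")
  expect_equal(rescue_status(c(10L, 0L), c(2L, 0L), c(FALSE, FALSE)),
               c("supported", "no_coverage"))
})

test_that("call matrix statuses are consistent with depth/alt counts", {
  sheet <- mk_sheet("P1", 2)
  calls <- rbind(mk_calls("P1_bulk", "chr1", c(1, 2)),
                 mk_calls("P1_ctc1", "chr1", 1))
  depth_tables <- list(
    P1_bulk = data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "C",
                         alt = "T", depth = c(30L, 30L),
                         alt_reads = c(15L, 15L),
                         key = c("chr1:1:C:T", "chr1:2:C:T")),
    P1_ctc1 = data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "C",
                         alt = "T", depth = c(25L, 0L),
                         alt_reads = c(12L, 0L),
                         key = c("chr1:1:C:T", "chr1:2:C:T")),
    P1_ctc2 = data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "C",
                         alt = "T", depth = c(9L, 14L),
                         alt_reads = c(1L, 0L),
                         key = c("chr1:1:C:T", "chr1:2:C:T")))
  cm <- build_call_matrix(c("chr1:1:C:T", "chr1:2:C:T"), calls,
                          depth_tables)
  expect_equal(cm$status["chr1:1:C:T", "P1_ctc1"], "called")
  expect_equal(cm$status["chr1:1:C:T", "P1_ctc2"], "supported")
  expect_equal(cm$status["chr1:2:C:T", "P1_ctc1"], "no_coverage")
  expect_equal(cm$status["chr1:2:C:T", "P1_ctc2"], "covered_ref")
})
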