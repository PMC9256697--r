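# Synthetic-data generator: determinism, noise-model calibration, truth
# conservation and the statistical structure the pipeline assumes.

test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(small_scenarios(), run_config(), seed = 101)
  b <- simulate_cohort(small_scenarios(), run_config(), seed = 101)
  expect_identical(a$reference, b$reference)
  expect_identical(a$patients$P1$calls, b$patients$P1$calls)
  expect_identical(a$patients$P3$windows, b$patients$P3$windows)
  expect_identical(a$patients$P2$truth$mutations,
                   b$patients$P2$truth$mutations)
})

test_that("written datasets round-trip through the readers", {
  co <- simulate_cohort(small_scenarios(), run_config(), seed = 102)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  got <- load_cohort(dir)
  expect_equal(nrow(got$sheet), nrow(co$sheet))
  expect_equal(got$reference, co$reference)
  for (sid in names(co$patients$P1$calls)) {
    a <- co$patients$P1$calls[[sid]]; b <- got$patients$P1$calls[[sid]]
    expect_setequal(a$key, b$key)
    expect_equal(a$depth[order(a$key)], b$depth[order(b$key)])
  }
  expect_equal(got$patients$P2$windows$P2_bulk$count,
               co$patients$P2$windows$P2_bulk$count)
})

test_that("noiseless WGA limit calls every truncal mutation in every CTC", {
  sc <- small_scenarios()["P1"]
  clean <- wga_model(ado_rate = 0, locus_dropout_rate = 0, fp_rate = 0,
                     coverage_mean = 200, coverage_dispersion = 50)
  sc$P1$wga$ctc_single <- clean
  sc$P1$wga$ctc_pool <- clean
  co <- simulate_cohort(sc, run_config(), seed = 103)
  p <- co$patients$P1
  truncal <- p$truth$mutations$key[p$truth$mutations$type == "truncal"]
  ctc_ids <- p$sheet$sample_id[p$sheet$sample_class %in%
                                 c("ctc_single", "ctc_pool")]
  for (sid in ctc_ids)
    expect_true(all(truncal %in% p$calls[[sid]]$key))
})

test_that("read sampling follows the stated depth and allele models", {
  set.seed(104)
  # total locus dropout: depth always 0
  all_drop <- sample_reads_at_site(rep(0.5, 200),
                                   wga_model(locus_dropout_rate = 1))
  expect_true(all(all_drop$depth == 0))
  # no alternate allele, no noise: alt reads always 0
  none <- sample_reads_at_site(rep(0, 500), wga_model(ado_rate = 0,
                                                      locus_dropout_rate = 0))
  expect_true(all(none$alt_reads == 0))
  # law of large numbers at VAF 0.5 without dropout
  r <- sample_reads_at_site(rep(0.5, 1e5),
                            wga_model(ado_rate = 0, locus_dropout_rate = 0,
                                      coverage_mean = 40))
  v <- r$alt_reads[r$depth > 0] / r$depth[r$depth > 0]
  expect_lt(abs(mean(v) - 0.5), 0.005)
})

test_that("heterozygous detection matches the closed-form dropout rate", {
  set.seed(105)
  n <- 4000
  w <- wga_model(ado_rate = 0.3, locus_dropout_rate = 0.4,
                 coverage_mean = 150, coverage_dispersion = 20)
  r <- sample_reads_at_site(rep(0.5, n), w)
  v <- ifelse(r$depth > 0, r$alt_reads / r$depth, 0)
  detected <- r$alt_reads >= w$caller_min_alt & v >= w$caller_min_vaf
  p_expect <- (1 - 0.3) * (1 - 0.4)
  expect_lt(abs(mean(detected) - p_expect), 3 * sqrt(p_expect / n))
})

test_that("artifact injection follows rate, spectrum and uniqueness", {
  set.seed(106)
  genome <- random_reference(2, 100000, kmer = "TTAACTGACAGC",
                             n_kmer_sites = 10)
  pool <- ctcconcord:::build_site_pool(genome$sequences, 40000)
  none <- inject_artifacts(pool, 0, disjoint_spectrum(1, 3))
  expect_equal(nrow(none), 0)
  counts <- vapply(1:40, function(i)
    nrow(inject_artifacts(pool, 50, disjoint_spectrum(1, 3))), numeric(1))
  expect_lt(abs(mean(counts) - 50), 5)  # Poisson mean
  # order-of-magnitude contrast between CTC and WBC rates
  big <- inject_artifacts(pool, 800, disjoint_spectrum(1, 3))
  small <- inject_artifacts(pool, 60, disjoint_spectrum(1, 3))
  expect_gt(nrow(big) / nrow(small), 5)
})

test_that("disjoint artifact spectra yield uncorrelated context histograms", {
  cors <- vapply(1:10, function(s) {
    set.seed(200 + s)
    genome <- random_reference(2, 100000)
    pool <- ctcconcord:::build_site_pool(genome$sequences, 40000)
    a <- inject_artifacts(pool, 400, disjoint_spectrum(1, 2))
    b <- inject_artifacts(pool, 400, disjoint_spectrum(2, 2))
    sa <- context_spectrum(a, genome$sequences)
    sb <- context_spectrum(b, genome$sequences)
    cor(as.numeric(sa), as.numeric(sb))
  }, numeric(1))
  expect_true(all(cors < 0.2))
})

test_that("every emitted call is traceable to exactly one truth category", {
  co <- simulate_cohort(small_scenarios(), run_config(), seed = 107)
  for (pid in names(co$patients)) {
    p <- co$patients[[pid]]
    tumor_keys <- p$truth$mutations$key
    for (sid in names(p$calls)) {
      art_keys <- p$truth$artifacts$key[p$truth$artifacts$sample_id == sid]
      in_tumor <- p$calls[[sid]]$key %in% tumor_keys
      in_art <- p$calls[[sid]]$key %in% art_keys
      expect_true(all(xor(in_tumor, in_art)))
    }
  }
})

test_that("bulk VAF of truncal mutations concentrates at purity/2", {
  co <- simulate_cohort(small_scenarios(), run_config(), seed = 108)
  p <- co$patients$P2            # P2 truncal region mostly diploid
  tr <- p$truth$mutations
  cn2 <- tr$key[tr$type == "truncal"]
  bulk <- p$depth$P2_bulk
  # restrict to diploid windows via the truth clone CN
  grid <- p$truth$window_grid
  widx <- match(paste(bulk$chrom, (bulk$pos - 1) %/% 10000),
                paste(grid$chrom, grid$start %/% 10000))
  dip <- rowSums(p$truth$clone_cn[widx, , drop = FALSE] != 2) == 0
  sel <- bulk$key %in% cn2 & dip & bulk$depth > 0
  vaf <- bulk$alt_reads[sel] / bulk$depth[sel]
  expect_lt(abs(mean(vaf) - p$truth$purity / 2), 0.02)
})

test_that("bulk window counts follow the purity mixture expectation", {
  co <- simulate_cohort(small_scenarios(), run_config(), seed = 109)
  p <- co$patients$P2
  rho <- p$truth$purity
  qbar <- as.numeric(p$truth$clone_cn %*%
                       p$truth$clones$f_excl)
  level <- rho * qbar + 2 * (1 - rho)
  tau <- sum(level) / length(level)
  obs <- p$windows$P2_bulk$count / sum(p$windows$P2_bulk$count)
  expected <- level / sum(level)
  # compare mean observed/expected ratio inside the big ERBB2-like event
  ev <- p$truth$window_grid$chrom == "chr7" &
    p$truth$window_grid$start >= 400000 & p$truth$window_grid$end <= 800000
  expect_lt(abs(mean(obs[ev]) / mean(expected[ev]) - 1), 0.05)
})

test_that("infeasible clone trees are rejected", {
  expect_error(sim_scenario(
    "X", 0.3,
    clones = list(list(clone_id = "C1", parent = NA, ccf_bulk = 1,
                       n_snvs = 5, cn_events = NULL),
                  list(clone_id = "A", parent = "C1", ccf_bulk = 1.2,
                       n_snvs = 5, cn_events = NULL)),
    ctc_singles = "C1"), "infeasible")
  expect_error(sim_scenario(
    "X", 0.3,
    clones = list(list(clone_id = "C1", parent = NA, ccf_bulk = 0.9,
                       n_snvs = 5, cn_events = NULL)),
    ctc_singles = "C1"), "truncal")
})
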