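# Copy-number pipeline: control normalization, circular binary
# segmentation, purity/ploidy correction, ploidy normalization,
# categorization and concordance.

mk_log2 <- function(mu, sd = 0.1, chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(mu)
  data.frame(chrom = chrom, start = seq(0L, by = 10000L, length.out = n),
             end = seq(10000L, by = 10000L, length.out = n),
             log2 = rnorm(n, mu, sd), stringsAsFactors = FALSE)
}

test_that("control normalization is library-size scaled and masks bad windows", {
  w <- data.frame(chrom = "chr1", start = seq(0L, by = 10000L, length.out = 10),
                  end = seq(10000L, by = 10000L, length.out = 10))
  s <- w; s$count <- rep(100L, 10)
  ctrl <- w; ctrl$count <- rep(100L, 10)
  res <- normalize_to_control(validate_windows(s), validate_windows(ctrl))
  expect_equal(res$log2, rep(0, 10))          # sample = control
  # sample exactly 2x control in half the genome: closed form
  s2 <- w; s2$count <- rep(c(200L, 100L), each = 5)
  res2 <- normalize_to_control(validate_windows(s2), validate_windows(ctrl))
  expect_equal(res2$log2[1:5], rep(log2((200 / 1500) / (100 / 1000)), 5))
  expect_equal(res2$log2[6:10], rep(log2((100 / 1500) / (100 / 1000)), 5))
  expect_equal(res2$log2[1] - res2$log2[10], 1)  # the halves differ 2-fold
  # zero-count control window is masked, not infinite
  ctrl0 <- ctrl; ctrl0$count[3] <- 0L
  res3 <- normalize_to_control(validate_windows(s), validate_windows(ctrl0))
  expect_true(is.na(res3$log2[3]))
  expect_true(all(is.finite(res3$log2[-3])))
  # mismatched grids error
  bad <- ctrl; bad$start <- bad$start + 10000L; bad$end <- bad$end + 10000L
  expect_error(normalize_to_control(validate_windows(s),
                                    validate_windows(bad)), "grids")
})

test_that("a noiseless two-level step is split exactly once at the boundary", {
  x <- mk_log2(rep(c(0, 1), each = 25), sd = 0)
  # add microscopic jitter so the permutation distribution is non-degenerate
  set.seed(1); x$log2 <- x$log2 + rnorm(50, 0, 1e-6)
  sg <- cbs_segment(x, run_config(), seed = 1)
  expect_equal(nrow(sg$segments), 2)
  expect_equal(sg$segments$start, c(0L, 250000L))
  expect_equal(sg$segments$n_windows, c(25L, 25L))
})

test_that("i.i.d. noise yields a single segment in most seeded runs", {
  splits <- vapply(1:20, function(s) {
    x <- mk_log2(rep(0, 150), sd = 0.1, seed = s)
    nrow(cbs_segment(x, run_config(), seed = s)$segments) > 1
  }, logical(1))
  expect_lte(mean(splits), 0.1)
})

test_that("segment partition and weighted-mean identities hold", {
  x <- mk_log2(rep(c(0, 0.8, -0.6), c(40, 30, 30)), sd = 0.1, seed = 2)
  x$log2[c(5, 50)] <- NA          # masked windows belong to no segment
  sg <- cbs_segment(x, run_config(), seed = 2)
  unmasked <- !is.na(x$log2)
  expect_true(all(!is.na(sg$windows$segment[unmasked])))
  expect_true(all(is.na(sg$windows$segment[!unmasked])))
  wmean <- sum(sg$segments$mean_log2 * sg$segments$n_windows) /
    sum(sg$segments$n_windows)
  expect_equal(wmean, mean(x$log2[unmasked]), tolerance = 1e-9)
})

test_that("multi-chromosome segmentation recovers per-chromosome structure", {
  set.seed(3)
  a <- mk_log2(rep(c(0, 0.7), c(30, 20)), chrom = "chr1")
  b <- mk_log2(rep(0, 40), chrom = "chr2")
  sg <- cbs_segment(rbind(a, b), run_config(), seed = 3)
  expect_equal(sum(sg$segments$chrom == "chr1"), 2)
  expect_equal(sum(sg$segments$chrom == "chr2"), 1)
})

test_that("pure-tumor integer profiles are recovered exactly", {
  set.seed(4)
  cn <- rep(c(2, 4, 1, 3, 2), each = 30)
  sim <- simulate_cn_windows(length(cn), cn, purity = 1,
                             base_count = 5000, size = 5000)
  l2 <- normalize_to_control(sim$tumor, sim$control)
  sg <- cbs_segment(l2, run_config(), seed = 4)
  fit <- fit_purity_ploidy(sg$segments, run_config())
  expect_equal(fit$rho, 1)
  expect_true(fit$admissible)
  expect_equal(round(fit$q), c(2, 4, 1, 3, 2)[cumsum(sg$segments$n_windows) %/% 30])
})

test_that("impure bulk purity is recovered on clean profiles", {
  set.seed(5)
  cn <- rep(c(2, 3, 1, 4, 2, 1, 3, 2), c(60, 40, 30, 25, 60, 35, 30, 60))
  for (rho in c(0.20, 0.35, 0.50)) {
    sim <- simulate_cn_windows(length(cn), cn, purity = rho,
                               base_count = 4000, size = 2000)
    l2 <- normalize_to_control(sim$tumor, sim$control)
    sg <- cbs_segment(l2, run_config(), seed = 5)
    fit <- fit_purity_ploidy(sg$segments, run_config())
    expect_true(fit$admissible)
    expect_lte(abs(fit$rho - rho), 0.05)
    # windows assigned the true integer copy number
    qwin <- round(fit$q)[sg$windows$segment]
    expect_gte(mean(qwin == cn, na.rm = TRUE), 0.95)
  }
})

test_that("flat diploid profiles are flagged degenerate and left at CN 2", {
  set.seed(6)
  sim <- simulate_cn_windows(200, rep(2, 200), purity = 0.5,
                             base_count = 4000, size = 2000)
  pr <- build_cn_profile(sim$tumor, sim$control, "S", purity_correct = TRUE,
                         run_config(), seed = 6)
  fit <- pr$purity_fit
  expect_false(is.null(fit$degenerate) && is.null(fit$used))
  expect_true(all(pr$segments$category == "neutral"))
  expect_equal(pr$segments$cn, rep(2, nrow(pr$segments)), tolerance = 0.1)
})

test_that("ploidy-2 normalization rescales to a weighted mean of 2", {
  set.seed(7)
  # triploid tumor (known pure) with one extra gain: CN' = 2q/tau closed
  # form; tau is the window-weighted mean copy number 3.2
  cn <- rep(c(3, 4, 3), c(80, 40, 80))
  sim <- simulate_cn_windows(length(cn), cn, purity = 1,
                             base_count = 5000, size = 5000)
  l2 <- normalize_to_control(sim$tumor, sim$control)
  sg <- cbs_segment(l2, run_config(), seed = 7)
  f <- fit_purity_ploidy(sg$segments, run_config(), rho_grid = 1)
  expect_true(f$admissible)
  expect_equal(sort(unique(round(f$q))), c(3, 4))
  expect_equal(f$tau, 3.2, tolerance = 0.051)
  cn2 <- f$q * 2 / f$tau
  expect_equal(sort(unique(round(cn2 * 1.6))), c(3, 4))  # 2q/3.2 scale
  # uniform tetraploid rescales to 2 everywhere (degenerate flat profile)
  sim2 <- simulate_cn_windows(150, rep(4, 150), purity = 1,
                              base_count = 4000, size = 2000)
  pr2 <- build_cn_profile(sim2$tumor, sim2$control, "S",
                          purity_correct = TRUE, run_config(), seed = 8)
  expect_equal(pr2$segments$cn, rep(2, nrow(pr2$segments)), tolerance = 0.1)
})

test_that("copy-number categories use strict printed thresholds", {
  cfg <- run_config()
  expect_equal(categorize_cn(c(4.5, 2.0, 0.5, 2.5, 4.0, 1.49, 0.8, 2.6), cfg),
               c("amp", "neutral", "deep_del", "neutral", "gain", "del",
                 "del", "gain"))
})

test_that("count_cnas counts non-neutral segments", {
  pr <- list(segments = data.frame(category = c("neutral", "gain", "del",
                                                "gain", "del", "neutral")))
  expect_equal(count_cnas(pr), 4)
  expect_equal(count_cnas(list(segments = data.frame(category = "neutral"))),
               0)
})

test_that("profile concordance: self-correlation 1, oracle equivalence", {
  set.seed(9)
  cn_a <- rep(c(2, 4, 1, 2, 3), each = 40)
  cn_b <- rep(c(2, 1, 3, 2, 4), each = 40)
  pa <- simulate_cn_windows(length(cn_a), cn_a, 1, 4000, 2000)
  pb <- simulate_cn_windows(length(cn_b), cn_b, 1, 4000, 2000)
  pr_a <- build_cn_profile(pa$tumor, pa$control, "A", FALSE, run_config(), 1)
  pr_b <- build_cn_profile(pb$tumor, pb$control, "B", FALSE, run_config(), 2)
  pr_a2 <- pr_a; pr_a2$sample_id <- "A2"
  cc <- cna_concordance(list(pr_a, pr_a2, pr_b))
  expect_equal(cc$rho["A", "A2"], 1)
  ok <- complete.cases(cbind(pr_a$windows$cn, pr_b$windows$cn))
  expect_equal(cc$rho["A", "B"],
               oracle_spearman(pr_a$windows$cn[ok], pr_b$windows$cn[ok]),
               tolerance = 1e-12)
})

test_that("same-clone CTC profiles are highly concordant when CNAs abound", {
  # aberration-rich genome (over half the windows non-diploid)
  set.seed(10)
  cn <- rep(c(2, 4, 1, 3, 2, 5, 1, 2, 3, 1), each = 30)
  prof <- lapply(1:3, function(i) {
    sim <- simulate_cn_windows(length(cn), cn, 1, 4000, 1000)
    build_cn_profile(sim$tumor, sim$control, paste0("ctc", i), FALSE,
                     run_config(), seed = 10 + i)
  })
  cc <- cna_concordance(prof)
  off <- cc$rho[upper.tri(cc$rho)]
  expect_true(all(off > 0.9))
})

test_that("low-purity bulk copy numbers are noisier than matched CTC", {
  set.seed(11)
  cn <- rep(c(2, 4, 1, 3, 2), each = 40)
  bulk <- simulate_cn_windows(length(cn), cn, purity = 0.25, 2000, 800)
  ctc <- simulate_cn_windows(length(cn), cn, purity = 1, 2000, 800)
  pr_b <- build_cn_profile(bulk$tumor, bulk$control, "bulk", TRUE,
                           run_config(), 1)
  pr_c <- build_cn_profile(ctc$tumor, ctc$control, "ctc", FALSE,
                           run_config(), 2)
  # window-level CN residuals around segment means, on the ploidy-2 scale
  resid_var <- function(pr, l2df) {
    f <- pr$purity_fit
    R <- 2^l2df$log2
    if (!is.null(f) && isTRUE(f$admissible)) {
      D <- f$rho * f$tau + 2 * (1 - f$rho)
      qw <- (R * D - 2 * (1 - f$rho)) / f$rho
      cnw <- qw * 2 / f$tau
    } else cnw <- 2 * R
    stats::var(cnw - pr$segments$cn[pr$windows$segment], na.rm = TRUE)
  }
  l2b <- normalize_to_control(bulk$tumor, bulk$control)
  l2c <- normalize_to_control(ctc$tumor, ctc$control)
  expect_gt(resid_var(pr_b, l2b), resid_var(pr_c, l2c))
})
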