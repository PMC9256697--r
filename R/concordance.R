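# Recovery of bulk mutations in CTC samples: coverage-conditioned
# selection, low-coverage accounting, recovery curves over CTC sample
# subsets, and VAF comparison / correlation statistics.

#' Select adequately covered bulk mutations
#'
#' A bulk mutation is selected when its depth reaches
#' `cfg$min_select_depth` in at least one CTC sample.
#'
#' @param bulk_keys Character vector of bulk mutation keys.
#' @param depth Matrix of depths, keys x CTC samples (missing sites count
#'   as depth 0).
#' @param cfg A [run_config()].
#' @return Character vector, the selected subset of `bulk_keys`.
#' @export
select_covered <- function(bulk_keys, depth, cfg = run_config()) {
  d <- matrix(0L, length(bulk_keys), ncol(depth),
              dimnames = list(bulk_keys, colnames(depth)))
  hit <- bulk_keys %in% rownames(depth)
  d[hit, ] <- depth[bulk_keys[hit], , drop = FALSE]
  bulk_keys[apply(d, 1, max) >= cfg$min_select_depth]
}

#' Low-coverage fraction of bulk mutations in CTC samples
#'
#' Pooled fraction of (bulk mutation, CTC sample) pairs with depth below
#' `cfg$low_cov_depth`, plus the per-sample fractions and, as a secondary
#' definition, the per-key fraction (keys whose *best* CTC depth is below
#' the cutoff).
#'
#' @inheritParams select_covered
#' @return List with `pooled`, `per_sample` (named numeric) and
#'   `per_key_max` fractions.
#' @export
low_coverage_fraction <- function(bulk_keys, depth, cfg = run_config()) {
  d <- matrix(0L, length(bulk_keys), ncol(depth),
              dimnames = list(bulk_keys, colnames(depth)))
  hit <- bulk_keys %in% rownames(depth)
  d[hit, ] <- depth[bulk_keys[hit], , drop = FALSE]
  low <- d < cfg$low_cov_depth
  list(pooled = mean(low),
       per_sample = colMeans(low),
       per_key_max = mean(apply(d, 1, max) < cfg$low_cov_depth))
}

#' Recovery curve of bulk mutations over CTC sample subsets
#'
#' For each subset size k of the CTC samples, the fraction of bulk
#' mutations called in at least one sample of the subset is computed over
#' all subsets (exhaustively when `choose(n, k)` does not exceed
#' `cfg$max_exhaustive_subsets`, otherwise over that many seeded uniform
#' Monte-Carlo draws), and summarized as median / min / max.
#'
#' @param bulk_keys Character vector of bulk mutation keys (nonempty).
#' @param called Logical matrix, keys x CTC samples: key called in sample.
#' @param cfg A [run_config()].
#' @param seed Seed for Monte-Carlo subset draws.
#' @param mode `"auto"` (exhaustive while feasible), or force
#'   `"exhaustive"` / `"monte_carlo"`.
#' @param n_draws Number of Monte-Carlo subset draws (defaults to
#'   `cfg$max_exhaustive_subsets`).
#' @return data.frame of class `recovery_curve` with columns `k`, `median`,
#'   `min`, `max`, `n_subsets`, `mode`.
#' @export
recovery_curve <- function(bulk_keys, called, cfg = run_config(),
                           seed = cfg$rng_seed,
                           mode = c("auto", "exhaustive", "monte_carlo"),
                           n_draws = cfg$max_exhaustive_subsets) {
  mode <- match.arg(mode)
  if (length(bulk_keys) == 0) stop("empty bulk mutation set")
  m <- matrix(FALSE, length(bulk_keys), ncol(called),
              dimnames = list(bulk_keys, colnames(called)))
  hit <- bulk_keys %in% rownames(called)
  m[hit, ] <- called[bulk_keys[hit], , drop = FALSE]
  n <- ncol(m)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    n_sub <- choose(n, k)
    exhaust <- (mode == "exhaustive") ||
      (mode == "auto" && n_sub <= cfg$max_exhaustive_subsets)
    if (exhaust) {
      subs <- combn(n, k, simplify = FALSE)
      kmode <- "exhaustive"
    } else {
      set.seed(derive_seed(seed, k))
      subs <- replicate(n_draws, sample.int(n, k), simplify = FALSE)
      kmode <- "monte_carlo"
    }
    fr <- vapply(subs, function(s)
      mean(rowSums(m[, s, drop = FALSE]) > 0), numeric(1))
    rows[[k]] <- data.frame(k = k, median = median(fr), min = min(fr),
                            max = max(fr), n_subsets = length(subs),
                            mode = kmode, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Full recovery analysis for one patient
#'
#' Computes [recovery_curve()] for the four combinations the study reports:
#' all bulk mutations vs the nonsynonymous/nonsense subset, each for all
#' keys and for the coverage-selected keys.
#'
#' @param bulk Data.frame of bulk mutations with `key` and `mclass`
#'   columns.
#' @param called Logical matrix keys x CTC samples.
#' @param depth Depth matrix keys x CTC samples.
#' @param cfg A [run_config()].
#' @return data.frame stacking the curves, with `mutation_set` and
#'   `selection` columns.
#' @export
recovery_analysis <- function(bulk, called, depth, cfg = run_config()) {
  sets <- list(all = bulk$key,
               nonsyn_nonsense = bulk$key[bulk$mclass %in%
                                            c("nonsynonymous", "nonsense")])
  out <- list()
  for (ms in names(sets)) {
    keys <- sets[[ms]]
    if (length(keys) == 0) next
    for (sel in c("all_bulk", "covered_20x")) {
      k2 <- if (sel == "covered_20x") select_covered(keys, depth, cfg)
            else keys
      if (length(k2) == 0) next
      rc <- recovery_curve(k2, called, cfg)
      rc$mutation_set <- ms
      rc$selection <- sel
      rc$n_keys <- length(k2)
      out[[paste(ms, sel)]] <- rc
    }
  }
  do.call(rbind, out)
}

#' Estimate the allele-dropout rate from single-CTC recovery
#'
#' Under the per-allele dropout model, a heterozygous truncal mutation is
#' recovered in a single CTC with probability (1 - ado) * (1 - d), where d
#' is the locus dropout rate; inverting the k = 1 recovery fraction yields
#' an ADO estimate.
#'
#' @param recovery_k1 Mean recovered fraction over single CTC samples.
#' @param locus_dropout Locus dropout rate (0 when coverage is deep and
#'   complete).
#' @return Estimated per-allele dropout probability.
#' @export
estimate_ado <- function(recovery_k1, locus_dropout = 0) {
  stopifnot(recovery_k1 >= 0, recovery_k1 <= 1, locus_dropout < 1)
  max(0, 1 - recovery_k1 / (1 - locus_dropout))
}

#' Compare bulk VAFs of mutations called vs not called in CTCs
#'
#' Two-sided Wilcoxon rank-sum test on the bulk VAF distributions of the
#' two groups. The null distribution is enumerated exactly when both groups
#' have at most 25 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param bulk_vaf Numeric vector of bulk VAFs (selected mutations).
#' @param called_in_ctc Logical vector, same length: called in any CTC.
#' @return List with `p_value`, `n_called`, `n_not_called`,
#'   `median_called`, `median_not_called`, `applicable`.
#' @export
vaf_called_vs_notcalled <- function(bulk_vaf, called_in_ctc) {
  stopifnot(length(bulk_vaf) == length(called_in_ctc))
  x <- bulk_vaf[called_in_ctc]
  y <- bulk_vaf[!called_in_ctc]
  if (length(x) == 0 || length(y) == 0)
    return(list(p_value = NA_real_, n_called = length(x),
                n_not_called = length(y),
                median_called = median(x), median_not_called = median(y),
                applicable = FALSE))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))$p.value
  list(p_value = p, n_called = length(x), n_not_called = length(y),
       median_called = median(x), median_not_called = median(y),
       applicable = TRUE)
}

#' Spearman correlation between bulk and CTC VAFs
#'
#' For mutations shared by the bulk and CTC samples, computes the Spearman
#' rank correlation (average ranks for ties, p-value from the
#' t-approximation via `cor.test`) per CTC sample and pooled over all
#' (mutation, sample) pairs.
#'
#' @param bulk_vaf Named numeric vector (names = mutation keys).
#' @param ctc_vaf Matrix keys x CTC samples of VAFs (`NA` where absent).
#' @return List with `per_sample` data.frame (sample, n, rho, p) and
#'   `pooled` (n, rho, p); samples with fewer than 3 shared mutations are
#'   flagged not applicable (`NA` rho).
#' @export
vaf_correlation <- function(bulk_vaf, ctc_vaf) {
  keys <- intersect(names(bulk_vaf), rownames(ctc_vaf))
  per <- list(); px <- c(); py <- c()
  for (sid in colnames(ctc_vaf)) {
    v <- ctc_vaf[keys, sid]
    ok <- !is.na(v) & !is.na(bulk_vaf[keys])
    n <- sum(ok)
    if (n < 3) {
      per[[sid]] <- data.frame(sample_id = sid, n = n, rho = NA_real_,
                               p_value = NA_real_)
      next
    }
    ct <- suppressWarnings(cor.test(bulk_vaf[keys][ok], v[ok],
                                    method = "spearman"))
    per[[sid]] <- data.frame(sample_id = sid, n = n,
                             rho = unname(ct$estimate),
                             p_value = ct$p.value)
    px <- c(px, bulk_vaf[keys][ok]); py <- c(py, v[ok])
  }
  pooled <- if (length(px) >= 3) {
    ct <- suppressWarnings(cor.test(px, py, method = "spearman"))
    list(n = length(px), rho = unname(ct$estimate), p = ct$p.value)
  } else list(n = length(px), rho = NA_real_, p = NA_real_)
  list(per_sample = do.call(rbind, per), pooled = pooled)
}
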