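#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults follow the
#' published analysis protocol this package implements: calls below a 20%
#' variant allele fraction are discarded unless present in the matched bulk,
#' bulk mutations are "selected" when covered at 20x in at least one CTC,
#' low coverage means fewer than 5 reads, the WGA artifact k-mer is
#' TTAACTGACAGC, read counting uses 10-kb windows, and copy-number
#' categories use the thresholds amp > 4, gain > 2.5, del < 1.5,
#' deep del < 0.8 on a ploidy-2 scale.
#'
#' @param vaf_floor Minimum variant allele fraction for a CTC/WBC call to
#'   survive filtering when the mutation is absent from the matched bulk.
#' @param min_select_depth Depth (reads) a bulk mutation needs in at least
#'   one CTC sample to count as "selected" (adequately covered).
#' @param low_cov_depth Depth below which a site counts as low-coverage.
#' @param artifact_kmer WGA artifact motif; calls whose flanking reference
#'   sequence contains it (either strand) are removed.
#' @param artifact_flank Half-width (bp) of the reference window scanned for
#'   the artifact motif around each call.
#' @param window_size Copy-number window width in bp.
#' @param cn_thresholds Named list with `amp`, `gain`, `del`, `deep_del`
#'   thresholds on the ploidy-2 copy-number scale (strict inequalities).
#' @param spectrum_pseudocount Pseudocount added to context frequencies
#'   before the log-correlation spectrum distance.
#' @param cbs_alpha Permutation significance level for accepting a
#'   segmentation split.
#' @param cbs_nperm Number of permutations per split test.
#' @param min_control_count Windows whose control count falls below this are
#'   masked before normalization.
#' @param purity_grid_step,ploidy_grid_step Grid resolution of the
#'   purity/ploidy search.
#' @param purity_fit_threshold Maximum admissible objective value for a
#'   purity/ploidy fit; above it the profile is left uncorrected.
#' @param max_exhaustive_subsets Largest number of CTC-sample subsets that is
#'   enumerated exhaustively for recovery curves; beyond it the same number
#'   of seeded Monte-Carlo draws is used.
#' @param rng_seed Seed used for every randomized operation in the pipeline.
#'
#' @return A list of class `ctc_config`.
#' @export
#' @examples
#' cfg <- run_config(rng_seed = 7)
#' cfg$vaf_floor
run_config <- function(vaf_floor = 0.20,
                       min_select_depth = 20L,
                       low_cov_depth = 5L,
                       artifact_kmer = "TTAACTGACAGC",
                       artifact_flank = 12L,
                       window_size = 10000L,
                       cn_thresholds = list(amp = 4, gain = 2.5,
                                            del = 1.5, deep_del = 0.8),
                       spectrum_pseudocount = 0.01,
                       cbs_alpha = 0.01,
                       cbs_nperm = 1000L,
                       min_control_count = 10L,
                       purity_grid_step = 0.01,
                       ploidy_grid_step = 0.05,
                       purity_fit_threshold = 0.05,
                       max_exhaustive_subsets = 10000L,
                       rng_seed = 1L) {
  stopifnot(vaf_floor >= 0, vaf_floor <= 1,
            min_select_depth > 0, low_cov_depth > 0,
            nchar(artifact_kmer) >= 1,
            artifact_flank >= nchar(artifact_kmer),
            window_size > 0,
            spectrum_pseudocount > 0,
            cbs_alpha > 0, cbs_alpha < 1, cbs_nperm > 0,
            max_exhaustive_subsets > 0)
  th <- cn_thresholds
  if (!all(c("amp", "gain", "del", "deep_del") %in% names(th)))
    stop("cn_thresholds must name amp, gain, del and deep_del")
  if (!(th$deep_del < th$del && th$del < 2 && 2 < th$gain && th$gain < th$amp))
    stop("cn_thresholds must satisfy deep_del < del < 2 < gain < amp")
  cfg <- list(vaf_floor = vaf_floor,
              min_select_depth = as.integer(min_select_depth),
              low_cov_depth = as.integer(low_cov_depth),
              artifact_kmer = toupper(artifact_kmer),
              artifact_flank = as.integer(artifact_flank),
              window_size = as.integer(window_size),
              cn_thresholds = th,
              spectrum_pseudocount = spectrum_pseudocount,
              cbs_alpha = cbs_alpha,
              cbs_nperm = as.integer(cbs_nperm),
              min_control_count = as.integer(min_control_count),
              purity_grid_step = purity_grid_step,
              ploidy_grid_step = ploidy_grid_step,
              purity_fit_threshold = purity_fit_threshold,
              max_exhaustive_subsets = as.integer(max_exhaustive_subsets),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "ctc_config"
  cfg
}

# deterministic 31-bit stream of sub-seeds derived from a base seed
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}
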