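# Copy-number pipeline: window counts -> control normalization -> circular
# binary segmentation -> purity/ploidy grid correction (bulk only) ->
# ploidy-2 normalization -> categorization -> Spearman concordance and
# sample clustering.

#' Normalize sample window counts against a matched control
#'
#' Library-size-scaled log2 ratio per window:
#' log2((sample_i / sum(sample)) / (control_i / sum(control))). Windows
#' whose control count falls below `cfg$min_control_count` are masked
#' (`NA`) and excluded downstream.
#'
#' @param sample,control Window-count data.frames on identical grids.
#' @param cfg A [run_config()].
#' @return data.frame chrom/start/end/log2 (NA where masked).
#' @export
normalize_to_control <- function(sample, control, cfg = run_config()) {
  if (nrow(sample) != nrow(control) ||
      !all(sample$chrom == control$chrom & sample$start == control$start &
             sample$end == control$end))
    stop("sample and control window grids differ")
  masked <- control$count < cfg$min_control_count
  ratio <- (sample$count / sum(sample$count)) /
    (control$count / sum(control$count))
  l2 <- log2(ratio)
  l2[masked | !is.finite(l2)] <- NA_real_
  data.frame(chrom = sample$chrom, start = sample$start, end = sample$end,
             log2 = l2, stringsAsFactors = FALSE)
}

#' Circular binary segmentation
#'
#' Per chromosome, recursively splits the (unmasked) window sequence at the
#' arc maximizing the arc-vs-complement two-sample t-statistic, accepting a
#' split when its seeded permutation p-value falls below `cfg$cbs_alpha`
#' (`cfg$cbs_nperm` permutations; minimum segment width 2 windows).
#' Masked windows are skipped and belong to no segment.
#'
#' @param log2df Output of [normalize_to_control()].
#' @param cfg A [run_config()].
#' @param seed Base seed for the permutation tests.
#' @return List with `windows` (input + `segment` id column) and `segments`
#'   (chrom, start, end, n_windows, mean_log2).
#' @export
cbs_segment <- function(log2df, cfg = run_config(), seed = cfg$rng_seed) {
  segs <- list()
  segment_id <- rep(NA_integer_, nrow(log2df))
  counter <- 0L
  stop_exceed <- max(1L, as.integer(ceiling(cfg$cbs_alpha *
                                              (1 + cfg$cbs_nperm) - 1)))
  emit <- function(chrom, idx) {
    sid <- length(segs) + 1L
    segs[[sid]] <<- data.frame(
      chrom = chrom, start = log2df$start[idx[1]],
      end = log2df$end[idx[length(idx)]], n_windows = length(idx),
      mean_log2 = mean(log2df$log2[idx]), stringsAsFactors = FALSE)
    segment_id[idx] <<- sid
  }
  recurse <- function(chrom, idx) {
    x <- log2df$log2[idx]
    n <- length(x)
    if (n < 4) { emit(chrom, idx); return(invisible()) }
    arc <- .cbs_best_arc(x)
    if (arc$B <= 0) { emit(chrom, idx); return(invisible()) }
    counter <<- counter + 1L
    pt <- .cbs_perm_test(x, arc$B, cfg$cbs_nperm, stop_exceed,
                         derive_seed(seed, counter))
    p <- (1 + pt$exceed) / (1 + cfg$cbs_nperm)
    if (p >= cfg$cbs_alpha) { emit(chrom, idx); return(invisible()) }
    cuts <- unique(c(0L, arc$i, arc$j, n))
    for (k in seq_len(length(cuts) - 1))
      recurse(chrom, idx[(cuts[k] + 1):cuts[k + 1]])
    invisible()
  }
  for (ch in unique(log2df$chrom)) {
    idx <- which(log2df$chrom == ch & !is.na(log2df$log2))
    if (length(idx) == 0) next
    recurse(ch, idx)
  }
  segments <- do.call(rbind, segs)
  list(windows = cbind(log2df, segment = segment_id),
       segments = segments)
}

#' Grid-search purity/ploidy correction
#'
#' Simplified absolute copy-number fit for impure bulk profiles: over a
#' grid of purity rho (0.05 to 1) and tumor ploidy tau (1.2 to 5), each
#' segment's ratio R = 2^mean_log2 implies a tumor copy number
#' q = (R * (rho * tau + 2(1 - rho)) - 2(1 - rho)) / rho. The objective is
#' the window-weighted mean squared distance of q from the nearest integer,
#' plus a consistency penalty ((weighted mean q) - tau)^2, a penalty on
#' negative q, a mild diploid-ploidy prior 0.005 (tau - 2)^2 breaking the
#' affine shift/doubling ambiguity inherent to ratio-only data, and a fixed
#' penalty for degenerate solutions where every
#' segment rounds to the same integer. Ties (within 1e-9) prefer the
#' highest purity, then the lowest ploidy. Fits whose objective exceeds
#' `cfg$purity_fit_threshold` are rejected and the profile left
#' uncorrected.
#'
#' @param segments Segment data.frame (`n_windows`, `mean_log2`).
#' @param cfg A [run_config()].
#' @param rho_grid Optional purity values to restrict the search to (e.g.
#'   `1` for a sample known to be pure).
#' @return List with `rho`, `tau`, `objective`, `q` (per segment, clipped
#'   at 0), `degenerate`, `admissible`, and `alternatives` (top 5 grid
#'   points).
#' @export
fit_purity_ploidy <- function(segments, cfg = run_config(),
                              rho_grid = NULL) {
  if (nrow(segments) < 3)
    stop("need at least 3 segments for a purity/ploidy fit")
  R <- 2^segments$mean_log2
  w <- segments$n_windows / sum(segments$n_windows)
  rhos <- if (!is.null(rho_grid)) rho_grid else
    seq(0.05, 1.0, by = cfg$purity_grid_step)
  taus <- seq(1.2, 5.0, by = cfg$ploidy_grid_step)
  best <- NULL
  grid <- expand.grid(rho = rhos, tau = taus)
  obj <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rho <- grid$rho[g]; tau <- grid$tau[g]
    D <- rho * tau + 2 * (1 - rho)
    q <- (R * D - 2 * (1 - rho)) / rho
    qr <- pmax(round(q), 0)
    o <- sum(w * (q - qr)^2) + (sum(w * q) - tau)^2 +
      4 * sum(w * pmax(0, -q)^2) + 0.005 * (tau - 2)^2
    if (length(unique(qr)) == 1) o <- o + 0.5
    obj[g] <- o
  }
  ord <- order(obj, -grid$rho, grid$tau)
  top <- grid[ord[1:min(5, length(ord))], ]
  top$objective <- obj[ord[1:min(5, length(ord))]]
  tie <- which(obj <= obj[ord[1]] + 1e-9)
  tie <- tie[order(-grid$rho[tie], grid$tau[tie])]
  pick <- tie[1]
  rho <- grid$rho[pick]; tau <- grid$tau[pick]
  D <- rho * tau + 2 * (1 - rho)
  q <- pmax((R * D - 2 * (1 - rho)) / rho, 0)
  qr <- pmax(round(q), 0)
  degenerate <- length(unique(qr)) == 1
  admissible <- obj[pick] <= cfg$purity_fit_threshold && !degenerate
  list(rho = rho, tau = tau, objective = obj[pick], q = q,
       degenerate = degenerate, admissible = admissible,
       alternatives = top)
}

#' Build a full copy-number profile for one sample
#'
#' Normalizes to the matched control, segments, optionally corrects for
#' purity/ploidy (bulk samples), rescales to a normalized ploidy of 2 and
#' categorizes segments. CTC and pooled-CTC samples are treated as pure
#' (tumor-cell selection by the isolation workflow): their ploidy-2 copy
#' number is 2R recentered to a weighted mean of 2.
#'
#' @param sample_counts,control_counts Window-count data.frames.
#' @param sample_id Sample identifier.
#' @param purity_correct Run the grid-search corrector (bulk samples).
#' @param cfg A [run_config()].
#' @param seed Segmentation seed.
#' @return List of class `cn_profile` with `windows` (incl. per-window
#'   ploidy-2 `cn`), `segments` (incl. `cn` and `category`), `purity_fit`.
#' @export
build_cn_profile <- function(sample_counts, control_counts, sample_id,
                             purity_correct = FALSE, cfg = run_config(),
                             seed = cfg$rng_seed) {
  l2 <- normalize_to_control(sample_counts, control_counts, cfg)
  sg <- cbs_segment(l2, cfg, seed)
  segments <- sg$segments
  R <- 2^segments$mean_log2
  w <- segments$n_windows / sum(segments$n_windows)
  fit <- NULL
  if (purity_correct && nrow(segments) >= 3) {
    fit <- tryCatch(fit_purity_ploidy(segments, cfg),
                    error = function(e) NULL)
  }
  if (!is.null(fit) && fit$admissible) {
    segments$cn <- fit$q * 2 / fit$tau
  } else {
    segments$cn <- 2 * R / sum(w * R)   # pure sample: recentered 2R
    if (purity_correct) fit <- c(fit, list(used = FALSE))
  }
  segments$category <- categorize_cn(segments$cn, cfg)
  segments$sample <- sample_id
  win <- sg$windows
  win$cn <- segments$cn[win$segment]
  win$category <- segments$category[win$segment]
  structure(list(sample_id = sample_id, windows = win,
                 segments = segments[, c("sample", "chrom", "start", "end",
                                         "n_windows", "mean_log2", "cn",
                                         "category")],
                 purity_fit = fit),
            class = "cn_profile")
}

#' Categorize ploidy-2 copy numbers
#'
#' Strict thresholds on the ploidy-2 scale: amplification when CN > 4,
#' gain when CN > 2.5, deep deletion when CN < 0.8, deletion when
#' CN < 1.5, neutral otherwise. Boundary values fall to the less extreme
#' category.
#'
#' @param cn Numeric vector of ploidy-2 copy numbers.
#' @param cfg A [run_config()].
#' @return Character vector of categories.
#' @export
categorize_cn <- function(cn, cfg = run_config()) {
  th <- cfg$cn_thresholds
  ifelse(cn > th$amp, "amp",
         ifelse(cn > th$gain, "gain",
                ifelse(cn < th$deep_del, "deep_del",
                       ifelse(cn < th$del, "del", "neutral"))))
}

#' Number of copy-number aberrations in a profile
#'
#' Counts categorized segments whose category is not neutral.
#' @param profile A `cn_profile`.
#' @return Integer count.
#' @export
count_cnas <- function(profile) {
  sum(profile$segments$category != "neutral")
}

#' Pairwise Spearman concordance of copy-number profiles
#'
#' Computes, over the windows unmasked in every profile, the Spearman
#' correlation of the per-window segment-mean ploidy-2 copy numbers for
#' every sample pair, and clusters the samples by complete linkage on
#' 1 - rho.
#'
#' @param profiles List of `cn_profile` objects (shared window grid).
#' @return List with `rho` (matrix), `hclust`, `newick`.
#' @export
cna_concordance <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  w0 <- profiles[[1]]$windows
  key <- paste(w0$chrom, w0$start)
  cnmat <- matrix(NA_real_, nrow(w0), length(ids),
                  dimnames = list(NULL, ids))
  for (k in seq_along(profiles)) {
    w <- profiles[[k]]$windows
    if (nrow(w) != nrow(w0) || !all(paste(w$chrom, w$start) == key))
      stop("profiles are not on a shared window grid")
    cnmat[, k] <- w$cn
  }
  ok <- complete.cases(cnmat)
  if (sum(ok) < 10) stop("fewer than 10 shared unmasked windows")
  rho <- cor(cnmat[ok, , drop = FALSE], method = "spearman")
  hc <- hclust(as.dist(1 - rho), method = "complete")
  nwk <- tryCatch(ape::write.tree(ape::as.phylo(hc)),
                  error = function(e) NA_character_)
  list(rho = rho, hclust = hc, newick = nwk, n_windows = sum(ok))
}
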