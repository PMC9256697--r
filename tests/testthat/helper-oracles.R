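# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the library calls the implementation uses) so each
# check compares two independent routes to the same quantity.

# exhaustive substring scan for a motif on either strand
oracle_kmer_hit <- function(window, motif) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  found <- function(pat) {
    k <- nchar(pat); n <- nchar(window)
    if (n < k) return(FALSE)
    for (i in seq_len(n - k + 1))
      if (substr(window, i, i + k - 1) == pat) return(TRUE)
    FALSE
  }
  found(motif) || found(rc)
}

# brute-force set algebra for the mutation taxonomy.
# called_sets: named list sample_id -> character keys; classes: named
# character sample_id -> sample_class
oracle_categorize <- function(called_sets, classes) {
  all_keys <- unique(unlist(called_sets))
  ctc_ids <- names(classes)[classes %in% c("ctc_single", "ctc_pool")]
  bulk_id <- names(classes)[classes == "bulk_tumor"]
  germ_id <- names(classes)[classes == "germline_blood"]
  wbc_id <- names(classes)[classes == "wbc_pool"]
  out <- character(0)
  for (k in all_keys) {
    in_bulk <- k %in% called_sets[[bulk_id]]
    in_germ <- k %in% called_sets[[germ_id]]
    in_wbc <- k %in% called_sets[[wbc_id]]
    n_ctc <- sum(vapply(ctc_ids, function(s) k %in% called_sets[[s]],
                        logical(1)))
    bulk_mut <- in_bulk && !in_germ && !in_wbc
    ctc_mut <- n_ctc >= 1 && !in_wbc
    lab <- if (ctc_mut && bulk_mut) "ctc_bulk"
    else if (ctc_mut && !bulk_mut && n_ctc >= 2) "ctc_shared"
    else if (ctc_mut && !bulk_mut && n_ctc == 1) "ctc_private"
    else if (bulk_mut) "bulk_only"
    else "excluded"
    out[k] <- lab
  }
  out
}

# exhaustive recovery fractions for subsets of size k
oracle_recovery_fractions <- function(called, k) {
  n <- ncol(called)
  subs <- combn(n, k, simplify = FALSE)
  vapply(subs, function(s) {
    hit <- rep(FALSE, nrow(called))
    for (j in s) hit <- hit | called[, j]
    mean(hit)
  }, numeric(1))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcox_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combs <- combn(m + n, m)
  W <- apply(combs, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  p_le <- mean(W <= w_obs)
  p_ge <- mean(W >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo permutation two-sided p for the rank-sum statistic
oracle_wilcox_perm <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  ew <- m * (length(pooled) + 1) / 2
  stat_obs <- abs(w_obs - ew)
  stat <- replicate(B, abs(sum(r[sample.int(length(pooled), m)]) - ew))
  mean(stat >= stat_obs - 1e-12)
}

# rank-then-Pearson Spearman
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# manual complete-linkage agglomeration: returns merge heights (sorted)
# and the flat grouping at k clusters
oracle_complete_linkage <- function(dm, k = NULL) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  labels <- rep(1L, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        d <- max(dm[clusters[[i]], clusters[[j]]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    if (!is.null(k) && length(clusters) == k)
      for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  }
  list(heights = heights, labels = labels)
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  N <- choose(sum(tab), 2)
  exp_ <- si * sj / N
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
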