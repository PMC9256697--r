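# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: clonal tumors sampled as an impure bulk biopsy,
# whole-genome-amplified single/pooled CTC samples with allele dropout,
# locus dropout and artifact mutations drawn from a patient-specific
# trinucleotide spectrum, and a near-clean amplified WBC pool. Every emitted
# call is traceable to exactly one truth category (clonal mutation or
# injected artifact).

#' WGA / sequencing noise model
#'
#' @param ado_rate Per-allele dropout probability during amplification.
#' @param locus_dropout_rate Fraction of sites with zero coverage.
#' @param fp_rate Expected number of artifact SNVs per sample.
#' @param coverage_mean,coverage_dispersion Negative-binomial depth
#'   parameters (mean and size).
#' @param caller_min_alt,caller_min_vaf Emulated caller: a variant is called
#'   when it has at least `caller_min_alt` supporting reads and an observed
#'   VAF of at least `caller_min_vaf`.
#' @return List of class `wga_model`.
#' @export
wga_model <- function(ado_rate = 0.3, locus_dropout_rate = 0.4,
                      fp_rate = 800, coverage_mean = 60,
                      coverage_dispersion = 2,
                      caller_min_alt = 3L, caller_min_vaf = 0.05) {
  stopifnot(ado_rate >= 0, ado_rate <= 1,
            locus_dropout_rate >= 0, locus_dropout_rate <= 1,
            fp_rate >= 0, coverage_mean > 0, coverage_dispersion > 0)
  structure(list(ado_rate = ado_rate,
                 locus_dropout_rate = locus_dropout_rate,
                 fp_rate = fp_rate,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 caller_min_alt = as.integer(caller_min_alt),
                 caller_min_vaf = caller_min_vaf),
            class = "wga_model")
}

#' Sample read support at one site under the WGA noise model
#'
#' Depth is negative-binomial (zero with probability
#' `locus_dropout_rate`); each of the two allele classes (alt, ref) drops
#' independently with probability `ado_rate`, which zeroes or inflates the
#' allele fraction (for a heterozygous site, to 0 or 1); alt reads are then
#' binomial in the post-dropout fraction. Vectorized over `true_vaf`.
#'
#' @param true_vaf True allele fraction(s) in the amplified material.
#' @param wga A [wga_model()].
#' @return data.frame with `depth` and `alt_reads`.
#' @export
sample_reads_at_site <- function(true_vaf, wga) {
  n <- length(true_vaf)
  stopifnot(all(true_vaf >= 0 & true_vaf <= 1))
  d_alt <- runif(n) < wga$ado_rate
  d_ref <- runif(n) < wga$ado_rate
  num <- true_vaf * !d_alt
  den <- num + (1 - true_vaf) * !d_ref
  f <- ifelse(den > 0, num / den, NA_real_)
  depth <- rnbinom(n, mu = wga$coverage_mean, size = wga$coverage_dispersion)
  depth[runif(n) < wga$locus_dropout_rate] <- 0L
  depth[is.na(f)] <- 0L   # both allele classes dropped: nothing to amplify
  f[is.na(f)] <- 0
  alt <- rbinom(n, depth, f)
  data.frame(depth = as.integer(depth), alt_reads = as.integer(alt))
}

# pooled-cell version: alt/total template copies given explicitly; each
# template drops independently with prob ado
sample_reads_pooled <- function(alt_copies, tot_copies, wga, locus_dropout) {
  n <- length(alt_copies)
  ra <- rbinom(n, alt_copies, 1 - wga$ado_rate)
  rr <- rbinom(n, pmax(tot_copies - alt_copies, 0), 1 - wga$ado_rate)
  den <- ra + rr
  f <- ifelse(den > 0, ra / den, 0)
  depth <- rnbinom(n, mu = wga$coverage_mean, size = wga$coverage_dispersion)
  depth[runif(n) < locus_dropout] <- 0L
  depth[den == 0] <- 0L
  alt <- rbinom(n, depth, f)
  data.frame(depth = as.integer(depth), alt_reads = as.integer(alt))
}

# ---------------------------------------------------------------------------
# context-guided site pools

# one-time pool of candidate positions with their reference trinucleotides;
# drawing consumes positions so sites are unique within a cohort
build_site_pool <- function(ref, n_candidates = 80000L) {
  chroms <- names(ref)
  lens <- nchar(ref)
  p <- lens / sum(lens)
  ch_idx <- sample.int(length(chroms), n_candidates, replace = TRUE, prob = p)
  pos <- 2L + as.integer(floor(runif(n_candidates) * (lens[ch_idx] - 2L)))
  # vectorized trinucleotide extraction per chromosome
  tri <- character(n_candidates)
  for (i in seq_along(chroms)) {
    sel <- ch_idx == i
    if (!any(sel)) next
    tri[sel] <- substring(ref[[i]], pos[sel] - 1L, pos[sel] + 1L)
  }
  keep <- !duplicated(paste(chroms[ch_idx], pos)) & !grepl("[^ACGT]", tri)
  env <- new.env(parent = emptyenv())
  env$chrom <- chroms[ch_idx][keep]
  env$pos <- pos[keep]
  env$tri <- tri[keep]
  env$by_tri <- split(seq_along(env$tri), env$tri)
  env$by_tri <- lapply(env$by_tri, sample) # random draw order
  env$cursor <- lapply(env$by_tri, function(x) 1L)
  env
}

# draw n sites whose pyrimidine-collapsed context follows `spectrum`
# (probability vector over context_classes()); returns chrom/pos/ref/alt.
# Vectorized per context class; the forward/reverse strand split is a
# uniform (hypergeometric) draw over the remaining candidate positions.
draw_context_sites <- function(pool, n, spectrum) {
  classes <- context_classes()
  stopifnot(length(spectrum) == 96)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  draw <- tabulate(sample.int(96, n, replace = TRUE, prob = spectrum), 96)
  take <- function(tri, k) {
    if (k == 0) return(integer(0))
    cur <- pool$cursor[[tri]]
    idxs <- pool$by_tri[[tri]]
    out <- idxs[cur:(cur + k - 1L)]
    pool$cursor[[tri]] <- cur + k
    out
  }
  avail <- function(tri) {
    idxs <- pool$by_tri[[tri]]
    if (is.null(idxs)) return(0L)
    length(idxs) - pool$cursor[[tri]] + 1L
  }
  out <- vector("list", 96)
  for (c96 in which(draw > 0)) {
    k <- draw[c96]
    lab <- classes[c96]
    five <- substr(lab, 1, 1); refb <- substr(lab, 3, 3)
    altb <- substr(lab, 5, 5); three <- substr(lab, 7, 7)
    tri_f <- paste0(five, refb, three)
    tri_r <- paste0(comp[three], comp[refb], comp[five])
    af <- avail(tri_f); ar <- avail(tri_r)
    if (af + ar < k)
      stop("site pool exhausted for context ", lab,
           "; enlarge n_candidates")
    kf <- stats::rhyper(1, af, ar, k)
    idx <- c(take(tri_f, kf), take(tri_r, k - kf))
    ori_f <- rep(c(TRUE, FALSE), c(kf, k - kf))
    out[[c96]] <- data.frame(
      chrom = pool$chrom[idx], pos = pool$pos[idx],
      ref = ifelse(ori_f, refb, comp[[refb]]),
      alt = ifelse(ori_f, altb, comp[[altb]]),
      context = lab, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))], list(empty)))
}

#' Draw artifact mutations for one sample
#'
#' The number of artifacts is Poisson in the sample's expected artifact
#' rate; contexts follow the patient's artifact spectrum; a fixed fraction
#' is placed inside planted copies of the blacklist k-mer so the artifact
#' filter has true positives to remove.
#'
#' @param pool Site pool from the cohort generator.
#' @param fp_rate Expected artifact count.
#' @param spectrum 96-class context probability vector.
#' @param kmer_sites data.frame of planted k-mer start positions.
#' @param kmer_fraction Fraction of artifacts placed at k-mer sites.
#' @param reference Named character reference sequences.
#' @return data.frame chrom/pos/ref/alt/context (`context` NA at k-mer sites).
#' @export
inject_artifacts <- function(pool, fp_rate, spectrum, kmer_sites = NULL,
                             kmer_fraction = 0, reference = NULL) {
  n <- rpois(1, fp_rate)
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  n_kmer <- 0L
  if (!is.null(kmer_sites) && nrow(kmer_sites) > 0 && kmer_fraction > 0)
    n_kmer <- rbinom(1, n, kmer_fraction)
  sites <- draw_context_sites(pool, n - n_kmer, spectrum)
  if (n_kmer > 0) {
    bases <- c("A", "C", "G", "T")
    idx <- sample.int(nrow(kmer_sites), n_kmer, replace = TRUE)
    off <- sample.int(12L, n_kmer, replace = TRUE) - 1L
    pos <- kmer_sites$pos[idx] + off
    chrom <- kmer_sites$chrom[idx]
    refb <- substr(reference[chrom], pos, pos)
    altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1), character(1))
    km <- data.frame(chrom = chrom, pos = as.integer(pos), ref = refb,
                     alt = unname(altb), context = NA_character_,
                     stringsAsFactors = FALSE)
    sites <- rbind(sites, km)
  }
  sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
}

#' Simulate window read counts for a copy-number profile
#'
#' Standalone generator for segmentation and purity-correction studies:
#' given per-window tumor copy numbers, purity and a matched diploid
#' control, draws negative-binomial read counts whose expectation is
#' proportional to the cell-mixture DNA content
#' purity * q + 2 * (1 - purity).
#'
#' @param windows Window grid (chrom/start/end) or an integer number of
#'   windows on one synthetic chromosome.
#' @param cn Integer tumor copy number per window.
#' @param purity Tumor-cell fraction (1 = pure).
#' @param base_count Expected reads per diploid window.
#' @param size Negative-binomial size (dispersion) parameter.
#' @return List with `tumor` and `control` window-count data.frames.
#' @export
simulate_cn_windows <- function(windows, cn, purity = 1,
                                base_count = 2000, size = 400) {
  if (is.numeric(windows) && length(windows) == 1) {
    n <- as.integer(windows)
    windows <- data.frame(chrom = "chr1",
                          start = seq(0L, by = 10000L, length.out = n),
                          end = seq(10000L, by = 10000L, length.out = n))
  }
  stopifnot(length(cn) == nrow(windows), all(cn >= 0), purity > 0,
            purity <= 1)
  level <- purity * cn + 2 * (1 - purity)
  tumor <- windows
  tumor$count <- as.integer(rnbinom(nrow(windows),
                                    mu = base_count * level / 2,
                                    size = size))
  control <- windows
  control$count <- as.integer(rnbinom(nrow(windows), mu = base_count,
                                      size = size))
  list(tumor = validate_windows(tumor), control = validate_windows(control))
}

# ---------------------------------------------------------------------------
# scenarios

#' Describe one synthetic patient
#'
#' @param patient_id Patient identifier.
#' @param purity Bulk tumor-cell fraction.
#' @param clones List of clone descriptions; each a list with `clone_id`,
#'   `parent` (NA for the truncal clone), `ccf_bulk`, `n_snvs`,
#'   `cn_events` (data.frame chrom/start/end/cn, 0-based half-open) and
#'   optional `drivers` (data.frame gene/protein_change/mclass).
#' @param ctc_singles Character vector: clone of each single CTC.
#' @param ctc_pools List of named integer vectors: cells per clone for each
#'   pooled CTC sample.
#' @param tumor_spectrum,artifact_spectrum Optional 96-class probability
#'   vectors; autogenerated patient-specific spectra when `NULL`.
#' @param wga_ctc,wga_wbc,wga_bulk,wga_germline Noise models per sample
#'   class ([wga_model()]).
#' @param kmer_fraction Fraction of artifacts planted in blacklist-motif
#'   context.
#' @return List of class `ctc_scenario`.
#' @export
sim_scenario <- function(patient_id, purity, clones, ctc_singles,
                         ctc_pools = list(),
                         tumor_spectrum = NULL, artifact_spectrum = NULL,
                         wga_ctc = wga_model(),
                         wga_wbc = wga_model(fp_rate = 60),
                         wga_bulk = wga_model(ado_rate = 0,
                                              locus_dropout_rate = 0,
                                              fp_rate = 0,
                                              coverage_mean = 120,
                                              coverage_dispersion = 10),
                         wga_germline = wga_model(ado_rate = 0,
                                                  locus_dropout_rate = 0,
                                                  fp_rate = 3,
                                                  coverage_mean = 120,
                                                  coverage_dispersion = 10),
                         kmer_fraction = 0.03) {
  ids <- vapply(clones, `[[`, character(1), "clone_id")
  if (anyDuplicated(ids)) stop("duplicate clone_id")
  ccf <- setNames(vapply(clones, `[[`, numeric(1), "ccf_bulk"), ids)
  parent <- setNames(vapply(clones, function(c) {
    if (is.null(c$parent) || is.na(c$parent)) NA_character_ else c$parent
  }, character(1)), ids)
  root <- ids[is.na(parent)]
  if (length(root) != 1) stop("exactly one truncal (parentless) clone required")
  if (abs(ccf[root] - 1) > 1e-9) stop("truncal clone must have ccf_bulk = 1")
  for (id in ids[!is.na(parent)]) {
    if (!(parent[id] %in% ids)) stop("unknown parent clone: ", parent[id])
    if (ccf[id] > ccf[parent[id]] + 1e-9)
      stop("infeasible clone tree: ", id, " has ccf above its parent")
  }
  for (cl in c(ctc_singles, unlist(lapply(ctc_pools, names))))
    if (!(cl %in% ids)) stop("CTC assigned to unknown clone: ", cl)
  structure(list(patient_id = patient_id, purity = purity, clones = clones,
                 clone_ids = ids, ccf = ccf, parent = parent, root = root,
                 ctc_singles = ctc_singles, ctc_pools = ctc_pools,
                 tumor_spectrum = tumor_spectrum,
                 artifact_spectrum = artifact_spectrum,
                 wga = list(ctc_single = wga_ctc, ctc_pool = wga_ctc,
                            wbc_pool = wga_wbc, bulk_tumor = wga_bulk,
                            germline_blood = wga_germline),
                 kmer_fraction = kmer_fraction),
            class = "ctc_scenario")
}

# concentrated random spectrum: heavy mass on `n_hot` contexts
random_spectrum <- function(n_hot = 20, hot = 1, cold = 0.03) {
  w <- rep(cold, 96)
  w[sample.int(96, n_hot)] <- hot
  w / sum(w)
}

#' Block-disjoint context spectra
#'
#' Partitions the 96 context classes into `of` equal blocks and returns the
#' uniform spectrum on block `i` — used to give patients fully disjoint
#' mutational patterns.
#' @param i Block index (1-based).
#' @param of Number of blocks.
#' @return Probability vector of length 96.
#' @export
disjoint_spectrum <- function(i, of = 3) {
  stopifnot(i >= 1, i <= of, 96 %% of == 0)
  w <- rep(0, 96)
  size <- 96 / of
  w[seq((i - 1) * size + 1, i * size)] <- 1
  w / sum(w)
}

#' Built-in driver gene map for the synthetic genome
#' @return data.frame chrom/start/end/gene (0-based half-open).
#' @export
default_gene_map <- function() {
  snv <- data.frame(chrom = paste0("chr", 1:5),
                    start = 400000L, end = 420000L,
                    gene = c("TP53", "AKT1", "ESR1", "PIK3CA", "PER3"))
  cna <- data.frame(chrom = paste0("chr", 6:10),
                    start = 500000L, end = 540000L,
                    gene = c("MYC", "ERBB2", "CCND1", "PTEN", "RB1"))
  rbind(snv, cna)
}

cn_ev <- function(chrom, start, end, cn)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             cn = cn, stringsAsFactors = FALSE)

drv <- function(gene, protein_change, mclass = "nonsynonymous")
  data.frame(gene = gene, protein_change = protein_change, mclass = mclass,
             stringsAsFactors = FALSE)

#' The default three-patient scenario bundle
#'
#' Mirrors the study design the generator emulates: a concordant
#' triple-negative-like patient, a concordant HER2-like patient with a
#' uniform ERBB2 amplification in every sample, and a discordant ER-like
#' patient carrying a CTC-only clone with its own driver mutation (ESR1) and
#' amplification (ERBB2) that are absent from the bulk.
#' @return Named list of three [sim_scenario()] objects.
#' @export
default_scenarios <- function() {
  p1 <- sim_scenario(
    patient_id = "P1", purity = 0.25,
    clones = list(
      list(clone_id = "C1", parent = NA, ccf_bulk = 1, n_snvs = 70,
           cn_events = rbind(cn_ev("chr6", 400000, 700000, 6),
                             cn_ev("chr2", 0, 400000, 3),
                             cn_ev("chr3", 500000, 1000000, 1),
                             cn_ev("chr9", 0, 400000, 1),
                             cn_ev("chr1", 600000, 1000000, 3),
                             cn_ev("chr4", 0, 350000, 1),
                             cn_ev("chr7", 500000, 900000, 3),
                             cn_ev("chr8", 0, 300000, 1)),
           drivers = drv("TP53", "M237K")),
      list(clone_id = "A", parent = "C1", ccf_bulk = 0.45, n_snvs = 50,
           cn_events = cn_ev("chr5", 0, 50000, 3)),
      list(clone_id = "B", parent = "C1", ccf_bulk = 0.20, n_snvs = 40,
           cn_events = cn_ev("chr10", 0, 50000, 1))),
    ctc_singles = c("A", "A", "C1", "B"),
    ctc_pools = list(c(C1 = 2, A = 2, B = 1), c(C1 = 1, A = 3, B = 1)))
  p2 <- sim_scenario(
    patient_id = "P2", purity = 0.30,
    clones = list(
      list(clone_id = "C1", parent = NA, ccf_bulk = 1, n_snvs = 90,
           cn_events = rbind(cn_ev("chr7", 400000, 800000, 8),
                             cn_ev("chr6", 450000, 750000, 5),
                             cn_ev("chr1", 0, 250000, 1),
                             cn_ev("chr4", 500000, 900000, 3),
                             cn_ev("chr2", 500000, 1000000, 3),
                             cn_ev("chr3", 0, 400000, 1),
                             cn_ev("chr5", 300000, 700000, 3),
                             cn_ev("chr9", 600000, 1000000, 1)),
           drivers = drv("TP53", "H193L")),
      list(clone_id = "R", parent = "C1", ccf_bulk = 0.04, n_snvs = 30,
           cn_events = cn_ev("chr10", 400000, 700000, 5))),
    ctc_singles = c("C1", "C1", "R"),
    ctc_pools = list(c(C1 = 9, R = 1), c(C1 = 10), c(C1 = 8, R = 2)))
  p3 <- sim_scenario(
    patient_id = "P3", purity = 0.30,
    clones = list(
      list(clone_id = "C1", parent = NA, ccf_bulk = 1, n_snvs = 60,
           cn_events = rbind(cn_ev("chr8", 400000, 700000, 5),
                             cn_ev("chr4", 500000, 900000, 3),
                             cn_ev("chr6", 500000, 900000, 1)),
           drivers = drv("AKT1", "E17K")),
      list(clone_id = "T", parent = "C1", ccf_bulk = 0.90, n_snvs = 45,
           cn_events = rbind(cn_ev("chr1", 600000, 900000, 3),
                             cn_ev("chr2", 500000, 800000, 1),
                             cn_ev("chr9", 400000, 700000, 1),
                             cn_ev("chr5", 0, 400000, 3),
                             cn_ev("chr10", 600000, 1000000, 1)),
           drivers = drv("TP53", "R175H")),
      list(clone_id = "S", parent = "T", ccf_bulk = 0.05, n_snvs = 25,
           cn_events = NULL, drivers = drv("PER3", "A1015T")),
      list(clone_id = "E", parent = "C1", ccf_bulk = 0, n_snvs = 45,
           cn_events = rbind(cn_ev("chr7", 450000, 750000, 7),
                             cn_ev("chr3", 0, 300000, 3),
                             cn_ev("chr5", 500000, 900000, 1),
                             cn_ev("chr10", 0, 400000, 3),
                             cn_ev("chr2", 0, 400000, 1),
                             cn_ev("chr9", 0, 350000, 3)),
           drivers = drv("ESR1", "Y537N"))),
    ctc_singles = c("S", "S", "E"),
    ctc_pools = list())
  list(P1 = p1, P2 = p2, P3 = p3)
}

# ---------------------------------------------------------------------------
# patient simulation internals

clone_descendants <- function(parent_map) {
  ids <- names(parent_map)
  desc <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    cur <- id
    repeat {
      p <- parent_map[[cur]]
      if (is.na(p)) break
      desc[[p]] <- c(desc[[p]], id)
      cur <- p
    }
  }
  desc
}

# per-clone copy number for every window (matrix n_windows x n_clones)
clone_cn_windows <- function(scenario, windows) {
  ids <- scenario$clone_ids
  cn <- matrix(2, nrow = nrow(windows), ncol = length(ids),
               dimnames = list(NULL, ids))
  path_to_root <- function(id) {
    out <- id
    while (!is.na(scenario$parent[[out[1]]]))
      out <- c(scenario$parent[[out[1]]], out)
    out
  }
  for (id in ids) {
    for (anc in path_to_root(id)) {
      ev <- scenario$clones[[match(anc, ids)]]$cn_events
      if (is.null(ev) || nrow(ev) == 0) next
      for (r in seq_len(nrow(ev))) {
        hit <- windows$chrom == ev$chrom[r] &
          windows$start >= ev$start[r] & windows$end <= ev$end[r]
        cn[hit, id] <- ev$cn[r]
      }
    }
  }
  cn
}

# exclusive cell fraction per clone (ccf minus children's ccf)
exclusive_fractions <- function(scenario) {
  f <- scenario$ccf
  for (id in names(f)) {
    kids <- names(scenario$parent)[!is.na(scenario$parent) &
                                     scenario$parent == id]
    f[id] <- f[id] - sum(scenario$ccf[kids])
  }
  if (any(f < -1e-9)) stop("clone ccfs exceed parent capacity")
  pmax(f, 0)
}

gene_at <- function(genes, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  for (r in seq_len(nrow(genes))) {
    hit <- chrom == genes$chrom[r] & pos > genes$start[r] &
      pos <= genes$end[r]
    out[hit] <- genes$gene[r]
  }
  out
}

window_grid <- function(ref, window_size) {
  out <- do.call(rbind, lapply(names(ref), function(ch) {
    len <- nchar(ref[[ch]])
    starts <- seq(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  }))
  out[order(match(out$chrom, names(ref)), out$start), ]
}

#' Simulate one patient
#'
#' Generates clone mutations and driver events, injects WGA artifacts,
#' samples read support at every site of the patient universe for every
#' sample, emulates the caller and produces window read counts, returning
#' the per-sample callsets, depth tables, window counts and full ground
#' truth. Uses the current RNG state; seed upstream for determinism.
#'
#' @param scenario A [sim_scenario()].
#' @param genome List with `sequences`, `kmer_sites` (see
#'   [random_reference()]).
#' @param genes Gene interval map (data.frame chrom/start/end/gene).
#' @param pool Shared context site pool.
#' @param cfg A [run_config()].
#' @return List with `sheet`, `calls`, `depth`, `windows`, `truth`.
#' @export
simulate_patient <- function(scenario, genome, genes, pool, cfg) {
  ref <- genome$sequences
  pid <- scenario$patient_id
  ids <- scenario$clone_ids
  if (is.null(scenario$tumor_spectrum))
    scenario$tumor_spectrum <- random_spectrum()
  if (is.null(scenario$artifact_spectrum))
    scenario$artifact_spectrum <- random_spectrum()

  ## sample sheet block
  n_single <- length(scenario$ctc_singles)
  n_pool <- length(scenario$ctc_pools)
  sheet <- data.frame(
    sample_id = c(paste0(pid, "_bulk"), paste0(pid, "_germline"),
                  paste0(pid, "_wbc"),
                  if (n_single) paste0(pid, "_ctc", seq_len(n_single)),
                  if (n_pool) paste0(pid, "_pool", seq_len(n_pool))),
    patient_id = pid,
    sample_class = c("bulk_tumor", "germline_blood", "wbc_pool",
                     rep("ctc_single", n_single), rep("ctc_pool", n_pool)),
    n_cells = c(1L, 1L, 1L, rep(1L, n_single),
                if (n_pool) vapply(scenario$ctc_pools, sum, numeric(1))),
    stringsAsFactors = FALSE)

  ## clone mutations (context-guided) + planted drivers
  muts <- list()
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(scenario$clones)) {
    cl <- scenario$clones[[k]]
    m <- draw_context_sites(pool, cl$n_snvs, scenario$tumor_spectrum)
    m$clone <- rep(cl$clone_id, nrow(m))
    m$gene <- gene_at(genes, m$chrom, m$pos)
    m$protein_change <- rep(NA_character_, nrow(m))
    m$mclass <- sample(c("nonsynonymous", "nonsense", "synonymous",
                         "noncoding"), nrow(m), replace = TRUE,
                       prob = c(0.25, 0.03, 0.12, 0.60))
    if (!is.null(cl$drivers) && nrow(cl$drivers)) {
      for (r in seq_len(nrow(cl$drivers))) {
        g <- genes[genes$gene == cl$drivers$gene[r], ]
        if (nrow(g) != 1) stop("driver gene not in gene map: ",
                               cl$drivers$gene[r])
        dpos <- g$start + sample.int(g$end - g$start - 2L, 1L) + 1L
        dref <- substr(ref[[g$chrom]], dpos, dpos)
        dalt <- sample(setdiff(bases, dref), 1)
        m <- rbind(m, data.frame(
          chrom = g$chrom, pos = as.integer(dpos), ref = dref, alt = dalt,
          context = NA_character_, clone = cl$clone_id, gene = g$gene,
          protein_change = cl$drivers$protein_change[r],
          mclass = cl$drivers$mclass[r], stringsAsFactors = FALSE))
      }
    }
    muts[[k]] <- m
  }
  muts <- do.call(rbind, muts)
  muts$type <- ifelse(muts$clone == scenario$root, "truncal", "subclonal")
  muts$key <- mutation_key(muts$chrom, muts$pos, muts$ref, muts$alt)

  ## artifacts per amplified sample
  artifacts <- list()
  for (i in seq_len(nrow(sheet))) {
    cls <- sheet$sample_class[i]
    w <- scenario$wga[[cls]]
    a <- inject_artifacts(pool, w$fp_rate, scenario$artifact_spectrum,
                          kmer_sites = genome$kmer_sites,
                          kmer_fraction = if (cls %in%
                                              c("ctc_single", "ctc_pool",
                                                "wbc_pool"))
                            scenario$kmer_fraction else 0,
                          reference = ref)
    if (nrow(a)) {
      a$sample_id <- sheet$sample_id[i]
      artifacts[[length(artifacts) + 1L]] <- a
    }
  }
  artifacts <- if (length(artifacts)) do.call(rbind, artifacts) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), context = character(0),
               sample_id = character(0), stringsAsFactors = FALSE)
  if (nrow(artifacts))
    artifacts$key <- mutation_key(artifacts$chrom, artifacts$pos,
                                  artifacts$ref, artifacts$alt)
  else artifacts$key <- character(0)

  ## universe of sites for depth tables
  universe <- rbind(muts[, c("chrom", "pos", "ref", "alt", "key")],
                    artifacts[, c("chrom", "pos", "ref", "alt", "key")])
  universe <- universe[!duplicated(universe$key), ]
  universe <- universe[order(universe$chrom, universe$pos), ]
  nU <- nrow(universe)

  ## per-clone CN at every mutation site and window
  windows <- window_grid(ref, cfg$window_size)
  clone_cn <- clone_cn_windows(scenario, windows)
  widx <- integer(nU)
  for (ch in unique(universe$chrom)) {
    sel <- universe$chrom == ch
    wsel <- which(windows$chrom == ch)
    widx[sel] <- wsel[window_of_position(universe$pos[sel],
                                         cfg$window_size) + 1L]
  }
  site_cn <- clone_cn[widx, , drop = FALSE]   # nU x n_clones

  desc <- clone_descendants(scenario$parent)
  carriers <- setNames(lapply(ids, function(id) c(id, desc[[id]])), ids)
  f_excl <- exclusive_fractions(scenario)

  # carrier indicator matrix: site x clone (clone's cells carry the site)
  carry <- matrix(FALSE, nU, length(ids), dimnames = list(NULL, ids))
  mut_clone <- setNames(muts$clone, muts$key)
  tum <- universe$key %in% muts$key
  for (id in ids) {
    owns <- mut_clone[universe$key[tum]]
    carry[tum, id] <- vapply(owns, function(o) id %in% carriers[[o]],
                             logical(1))
  }

  qbar <- as.numeric(site_cn %*% f_excl)          # mean tumor CN per site
  alt_frac_bulk <- as.numeric(carry %*% f_excl)   # carrier cell mass

  rho <- scenario$purity
  art_by_sample <- split(artifacts$key, artifacts$sample_id)

  calls <- list(); depth_tabs <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]; cls <- sheet$sample_class[i]
    w <- scenario$wga[[cls]]
    own_art <- universe$key %in% art_by_sample[[sid]]
    if (cls == "bulk_tumor") {
      tv <- rho * alt_frac_bulk / (rho * qbar + 2 * (1 - rho))
      tv[own_art] <- 0.5
      rd <- sample_reads_at_site(tv, w)
    } else if (cls == "germline_blood" || cls == "wbc_pool") {
      tv <- ifelse(own_art, 0.5, 0)
      rd <- sample_reads_at_site(tv, w)
    } else if (cls == "ctc_single") {
      cl <- scenario$ctc_singles[as.integer(sub(".*_ctc", "", sid))]
      q <- site_cn[, cl]
      tv <- ifelse(carry[, cl], 1 / q, 0)
      tv[own_art] <- 0.5
      rd <- sample_reads_at_site(tv, w)
    } else {   # ctc_pool
      cells <- scenario$ctc_pools[[as.integer(sub(".*_pool", "", sid))]]
      k_alt <- as.numeric(carry[, names(cells), drop = FALSE] %*% cells)
      tot <- as.numeric(site_cn[, names(cells), drop = FALSE] %*% cells)
      k_alt[own_art] <- round(tot[own_art] / 2)
      rd <- sample_reads_pooled(k_alt, tot, w,
                                w$locus_dropout_rate / sum(cells))
    }
    # injected artifacts exist in the amplified library by construction:
    # they see sequencing sampling but not locus dropout or allele dropout
    if (any(own_art)) {
      na <- sum(own_art)
      da <- rnbinom(na, mu = w$coverage_mean, size = w$coverage_dispersion)
      rd$depth[own_art] <- da
      rd$alt_reads[own_art] <- rbinom(na, da, 0.5)
    }
    vaf <- ifelse(rd$depth > 0, rd$alt_reads / rd$depth, NA)
    called <- !is.na(vaf) & rd$alt_reads >= w$caller_min_alt &
      vaf >= w$caller_min_vaf
    dt <- data.frame(chrom = universe$chrom, pos = universe$pos,
                     ref = universe$ref, alt = universe$alt,
                     depth = rd$depth, alt_reads = rd$alt_reads,
                     key = universe$key, stringsAsFactors = FALSE)
    depth_tabs[[sid]] <- dt
    cs <- dt[called, c("chrom", "pos", "ref", "alt", "depth", "alt_reads")]
    cs$called <- rep(TRUE, nrow(cs))
    mi <- match(mutation_key(cs$chrom, cs$pos, cs$ref, cs$alt), muts$key)
    cs$gene <- muts$gene[mi]
    cs$protein_change <- muts$protein_change[mi]
    cs$mclass <- muts$mclass[mi]
    calls[[sid]] <- finalize_calls(cs, sid)
  }

  ## window counts
  nW <- nrow(windows)
  win_tabs <- list()
  base_count <- 2000
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]; cls <- sheet$sample_class[i]
    level <- switch(cls,
      bulk_tumor = rho * as.numeric(clone_cn %*% f_excl) + 2 * (1 - rho),
      germline_blood = rep(2, nW),
      wbc_pool = rep(2, nW),
      ctc_single = clone_cn[, scenario$ctc_singles[
        as.integer(sub(".*_ctc", "", sid))]],
      ctc_pool = {
        cells <- scenario$ctc_pools[[as.integer(sub(".*_pool", "", sid))]]
        as.numeric(clone_cn[, names(cells), drop = FALSE] %*% cells) /
          sum(cells)
      })
    mu <- base_count * level / 2
    wga_cls <- cls %in% c("ctc_single", "ctc_pool", "wbc_pool")
    if (wga_cls)
      mu <- mu * exp(rnorm(nW, 0, 0.1))   # mild WGA window bias
    cnt <- rnbinom(nW, mu = mu, size = if (wga_cls) 150 else 800)
    win_tabs[[sid]] <- validate_windows(
      data.frame(chrom = windows$chrom, start = windows$start,
                 end = windows$end, count = as.integer(cnt)))
  }

  ## sample-level true CN per window (tumor-content scale, ploidy units)
  true_cn <- matrix(NA_real_, nW, nrow(sheet),
                    dimnames = list(NULL, sheet$sample_id))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]; cls <- sheet$sample_class[i]
    true_cn[, sid] <- switch(cls,
      bulk_tumor = as.numeric(clone_cn %*% f_excl),
      germline_blood = rep(2, nW), wbc_pool = rep(2, nW),
      ctc_single = clone_cn[, scenario$ctc_singles[
        as.integer(sub(".*_ctc", "", sid))]],
      ctc_pool = {
        cells <- scenario$ctc_pools[[as.integer(sub(".*_pool", "", sid))]]
        as.numeric(clone_cn[, names(cells), drop = FALSE] %*% cells) /
          sum(cells)
      })
  }

  list(sheet = sheet, calls = calls, depth = depth_tabs,
       windows = win_tabs,
       truth = list(patient_id = pid, purity = rho,
                    clones = data.frame(clone_id = ids,
                                        parent = unname(scenario$parent),
                                        ccf_bulk = unname(scenario$ccf),
                                        f_excl = unname(f_excl)),
                    mutations = muts, artifacts = artifacts,
                    window_grid = windows, clone_cn = clone_cn,
                    true_cn = true_cn,
                    tumor_spectrum = scenario$tumor_spectrum,
                    artifact_spectrum = scenario$artifact_spectrum))
}

#' Simulate a multi-patient cohort
#'
#' Builds a shared synthetic reference genome (with planted artifact-motif
#' sites), a gene map and a COSMIC-style recurrence table, then simulates
#' every patient. Fully deterministic given `seed`.
#'
#' @param scenarios Named list of [sim_scenario()] objects
#'   (default: [default_scenarios()]).
#' @param cfg A [run_config()].
#' @param seed Integer seed.
#' @param outdir Optional directory; when given, the full on-disk dataset is
#'   written (sample sheet, reference FASTA, gene BED, COSMIC TSV, per-sample
#'   VCF callsets, depth tables, window counts and truth tables).
#' @param n_chrom,chrom_len Genome shape.
#' @return Cohort list with `sheet`, `reference`, `genes`, `cosmic`,
#'   `kmer_sites` and per-patient results under `patients`.
#' @export
simulate_cohort <- function(scenarios = default_scenarios(),
                            cfg = run_config(), seed = cfg$rng_seed,
                            outdir = NULL, n_chrom = 10, chrom_len = 1e6) {
  set.seed(seed)
  genome <- random_reference(n_chrom, chrom_len, kmer = cfg$artifact_kmer,
                             n_kmer_sites = 30)
  genes <- default_gene_map()
  pool <- build_site_pool(genome$sequences)
  patients <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    set.seed(derive_seed(seed, i))
    if (is.null(sc$tumor_spectrum)) sc$tumor_spectrum <- random_spectrum()
    if (is.null(sc$artifact_spectrum))
      sc$artifact_spectrum <- random_spectrum()
    patients[[sc$patient_id]] <- simulate_patient(sc, genome, genes, pool,
                                                  cfg)
  }
  sheet <- validate_sample_sheet(
    do.call(rbind, lapply(patients, `[[`, "sheet")))
  cosmic <- build_cosmic_table(scenarios)
  cohort <- list(sheet = sheet, reference = genome$sequences,
                 kmer_sites = genome$kmer_sites, genes = genes,
                 cosmic = cosmic, patients = patients, seed = seed)
  class(cohort) <- "ctc_cohort"
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

# COSMIC-style recurrence table consistent with the planted drivers:
# high counts for driver variants (TP53 entries moderate so the TP53-specific
# display cutoff matters), low-count noise entries elsewhere
build_cosmic_table <- function(scenarios) {
  rows <- list(
    data.frame(gene = "TP53",
               protein_change = c("M237K", "H193L", "R175H"),
               count = c(12L, 9L, 40L), stringsAsFactors = FALSE),
    data.frame(gene = c("AKT1", "ESR1", "PIK3CA"),
               protein_change = c("E17K", "Y537N", "H1047R"),
               count = c(120L, 60L, 300L), stringsAsFactors = FALSE),
    data.frame(gene = c("PER3", "GPR12", "OR5A1"),
               protein_change = c("A1015T", "L88F", "S31T"),
               count = c(2L, 1L, 3L), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a simulated cohort to disk
#' @param cohort A `ctc_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("calls", "depth", "windows", "truth"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  write_sample_sheet(cohort$sheet, file.path(outdir, "sample_sheet.tsv"))
  write_reference_fasta(cohort$reference, file.path(outdir, "reference.fa"))
  write_gene_intervals(cohort$genes, file.path(outdir, "genes.bed"))
  write.table(cohort$cosmic, file.path(outdir, "cosmic_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in cohort$patients) {
    for (sid in names(p$calls))
      write_calls_vcf(p$calls[[sid]],
                      file.path(outdir, "calls", paste0(sid, ".vcf")), sid)
    for (sid in names(p$depth))
      write_depth_table(p$depth[[sid]],
                        file.path(outdir, "depth", paste0(sid, ".tsv")))
    for (sid in names(p$windows))
      write_window_counts(p$windows[[sid]],
                          file.path(outdir, "windows", paste0(sid, ".tsv")))
    tr <- p$truth
    write.table(tr$mutations,
                file.path(outdir, "truth",
                          paste0(tr$patient_id, "_mutations.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tr$artifacts,
                file.path(outdir, "truth",
                          paste0(tr$patient_id, "_artifacts.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tr$clones,
                file.path(outdir, "truth",
                          paste0(tr$patient_id, "_clones.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(patient_id = tr$patient_id, purity = tr$purity),
                file.path(outdir, "truth",
                          paste0(tr$patient_id, "_purity.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' Load a cohort dataset from disk
#'
#' Reads the files written by [write_cohort()] (truth tables are optional)
#' back into the in-memory cohort structure consumed by the analysis
#' functions.
#' @param dir Dataset directory.
#' @return `ctc_cohort`-shaped list (without truth unless present).
#' @export
load_cohort <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  reference <- read_reference_fasta(file.path(dir, "reference.fa"))
  genes <- read_gene_intervals(file.path(dir, "genes.bed"))
  cosmic_path <- file.path(dir, "cosmic_counts.tsv")
  cosmic <- if (file.exists(cosmic_path))
    read.delim(cosmic_path, stringsAsFactors = FALSE) else NULL
  patients <- list()
  for (pid in unique(sheet$patient_id)) {
    sub <- sheet[sheet$patient_id == pid, ]
    calls <- list(); depth <- list(); windows <- list()
    for (sid in sub$sample_id) {
      calls[[sid]] <- read_calls(file.path(dir, "calls",
                                           paste0(sid, ".vcf")), sid)
      depth[[sid]] <- read_depth_table(file.path(dir, "depth",
                                                 paste0(sid, ".tsv")))
      windows[[sid]] <- read_window_counts(file.path(dir, "windows",
                                                     paste0(sid, ".tsv")))
    }
    patients[[pid]] <- list(sheet = sub, calls = calls, depth = depth,
                            windows = windows)
  }
  structure(list(sheet = sheet, reference = reference, genes = genes,
                 cosmic = cosmic, patients = patients),
            class = "ctc_cohort")
}
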