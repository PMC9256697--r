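---
title: "Comparing CTC and bulk tumor genomes: models and methods"
author: "ctcconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing CTC and bulk tumor genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Circulating tumor cells (CTCs) isolated from blood can be profiled singly
or in small pools after whole-genome amplification (WGA), offering a
minimally invasive window on tumor heterogeneity. WGA, however, distorts
the signal: each allele at each locus drops out with substantial
probability (allele dropout, ADO), many loci receive no coverage at all,
and the amplification chemistry introduces hundreds of artifact
substitutions per cell. The analytical question this package addresses is
how much of a matched bulk biopsy's somatic landscape — single-nucleotide
variants (SNVs) and copy-number aberrations (CNAs) — is recoverable from
CTC samples, and conversely what CTCs reveal that the bulk hides
(subclonal drivers carried by minority cell populations).

The package implements the complete analysis as reusable functions: call
filtering, a bulk/CTC mutation taxonomy, recovery statistics,
trinucleotide-spectrum clustering, and a window-based copy-number
pipeline, plus a synthetic-data generator that reproduces the statistical
structure of such experiments with known ground truth.

# Study design and data model

A cohort consists of patients, each contributing exactly one bulk tumor
biopsy, one germline blood sample, one pooled white-blood-cell (WBC)
control processed through the same isolation/WGA workflow as the CTCs,
and one or more CTC samples (single cells, `n_cells = 1`, or pools of 5
or 10 cells). Inputs per sample are a somatic callset (VCF 4.2 with
`AD`/`DP` FORMAT fields, or an equivalent TSV), a per-site depth table
over the patient's mutation universe, and read counts in fixed genomic
windows (BED-like TSV, 0-based half-open). Point mutations are 1-based
(VCF convention); all intervals are 0-based half-open; the two
conventions meet only in the window-index helper.

# Mutation filtering

Three filters are applied, with all predicates evaluated on the
unfiltered input (`filter_calls()`):

1. **Artifact k-mer.** Calls whose flanking reference sequence
   (position ± 12 bp) contains the WGA artifact motif `TTAACTGACAGC` on
   either strand are removed. The match window and the
   flanking-reference (rather than read-level) interpretation are
   documented choices; removed calls are reported so users can audit.
2. **Cross-patient recurrence.** Mutation keys (chrom:pos:ref:alt)
   called in more than one patient are removed everywhere — recurrent
   cross-patient events on amplified material are treated as systematic
   artifacts.
3. **VAF floor with bulk rescue.** Calls below a 20% variant allele
   fraction are removed unless the same mutation is *called* in the
   patient's bulk sample. A call at exactly the floor is kept. "Present
   in the bulk" is interpreted as called (not merely read-supported),
   which is stricter and reproducible.

Because the first two predicates operate on whole mutation keys and the
rescue consults only the same key in the bulk, union-marking on the
input equals sequential application in the order listed; a literal
VAF-before-cross-patient sequence can differ (removing a key's only call
in one patient changes the cross-patient counts), which is why the
pipeline fixes the marking semantics.

# Mutation taxonomy

Over a patient's filtered, called mutations:

* **bulk** mutations: called in the bulk, absent from germline and WBC;
* **CTC** mutations: called in ≥ 1 CTC sample, absent from the WBC pool;
* **ctc_bulk** = CTC ∩ bulk; **ctc_shared** = CTC mutations in ≥ 2 CTC
  samples but not the bulk; **ctc_private** = CTC mutations in exactly
  one CTC sample and not the bulk; **bulk_only** = bulk mutations never
  seen in a CTC; everything else (e.g. germline-contaminated) is
  **excluded**. The labels are mutually exclusive and exhaustive, and the
  three CTC categories partition the CTC mutation set — both properties
  are asserted against a brute-force set-algebra oracle in the tests.

For driver review, `rescue_status()` reproduces the manual-recovery
convention: `called` (caller flag), `supported` (≥ 1 alternative read —
"recovered"), `covered_ref`, `no_coverage`.

# Recovery and VAF statistics

`recovery_curve()` computes, for every subset size k of the CTC samples,
the fraction of bulk mutations called in at least one sample of the
subset, summarized as median/min/max over subsets. Subsets are
enumerated exhaustively while `choose(n, k)` ≤ 10⁴ (configurable);
beyond that the same number of seeded uniform draws is used. The
exhaustive median is non-decreasing in k (unions are monotone), which
the tests assert. Curves are computed for all bulk mutations and for the
nonsynonymous/nonsense subset, each with and without the
coverage-conditioned selection (bulk mutations with ≥ 20× depth in at
least one CTC). Low-coverage accounting reports the fraction of
(bulk mutation, CTC sample) pairs under 5 reads — the pairwise
definition is the headline; a per-key-best-depth variant is also
emitted because the corresponding published per-patient number is
ambiguous between the two.

VAF comparisons use the two-sided Wilcoxon rank-sum test (exact
enumeration when both groups ≤ 25 without ties, otherwise the normal
approximation with tie and continuity correction) and Spearman rank
correlation via `cor.test`. Both are cross-checked in the test suite
against independent oracles (full enumeration, 10⁵-draw permutation,
rank-then-Pearson). No multiple-testing correction is applied, matching
the analysis protocol.

# Trinucleotide spectra and clustering

`context_spectrum()` counts mutations in the 96 pyrimidine-strand
trinucleotide classes (purine-reference sites are reverse-complemented;
contig-edge sites are skipped with a logged count). Samples are compared
with the distance d = 1 − cor(log(0.01 + f)), where f are the 96 context
frequencies; the pseudocount is applied to frequencies (not counts) and
the natural log is used (the base cancels in the correlation).
`cluster_spectra()` performs complete-linkage agglomeration on the
pairwise distance matrix; samples are sorted lexicographically before
clustering so tie-breaking is input-order invariant, and the dendrogram
is serialized as Newick. Spectra are built per CTC/WBC sample from its
filtered calls minus germline-called keys. De novo signature
factorization (NMF) and COSMIC-signature refitting are deliberately out
of scope.

# Copy-number pipeline

1. **Normalization.** Window read counts are library-size scaled against
   the matched control (WBC pool for CTC samples, germline blood for the
   bulk): log2((sᵢ/Σs)/(cᵢ/Σc)). Windows with control counts below 10
   are masked.
2. **Segmentation.** Circular binary segmentation: per chromosome, the
   arc (i, j] maximizing the arc-vs-complement two-sample t-statistic is
   accepted when its seeded permutation p-value is below α = 0.01 (1000
   permutations by default), then recursion continues on the pieces;
   minimum segment width is 2 windows. Because the value multiset is
   fixed under permutation, the total sum of squares is constant and
   maximizing |t| is equivalent to maximizing the between-group sum of
   squares — the kernel exploits this, plus a conservative dyadic
   partial-sum bound that prunes permutation scans without changing any
   decision, and stops a test early once the exceedance count already
   implies p ≥ α. Undo-splits, change-point pruning and hybrid p-values
   of more elaborate implementations are intentionally omitted; the
   permutation test's type-I calibration is verified directly
   (false-split rate ≤ 2α on null simulations).
3. **Purity/ploidy correction (bulk only).** A grid search over purity
   ρ ∈ [0.05, 1] (step 0.01) and tumor ploidy τ ∈ [1.2, 5] (step 0.05):
   each segment's ratio R = 2^(mean log2) implies
   q = (R·(ρτ + 2(1−ρ)) − 2(1−ρ))/ρ, and the objective is the
   window-weighted squared distance of q from the nearest integer, plus
   a self-consistency term ((Σw·q) − τ)², a penalty on negative q, a
   mild diploid prior 0.005·(τ − 2)², and a fixed penalty when all
   segments round to the same integer (flat profiles are unidentifiable
   and flagged degenerate, with CN left at 2). The diploid prior breaks
   the affine shift/doubling ambiguity that ratio-only data cannot
   resolve — a pure triploid genome is indistinguishable from a
   0.66-pure diploid one, and whole-genome-doubling calling is a
   non-goal; `rho_grid = 1` restricts the fit for samples known to be
   pure. Near-ties (within 1e-9) prefer the highest purity, then the
   lowest ploidy; fits with objective above 0.05 are rejected and the
   profile left uncorrected. This corrector is a documented
   simplification of full absolute copy-number models (no karyotype
   priors, no SNV-multiplicity likelihood).
4. **Ploidy-2 normalization and categories.** Corrected bulk copy
   numbers are rescaled as CN′ = 2q/τ̂; CTC and pooled-CTC samples are
   treated as pure (tumor-cell selection by the isolation workflow) and
   use CN′ = 2R recentered to a weighted mean of 2. Categories use
   strict thresholds on this scale: amplification CN > 4, gain CN > 2.5,
   deletion CN < 1.5, deep deletion CN < 0.8; boundary values fall to
   the less extreme category. The per-sample CNA count is the number of
   non-neutral segments (the published per-sample counts never define
   their unit; this choice is labeled in all reports).
5. **Concordance.** Pairwise Spearman correlation of per-window
   segment-mean CN′ over the windows unmasked in every profile ("across
   the whole genome" is read as a window-level vector), followed by
   complete-linkage clustering on 1 − ρ.

# The synthetic cohort generator

`simulate_cohort()` builds a small genome (10 chromosomes × 1 Mb, so
1000 windows at the 10-kb default), plants 30 copies of the artifact
motif, lays out driver genes at fixed coordinates, and simulates each
patient from a clone tree:

* **Clones** carry private SNVs (sites drawn so their trinucleotide
  context follows a patient-specific spectrum) and copy-number events;
  children inherit both. Cancer-cell fractions define exclusive cell
  populations; bulk VAF of a mutation is ρ·(carrier mass)/(ρ·q̄ + 2(1−ρ)),
  so a truncal heterozygous mutation in a diploid region sits at ρ/2.
* **WGA noise** (`wga_model`): per-allele dropout 0.3, locus dropout
  0.4, negative-binomial depth (mean 60, size 2 for amplified samples;
  mean 120, size 10 for unamplified bulk/germline), and Poisson artifact
  counts — 800 per CTC sample, 60 per WBC pool, drawn from the patient's
  artifact spectrum with 3% planted inside artifact-motif context so the
  k-mer filter has true positives. Artifacts exist in the amplified
  library by construction, so they see sequencing sampling but not
  dropout. These rates were chosen once to reproduce the reported orders
  of magnitude (hundreds of private mutations per CTC, an order of
  magnitude fewer on WBCs, bulk purities of 0.2–0.35) — they are the
  study conditions, not tuning knobs.
* **The caller** is emulated as: called ⇔ ≥ 3 alternative reads and
  observed VAF ≥ 0.05. With deep bulk coverage this calls truncal
  mutations at ρ/2 reliably while leaving low-CCF subclones below the
  threshold, which is what produces the ctc_shared class.
* **Window counts** are negative binomial around 2000 reads per diploid
  window (size 800 for unamplified samples, size 150 plus a lognormal
  sd-0.1 window factor for WGA samples). The purity-amplified error
  1/ρ · dR makes corrected bulk profiles visibly noisier than CTC
  profiles at these settings, as observed in real data.
* **The default bundle** ships three patients mirroring the structure of
  the motivating study: a concordant TNBC-like patient (purity 0.25,
  subclones at CCF 0.45/0.20 with small focal private events), a
  concordant HER2-like patient (purity 0.30, truncal ERBB2-region
  amplification at CN 8 in every sample, a CCF-0.04 subclone visible
  only in CTCs), and a discordant ER-like patient whose CTC compartment
  contains a clone absent from the bulk (CCF 0), carrying its own
  driver mutation (ESR1-like), its own driver amplification
  (ERBB2-region CN 7) and six private copy-number events. Roughly 30%
  of each tumor genome is aberrant, in line with breast cancer, which
  is what gives within-patient profile correlations of ~0.7–0.85
  against near-zero cross-patient values. CTC singles are assigned to
  clones explicitly (e.g. the divergent clone occupies exactly one
  single) so the qualitative structure is reproducible rather than a
  coin flip of multinomial sampling.

Ground truth (clone assignments, per-sample artifacts, per-window clone
copy numbers, purity) is returned and written to `truth/*.tsv`, and every
emitted call is traceable to exactly one of clonal truth or artifact —
a tested invariant.

**What the generator does not emulate:** spatially correlated WGA bias
(dropout is independent across sites, so recovery of bulk mutations by
unions of many CTCs is more optimistic than in real exomes, where the
published union-recovery percentages are much lower), exome capture
structure, GC/mappability waves, sequencing error in reads, and realistic
human coordinates. Passing tests therefore validate the statistical
machinery under the stated model, not performance on real WGA exomes.
The default bundle also gives bulk VAFs little dynamic range (most bulk
mutations are truncal at ρ/2), so the bulk-vs-CTC VAF rank correlation
in simulation is weak even though the pipeline computes it correctly.

# Numerical choices and degenerate inputs

* Permutation decisions use p̂ = (1 + #exceed)/(1 + nperm), conservative
  with ties counted as exceedances; a constant segment yields p̂ = 1.
* Depth-0 sites have undefined VAF (recorded missing, counted below the
  VAF floor unless rescued).
* Zero-variance log-spectra make the spectrum distance undefined;
  clustering refuses with the offending sample named.
* Purity fits need ≥ 3 segments; flat profiles return the degenerate
  branch (CN 2 everywhere).
* The CBS recovery scenario in the validation suite (5 breakpoints,
  5000 windows, shifts ≥ 0.4 at σ = 0.1) runs at 200 permutations,
  which preserves the α = 0.01 decision exactly (significance ⇔ ≤ 1
  exceedance) at a fifth of the cost; calibration runs use the default
  1000. One accepted false arc adds two segment boundaries, so "at most
  one spurious split event" corresponds to at most two extra segments.
* Validation problem sizes: 100 randomized callsets for the taxonomy
  oracle; 10⁴ Monte-Carlo subset draws against exhaustive enumeration at
  n ≤ 6; 100 null and 50 breakpoint-recovery segmentation runs; purity
  recovery at ρ ∈ {0.20, 0.35, 0.50}; 600 truncal mutations for the ADO
  inversion; 20 seeds × 3 patients × 5 CTCs for spectrum clustering.

# Known limitations

The purity corrector inherits the identifiability limits of ratio-only
data (genome doublings, flat genomes, heavily subclonal copy numbers);
the diploid prior encodes a preference, not knowledge. The taxonomy
treats the WBC pool purely as an exclusion list. Recovery statistics
assume the bulk callset is the truth being recovered; bulk false
negatives (low purity) appear as CTC-private or CTC-shared instead.
Indels are skipped throughout.
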