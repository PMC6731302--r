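#' Partitioned LD scores from reference genotypes
#'
#' For each target SNP `j` and annotation `c`, computes
#' `l(j,c) = sum_k a_ck * r2_jk` over reference SNPs `k` on the same
#' chromosome within `window` bases, where `r2_jk` is the squared genotypic
#' correlation in the reference panel with the small-sample adjustment
#' `r2_adj = r2 - (1 - r2) / (n_ref - 2)` (approximately unbiased for the
#' population `rho^2`; without it the regression intercept is inflated at
#' reference panels of a few hundred samples).
#'
#' @param ref A cohort (or list with `genotypes` and `variants`) serving as
#'   the LD reference panel.
#' @param annot An [annotation_matrix()] (or plain matrix) over the reference
#'   SNPs.
#' @param window One-sided physical window in bases (default 1 Mb; stands in
#'   for the 1 cM genetic window when no genetic map is available).
#' @param at Optional logical mask of target SNPs to score (e.g. regression
#'   SNPs); scores still sum over all reference SNPs in the window. Default
#'   all.
#' @param keep_ref Optional logical mask dropping reference SNPs (e.g.
#'   non-uniquely-mappable SNPs) from the panel before scoring.
#' @param chunk Number of target SNPs per block of the blocked computation.
#' @return Object of class `ldscore_table`: `variants` (scored SNPs),
#'   `scores` (matrix, one column per annotation), `n_ref`, `window`, `M`
#'   (per-annotation value sums over all reference SNPs) and `M_5_50` (sums
#'   over common MAF >= 0.05 reference SNPs).
#' @export
ld_scores <- function(ref, annot, window = 1e6, at = NULL, keep_ref = NULL,
                      chunk = 1024L) {
  if (window <= 0) stop("window must be > 0")
  g <- ref$genotypes; v <- ref$variants
  A_all <- annot_values(annot)
  if (nrow(A_all) != ncol(g)) stop("annotation rows must match reference SNPs")
  if (is.null(keep_ref)) keep_ref <- rep(TRUE, ncol(g))
  mono <- matrixStats_colVars(g) == 0
  if (any(mono & keep_ref)) {
    message(sum(mono & keep_ref), " monomorphic reference SNPs excluded from the panel")
    keep_ref <- keep_ref & !mono
  }
  if (is.null(at)) at <- rep(TRUE, ncol(g))
  at <- at & !mono
  n <- nrow(g)
  if (n < 3) stop("reference panel too small for the r2 adjustment")
  X <- standardize_genotypes(g[, keep_ref, drop = FALSE])
  vref <- v[keep_ref, , drop = FALSE]
  A <- A_all[keep_ref, , drop = FALSE]
  tgt_idx <- which(at)
  scores <- matrix(0, length(tgt_idx), ncol(A_all),
                   dimnames = list(NULL, colnames(A_all)))
  Xt <- standardize_genotypes(g[, tgt_idx, drop = FALSE])
  for (chr in unique(as.character(v$chr[tgt_idx]))) {
    ti <- which(as.character(v$chr[tgt_idx]) == chr)
    ri <- which(as.character(vref$chr) == chr)
    if (!length(ri)) next
    bp_t <- v$bp[tgt_idx][ti]; bp_r <- vref$bp[ri]
    for (s in seq(1, length(ti), by = chunk)) {
      ci <- ti[s:min(s + chunk - 1, length(ti))]
      bp_c <- v$bp[tgt_idx][ci]
      near <- ri[bp_r >= min(bp_c) - window & bp_r <= max(bp_c) + window]
      if (!length(near)) next
      r <- crossprod(Xt[, ci, drop = FALSE], X[, near, drop = FALSE]) / (n - 1)
      r2 <- r^2
      r2 <- r2 - (1 - r2) / (n - 2)
      outw <- abs(outer(bp_c, vref$bp[near], "-")) > window
      r2[outw] <- 0
      scores[ci, ] <- scores[ci, ] + r2 %*% A[near, , drop = FALSE]
    }
  }
  common <- if (!is.null(vref$maf)) vref$maf >= 0.05 else rep(TRUE, nrow(vref))
  structure(list(
    variants = v[tgt_idx, , drop = FALSE],
    scores = scores, n_ref = n, window = window,
    M = colSums(A), M_5_50 = colSums(A[common, , drop = FALSE])
  ), class = "ldscore_table")
}

#' @export
print.ldscore_table <- function(x, ...) {
  cat(sprintf("ldscore_table: %d SNPs x %d annotations (n_ref = %d, window = %g bp)\n",
              nrow(x$scores), ncol(x$scores), x$n_ref, x$window))
  invisible(x)
}

#' Regression-SNP and heritability-SNP filters
#'
#' The regression set excludes SNPs with marginal association statistics
#' `chi2 > max(80, 0.001 * N)` and SNPs inside the major histocompatibility
#' complex region; the heritability set is the common (MAF >= 0.05) SNPs of
#' the reference panel. Both masks are aligned to the variant table and
#' reported with counts.
#'
#' @param variants Variant table with `maf`.
#' @param sumstats A [gwas_sumstats()] table.
#' @param n GWAS sample size; defaults to the median `N` in `sumstats`.
#' @param mhc Named list `chr`, `start`, `end` (1-based, inclusive) for the
#'   MHC exclusion region; `NULL` disables it. Default chr6:25-34 Mb.
#' @param chisq_cap Apply the large-chi-square cap? It guards real-data
#'   analyses against confounding at sentinel SNPs; model-faithful
#'   simulations may disable it.
#' @return List with logical `regression` and `heritability` masks (per
#'   variant row) and a `counts` list.
#' @export
filter_snps <- function(variants, sumstats, n = NULL,
                        mhc = list(chr = "6", start = 25e6, end = 34e6),
                        chisq_cap = TRUE) {
  n <- n %||% median(sumstats$N)
  idx <- match(variants$snp, sumstats$SNP)
  present <- !is.na(idx)
  chi2 <- rep(NA_real_, nrow(variants))
  chi2[present] <- sumstats$CHISQ[idx[present]]
  cap <- max(80, 0.001 * n)
  regression <- present
  if (chisq_cap) regression <- regression & chi2 <= cap
  if (!is.null(mhc)) {
    in_mhc <- as.character(variants$chr) == as.character(mhc$chr) &
      variants$bp >= mhc$start & variants$bp <= mhc$end
    regression <- regression & !in_mhc
  } else in_mhc <- rep(FALSE, nrow(variants))
  regression[is.na(regression)] <- FALSE
  if (!any(regression)) stop("empty regression SNP set after filtering")
  if (is.null(variants$maf)) stop("variant table needs 'maf' for the heritability mask")
  heritability <- variants$maf >= 0.05
  if (!any(heritability)) stop("no common (MAF >= 0.05) SNPs for the heritability set")
  list(regression = regression, heritability = heritability,
       counts = list(n_variants = nrow(variants),
                     n_regression = sum(regression),
                     n_excluded_chisq = if (chisq_cap) sum(present & chi2 > cap, na.rm = TRUE) else 0L,
                     n_excluded_mhc = sum(in_mhc),
                     n_heritability = sum(heritability),
                     chisq_cap = if (chisq_cap) cap else NA_real_))
}
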