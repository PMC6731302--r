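#' Excess overlap between two binary annotations
#'
#' `Excess(A, B) = (|A and B| / M) / ((|A| / M) * (|B| / M))`, where `M` is
#' the total SNP count: the joint SNP frequency relative to the product of
#' the marginals. 1 under independence, `M / |B|` when `A` is a subset of
#' `B`, `M / |A|` for an annotation with itself. The standard error comes
#' from a block jackknife over contiguous SNP blocks (200 by default, the
#' same genomic blocks the regression uses).
#'
#' @param a,b Binary 0/1 vectors over the same SNPs.
#' @param n_blocks Jackknife blocks (default 200).
#' @return List with `excess`, `se`, `n_overlap`, `n_a`, `n_b`, `M`.
#' @export
excess_overlap <- function(a, b, n_blocks = 200L) {
  stopifnot(length(a) == length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("excess overlap is defined for binary annotations")
  if (sum(a) == 0 || sum(b) == 0) stop("empty annotation")
  M <- length(a)
  ex <- function(na, nb, nab, m) (nab / m) / ((na / m) * (nb / m))
  est <- ex(sum(a), sum(b), sum(a * b), M)
  nb_ <- min(as.integer(n_blocks), M)
  block <- rep(seq_len(nb_), each = ceiling(M / nb_))[seq_len(M)]
  bl_a <- tapply(a, block, sum); bl_b <- tapply(b, block, sum)
  bl_ab <- tapply(a * b, block, sum); bl_m <- tabulate(block, nb_)
  loo <- vapply(seq_len(nb_), function(k)
    ex(sum(a) - bl_a[k], sum(b) - bl_b[k], sum(a * b) - bl_ab[k], M - bl_m[k]),
    numeric(1))
  loo[!is.finite(loo)] <- est
  list(excess = est, se = jackknife_se(loo),
       n_overlap = sum(a * b), n_a = sum(a), n_b = sum(b), M = M)
}

#' Random-effects meta-analysis across traits
#'
#' DerSimonian-Laird random-effects pooling of per-trait estimates (e.g.
#' enrichment or tau* for one annotation across many traits). Reduces to
#' inverse-variance fixed-effects pooling when the estimated between-trait
#' variance is zero. A single trait is returned unchanged with a warning.
#'
#' @param estimates Per-trait estimates.
#' @param ses Per-trait standard errors (finite, > 0).
#' @param labels Optional trait labels.
#' @return List with `estimate`, `se`, `tau2` (between-trait variance), `k`
#'   (number of traits), and per-trait `weights` (normalized).
#' @export
meta_analyze <- function(estimates, ses, labels = NULL) {
  stopifnot(length(estimates) == length(ses))
  if (!all(is.finite(ses)) || any(ses <= 0)) stop("all standard errors must be finite and positive")
  k <- length(estimates)
  if (k < 1) stop("no traits to meta-analyze")
  if (k == 1) {
    warning("a single trait: returning it unchanged")
    return(list(estimate = estimates, se = ses, tau2 = 0, k = 1L,
                weights = setNames(1, labels %||% "trait1")))
  }
  fit <- metafor::rma(yi = estimates, sei = ses, method = "DL")
  w <- weights(fit) / 100
  list(estimate = as.numeric(fit$beta), se = fit$se, tau2 = fit$tau2,
       k = k, weights = setNames(as.numeric(w), labels %||% paste0("trait", seq_len(k))))
}

#' Contrast a quantity between two trait classes
#'
#' Meta-analyzes each class separately ([meta_analyze()]) and tests the
#' difference of pooled means with a two-sided z-test,
#' `z = (m_a - m_b) / sqrt(se_a^2 + se_b^2)`. Trait classes must not share
#' traits.
#'
#' @param results data.frame with columns `trait`, `class`, `estimate`, `se`.
#' @param class_a,class_b Class labels to contrast (e.g. `"blood"` vs
#'   `"other"`).
#' @return List with `difference`, `se`, `z`, `p`, and the two class metas.
#' @export
class_contrast <- function(results, class_a, class_b) {
  ra <- results[results$class == class_a, , drop = FALSE]
  rb <- results[results$class == class_b, , drop = FALSE]
  if (!nrow(ra) || !nrow(rb)) stop("both classes must be non-empty")
  if (length(intersect(ra$trait, rb$trait)))
    stop("classes share traits: ", paste(intersect(ra$trait, rb$trait), collapse = ", "))
  ma <- meta_analyze(ra$estimate, ra$se, ra$trait)
  mb <- meta_analyze(rb$estimate, rb$se, rb$trait)
  d <- ma$estimate - mb$estimate
  se <- sqrt(ma$se^2 + mb$se^2)
  z <- d / se
  list(difference = d, se = se, z = z, p = 2 * pnorm(-abs(z)),
       meta_a = ma, meta_b = mb)
}

#' Bonferroni significance against a designed hypothesis family
#'
#' Calls a p-value significant iff `p < alpha / n_tests`, correcting against
#' the full designed family (e.g. 281 consensus 9-mers, or 281 * 27 = 7587
#' one-mismatch neighbors), not merely the tests performed.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param n_tests Size of the designed hypothesis family (>= number of
#'   p-values supplied).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector of significance calls, with the per-test threshold
#'   in attribute `"threshold"`.
#' @export
multiple_testing <- function(pvalues, n_tests, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (n_tests < length(pvalues)) stop("n_tests must cover at least the supplied p-values")
  thr <- alpha / n_tests
  structure(pvalues < thr, threshold = thr)
}

#' Drop duplicated traits, keeping the larger sample size
#'
#' When two data sets measure the same trait (high genetic correlation,
#' supplied as input metadata), only the larger-N one should enter
#' meta-analysis.
#'
#' @param manifest data.frame with columns `trait`, `N` (and anything else).
#' @return The manifest with, per duplicated trait name, only the largest-N
#'   row retained.
#' @export
dedupe_traits <- function(manifest) {
  stopifnot(all(c("trait", "N") %in% names(manifest)))
  ord <- order(manifest$trait, -manifest$N)
  m <- manifest[ord, , drop = FALSE]
  m[!duplicated(m$trait), , drop = FALSE]
}
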