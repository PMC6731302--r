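#' Fit the stratified LD score regression
#'
#' Regresses per-SNP GWAS chi-square statistics on annotation-partitioned LD
#' scores under the model `E[chi2_j] = N * sum_c l(j,c) tau_c + 1`, by
#' weighted least squares with a free intercept (constrainable to 1). All
#' downstream uncertainty comes from a leave-one-block-out genomic jackknife
#' over contiguous blocks with equal numbers of regression SNPs (200 blocks
#' by default); the per-block tau estimates are stored in the fit so every
#' derived quantity (h2, enrichment, tau*) can be re-derived per block.
#'
#' Weights (switchable to unweighted) are the product of an overcounting
#' weight `1 / max(1, l_tot(j))` and a heteroskedasticity weight
#' `1 / (2 * (N * l_tot(j) * taubar + 1)^2)` with `taubar` from a one-pass
#' moment pre-fit, followed by one re-weighting iteration using the fitted
#' per-SNP variance; `l_tot` is the LD score of the all-ones annotation when
#' present (the recommended design includes one), else the row maximum.
#'
#' @param sumstats A [gwas_sumstats()] table (or anything with `SNP`,
#'   `CHISQ`, `N`).
#' @param ldscores An [ld_scores()] table.
#' @param annot The [annotation_matrix()] the scores were computed from
#'   (provides heritability-SNP values, sd(c), M_c and the size gate).
#' @param filters Optional [filter_snps()] masks aligned to the annotation's
#'   variant rows; defaults to all scored SNPs / all annotation rows.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param intercept `"free"` (default) or `"fixed"` (constrained to 1).
#' @param weights `"default"` or `"none"`.
#' @return Object of class `sldsc_fit`.
#' @export
sldsc_fit <- function(sumstats, ldscores, annot, filters = NULL,
                      n_blocks = 200L, intercept = c("free", "fixed"),
                      weights = c("default", "none")) {
  intercept <- match.arg(intercept); weights <- match.arg(weights)
  A_all <- annot_values(annot)
  meta <- if (inherits(annot, "annot_matrix")) annot$meta else
    data.frame(name = colnames(A_all), source = NA, pct_snps = NA,
               flank_of = NA_character_, expected_only = FALSE)
  L <- ldscores$scores
  if (ncol(L) != ncol(A_all)) stop("ldscores and annotation have different annotation counts")
  cn <- colnames(L) %||% colnames(A_all)
  scored <- ldscores$variants
  idx <- match(scored$snp, sumstats$SNP)
  reg <- !is.na(idx)
  # regression mask: scored SNPs present in sumstats, intersected with filters
  if (!is.null(filters)) {
    # filters are aligned to the full variant table used to build the annotation
    full_snps <- if (inherits(annot, "annot_matrix")) annot$snps else scored$snp
    reg <- reg & filters$regression[match(scored$snp, full_snps)]
    herit <- filters$heritability
  } else {
    herit <- rep(TRUE, nrow(A_all))
  }
  if (sum(reg) < 2L * ncol(L)) stop("too few regression SNPs after filtering")
  if (sum(reg) < 200L * ncol(L))
    warning("fewer than 200 regression SNPs per annotation; estimates may be unstable")
  chi2 <- sumstats$CHISQ[idx[reg]]
  N <- median(sumstats$N[idx[reg]])
  Lr <- L[reg, , drop = FALSE]
  p_ann <- ncol(Lr)
  # rank check, naming a collinear pair
  qrX <- qr(cbind(1, Lr))
  if (qrX$rank < p_ann + 1L) {
    cc <- cor(Lr)
    pair <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(pair))
      stop(sprintf("rank-deficient design: annotations '%s' and '%s' are collinear",
                   cn[pair[1, 1]], cn[pair[1, 2]]))
    stop("rank-deficient design")
  }
  ell_tot_col <- which(apply(A_all, 2, function(v) all(v == 1)))[1]
  ell_tot <- if (!is.na(ell_tot_col)) Lr[, ell_tot_col] else do.call(pmax, as.data.frame(Lr))
  wfun <- function(pred_var) {
    if (weights == "none") return(rep(1, nrow(Lr)))
    1 / pmax(1, ell_tot) / (2 * (N * pred_var + 1)^2)
  }
  taubar <- max((mean(chi2) - 1) / (N * mean(ell_tot)), 0)
  w <- wfun(ell_tot * taubar)
  nb <- min(as.integer(n_blocks), sum(reg))
  block <- rep(seq_len(nb), each = ceiling(sum(reg) / nb))[seq_len(sum(reg))]
  fit_once <- function(w) {
    if (intercept == "free") {
      X <- cbind(`(intercept)` = 1, N * Lr); y <- chi2
    } else {
      X <- N * Lr; y <- chi2 - 1
    }
    sw <- sqrt(w)
    Xw <- X * sw; yw <- y * sw
    XtX <- crossprod(Xw); Xty <- crossprod(Xw, yw)
    # per-block moments for leave-one-out refits
    pdim <- ncol(X)
    XtX_b <- array(0, c(pdim, pdim, nb)); Xty_b <- matrix(0, pdim, nb)
    for (b in seq_len(nb)) {
      sel <- block == b
      XtX_b[, , b] <- crossprod(Xw[sel, , drop = FALSE])
      Xty_b[, b] <- crossprod(Xw[sel, , drop = FALSE], yw[sel])
    }
    est <- solve(XtX, Xty)
    loo <- matrix(0, nb, pdim)
    for (b in seq_len(nb))
      loo[b, ] <- drop(solve(XtX - XtX_b[, , b], Xty - Xty_b[, b]))
    list(est = drop(est), loo = loo)  # loo: nb x pdim
  }
  f1 <- fit_once(w)
  # one re-weighting iteration from the fitted per-SNP variance
  if (weights == "default") {
    tau_hat <- if (intercept == "free") f1$est[-1] else f1$est
    pred <- pmax(drop(Lr %*% tau_hat), 0)
    f1 <- fit_once(wfun(pred))
  }
  if (intercept == "free") {
    icpt <- unname(f1$est[1]); tau <- f1$est[-1]
    icpt_loo <- f1$loo[, 1]; tau_loo <- f1$loo[, -1, drop = FALSE]
  } else {
    icpt <- 1; tau <- f1$est
    icpt_loo <- rep(1, nb); tau_loo <- f1$loo
  }
  names(tau) <- cn; colnames(tau_loo) <- cn
  A_h <- A_all[herit, , drop = FALSE]
  Msum <- colSums(A_h)
  Q <- crossprod(A_h)                  # Q[c,d] = sum_j a_cj a_dj over herit SNPs
  M <- sum(herit)
  sd_c <- apply(A_h, 2, sd)
  h2 <- drop(Msum %*% tau)
  h2_loo <- drop(tau_loo %*% Msum)
  structure(list(
    tau = tau, tau_se = jackknife_se(tau_loo),
    intercept = icpt, intercept_se = jackknife_se(icpt_loo),
    tau_loo = tau_loo, intercept_loo = icpt_loo,
    h2_g = h2, h2_se = jackknife_se(h2_loo), h2_loo = h2_loo,
    M = M, Msum = Msum, Q = Q, sd_c = sd_c, A_herit = A_h,
    pct_snps = Msum / M, meta = meta, annot_names = cn,
    N = N, n_blocks = nb, n_regression = sum(reg),
    intercept_mode = intercept, weights = weights
  ), class = "sldsc_fit")
}

#' Delete-one-block jackknife standard error
#'
#' SE from leave-one-out estimates: `sqrt((B-1)/B * sum((x_b - mean)^2))`,
#' columnwise for a matrix of leave-one-out values.
#'
#' @param loo Vector (or `blocks x quantities` matrix) of leave-one-out
#'   estimates.
#' @return Standard error(s).
#' @export
jackknife_se <- function(loo) {
  loo <- as.matrix(loo)
  nb <- nrow(loo)
  m <- colMeans(loo)
  drop(sqrt((nb - 1) / nb * colSums((loo - rep(m, each = nb))^2)))
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("sldsc_fit: %d annotations, %d regression SNPs, N = %d, %d jackknife blocks\n",
              length(x$tau), x$n_regression, as.integer(x$N), x$n_blocks))
  cat(sprintf("  intercept = %.3f (se %.3f, %s), h2_g = %.4f (se %.4f)\n",
              x$intercept, x$intercept_se, x$intercept_mode, x$h2_g, x$h2_se))
  print(data.frame(annotation = x$annot_names, tau = x$tau, se = x$tau_se,
                   row.names = NULL))
  invisible(x)
}

.annot_index <- function(fit, annotation) {
  if (is.character(annotation)) {
    k <- match(annotation, fit$annot_names)
    if (is.na(k)) stop("unknown annotation: ", annotation)
    k
  } else as.integer(annotation)
}

#' Standardized per-annotation effect size tau*
#'
#' `tau*_c = tau_c * sd(c) / (h2_g / M_c)`: the change in per-SNP
#' heritability per standard deviation of the annotation, in units of the
#' genome-wide mean per-SNP heritability, comparable across traits and
#' annotations. The whole formula is recomputed per leave-one-out jackknife
#' block for the SE; the p-value takes `tau*/se` as standard normal.
#'
#' @param fit An [sldsc_fit()].
#' @param annotation Annotation name or index.
#' @return List with `estimate`, `se`, `p` (and `loo` leave-one-out values).
#' @export
tau_star <- function(fit, annotation) {
  k <- .annot_index(fit, annotation)
  if (fit$sd_c[k] == 0) {
    warning("constant annotation: sd(c) = 0, tau* defined as 0")
    return(list(estimate = 0, se = 0, p = 1, loo = rep(0, fit$n_blocks)))
  }
  if (fit$h2_g <= 0) {
    warning("estimated h2_g <= 0: tau* undefined, returning NA")
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                loo = rep(NA_real_, fit$n_blocks)))
  }
  ts <- function(tau_vec, h2) unname(tau_vec[k] * fit$sd_c[k] / (h2 / fit$M))
  est <- ts(fit$tau, fit$h2_g)
  loo <- vapply(seq_len(fit$n_blocks), function(b)
    ts(fit$tau_loo[b, ], fit$h2_loo[b]), numeric(1))
  se <- jackknife_se(loo)
  list(estimate = est, se = se,
       p = 2 * pnorm(-abs(est / se)), loo = loo)
}

#' Observed heritability share and enrichment of an annotation
#'
#' Observed `%h2(c)` is the share of total SNP heritability causally
#' explained by the common SNPs in the annotation,
#' `sum_j a_jc Var(beta_j) / h2_g` with `Var(beta_j) = sum_c a_cj tau_c`;
#' observed enrichment divides it by the annotation's share of common SNPs.
#' Standard errors come from the fit's genomic block jackknife; the p-value
#' tests enrichment different from 1 by a jackknife-t with `n_blocks - 1`
#' degrees of freedom. Annotations tagged expected-only (spanning under 0.4%
#' of common SNPs) are refused unless `force = TRUE`, since the stratified
#' regression is unreliable for very small annotations; use
#' [expected_enrichment()] for those.
#'
#' @param fit An [sldsc_fit()].
#' @param annotation Annotation name or index.
#' @param force Report despite the size gate?
#' @return List with `pct_h2`, `pct_h2_se`, `enrichment`, `enrichment_se`,
#'   `p`, `pct_snps`, and leave-one-out values.
#' @export
observed_enrichment <- function(fit, annotation, force = FALSE) {
  k <- .annot_index(fit, annotation)
  if (!force && isTRUE(fit$meta$expected_only[k]))
    stop(sprintf("annotation '%s' spans under the 0.4%% common-SNP size gate; report expected_enrichment() instead (or force = TRUE)",
                 fit$annot_names[k]))
  pct <- fit$pct_snps[k]
  if (pct == 0) stop("annotation covers no heritability SNPs")
  f <- function(tau_vec, h2) {
    h2c <- drop(fit$Q[k, ] %*% tau_vec)
    c(pct_h2 = unname(h2c / h2), enrichment = unname(h2c / h2 / pct))
  }
  est <- f(fit$tau, fit$h2_g)
  loo <- t(vapply(seq_len(fit$n_blocks), function(b)
    f(fit$tau_loo[b, ], fit$h2_loo[b]), numeric(2)))
  se <- jackknife_se(loo)
  tstat <- (est["enrichment"] - 1) / se["enrichment"]
  list(pct_h2 = unname(est["pct_h2"]), pct_h2_se = unname(se["pct_h2"]),
       enrichment = unname(est["enrichment"]), enrichment_se = unname(se["enrichment"]),
       p = unname(2 * pt(-abs(tstat), df = fit$n_blocks - 1)),
       pct_snps = unname(pct), loo = loo)
}

#' Expected heritability share and enrichment under a conditioning model
#'
#' The enrichment a focal annotation would show if its own effect were zero:
#' per-SNP variances are taken from a conditioning fit that does NOT include
#' the focal annotation, summed over focal-annotation SNPs and divided by
#' the total. Comparing observed with expected enrichment quantifies how
#' much of an annotation's signal is explained by the conditioning
#' annotations (e.g. the baseline-LD model).
#'
#' @param fit A conditioning [sldsc_fit()] fitted without the focal
#'   annotation.
#' @param focal Numeric annotation values for the focal annotation, aligned
#'   to the same variant rows the conditioning annotation matrix used.
#' @param herit_mask Logical heritability mask used in the conditioning fit
#'   (defaults to all rows, matching the fit's default).
#' @param name Focal annotation name for messages.
#' @return List with `pct_h2`, `pct_h2_se`, `enrichment`, `enrichment_se`,
#'   `pct_snps`, and leave-one-out values.
#' @export
expected_enrichment <- function(fit, focal, herit_mask = NULL, name = "focal") {
  focal <- as.numeric(focal)
  f_h <- if (is.null(herit_mask)) focal else focal[herit_mask]
  if (length(f_h) != fit$M) stop("focal annotation must align to the fit's heritability SNPs")
  # reject a focal that is already one of the conditioning annotations
  qf <- drop(crossprod(fit$A_herit, f_h))
  dup <- which(vapply(seq_along(fit$annot_names), function(k)
    max(abs(fit$A_herit[, k] - f_h)) == 0, logical(1)))
  if (length(dup))
    stop(sprintf("focal annotation duplicates conditioning annotation '%s'; expected enrichment requires the focal to be absent from the conditioning model",
                 fit$annot_names[dup[1]]))
  pct <- sum(f_h) / fit$M
  if (pct == 0) stop("focal annotation covers no heritability SNPs")
  f <- function(tau_vec, h2) {
    h2c <- drop(qf %*% tau_vec)
    c(pct_h2 = unname(h2c / h2), enrichment = unname(h2c / h2 / pct))
  }
  est <- f(fit$tau, fit$h2_g)
  loo <- t(vapply(seq_len(fit$n_blocks), function(b)
    f(fit$tau_loo[b, ], fit$h2_loo[b]), numeric(2)))
  se <- jackknife_se(loo)
  list(pct_h2 = unname(est["pct_h2"]), pct_h2_se = unname(se["pct_h2"]),
       enrichment = unname(est["enrichment"]), enrichment_se = unname(se["enrichment"]),
       pct_snps = unname(pct), loo = loo, name = name)
}

#' Joint conditional fit with focal annotations and their flanks
#'
#' Fits one stratified regression containing the conditioning annotations,
#' all focal annotations and their flank annotations simultaneously, and
#' reports per-focal tau, tau* and observed enrichment, plus expected
#' enrichment from a conditioning-only refit (focal and flank columns
#' removed). Each focal annotation should have exactly one flank annotation
#' (registered via `flank_of` in [annotation_matrix()]).
#'
#' @param sumstats,ldscores,annot,filters,n_blocks,intercept,weights As in
#'   [sldsc_fit()]; `annot`/`ldscores` must contain conditioning + focal +
#'   flank columns.
#' @param focal Character vector of focal annotation names.
#' @param force_observed Report observed enrichment for annotations under
#'   the size gate?
#' @return A `partition_result` data.frame, one row per focal annotation.
#' @export
joint_conditional_fit <- function(sumstats, ldscores, annot, focal,
                                  filters = NULL, n_blocks = 200L,
                                  intercept = "free", weights = "default",
                                  force_observed = FALSE) {
  stopifnot(inherits(annot, "annot_matrix"))
  if (!all(focal %in% annot$meta$name)) stop("focal annotations missing from the matrix")
  flanks <- annot$meta$name[!is.na(annot$meta$flank_of) & annot$meta$flank_of %in% focal]
  nfl <- table(factor(annot$meta$flank_of[annot$meta$name %in% flanks], levels = focal))
  if (any(nfl != 1))
    warning("each focal annotation should have exactly one flank annotation; counts: ",
            paste(sprintf("%s=%d", names(nfl), nfl), collapse = ", "))
  fit <- sldsc_fit(sumstats, ldscores, annot, filters = filters,
                   n_blocks = n_blocks, intercept = intercept, weights = weights)
  drop_cols <- c(focal, flanks)
  keep <- setdiff(annot$meta$name, drop_cols)
  if (!length(keep)) stop("no conditioning annotations remain after removing focal set")
  sub_annot <- subset_annot(annot, keep)
  sub_ld <- ldscores
  sub_ld$scores <- ldscores$scores[, keep, drop = FALSE]
  sub_ld$M <- ldscores$M[keep]; sub_ld$M_5_50 <- ldscores$M_5_50[keep]
  cond <- sldsc_fit(sumstats, sub_ld, sub_annot, filters = filters,
                    n_blocks = n_blocks, intercept = intercept, weights = weights)
  herit <- if (is.null(filters)) rep(TRUE, nrow(annot$values)) else filters$heritability
  rows <- lapply(focal, function(fc) {
    k <- .annot_index(fit, fc)
    oe <- observed_enrichment(fit, fc, force = force_observed ||
                                isTRUE(fit$meta$expected_only[k]))
    ts <- tau_star(fit, fc)
    ee <- expected_enrichment(cond, annot$values[herit, fc], name = fc)
    data.frame(
      annotation = fc, pct_snps = oe$pct_snps,
      pct_h2 = oe$pct_h2, pct_h2_se = oe$pct_h2_se,
      enrichment = oe$enrichment, enrichment_se = oe$enrichment_se,
      enrichment_p = oe$p,
      tau = fit$tau[k], tau_se = fit$tau_se[k],
      tau_star = ts$estimate, tau_star_se = ts$se, tau_star_p = ts$p,
      expected_pct_h2 = ee$pct_h2, expected_pct_h2_se = ee$pct_h2_se,
      expected_enrichment = ee$enrichment,
      expected_enrichment_se = ee$enrichment_se,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition_result", "data.frame")
  out
}

# column-subset of an annotation matrix preserving metadata
subset_annot <- function(annot, keep) {
  stopifnot(inherits(annot, "annot_matrix"))
  ki <- match(keep, annot$meta$name)
  structure(list(snps = annot$snps,
                 values = annot$values[, ki, drop = FALSE],
                 meta = annot$meta[ki, , drop = FALSE],
                 binary = annot$binary[ki]),
            class = "annot_matrix")
}
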