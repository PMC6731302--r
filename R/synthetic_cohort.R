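#' Simulation configuration for a synthetic GWAS cohort
#'
#' Defines the genetic architecture and cohort dimensions used by
#' [simulate_genotypes()], [draw_effects()] and [simulate_phenotype()].
#' Genotypes are LD-structured: haplotypes are Gaussian-copula latents with
#' within-block autocorrelation `ld_decay^|j-k|` (zero across blocks),
#' thresholded at the allele-frequency quantile and paired into diploid
#' dosages. Effect sizes follow the annotation-additive model
#' `Var(beta_j) = sum_c a_cj tau_c` or, in flat polygenic mode,
#' `beta ~ N(0, h2_g / n_causal)` for a random causal subset.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_snps Number of SNPs.
#' @param n_blocks_ld Number of independent LD blocks the SNPs are split into.
#' @param ld_decay Latent correlation decay per SNP-index step within a block,
#'   in `[0, 1)`. Observed dosage correlation is attenuated relative to the
#'   latent correlation by the threshold step.
#' @param maf_range Closed interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn uniformly.
#' @param h2_g Total SNP heritability in `[0, 1]`.
#' @param n_causal Number of causal SNPs for flat polygenic mode.
#' @param tau_vector Optional per-annotation coefficients (per-SNP variance
#'   units) for annotation-dependent architectures.
#' @param seed Mandatory RNG seed; every stage draws from a named substream of
#'   this seed, so identical configs reproduce bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps, n_blocks_ld = 10L, ld_decay = 0.9,
                       maf_range = c(0.05, 0.5), h2_g = 0.5,
                       n_causal = n_snps, tau_vector = NULL, seed) {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric 'seed' is mandatory")
  n_individuals <- as.integer(n_individuals)
  n_snps <- as.integer(n_snps)
  if (n_snps <= 0L) stop("degenerate config: n_snps must be positive")
  if (n_individuals <= 1L) stop("degenerate config: n_individuals must exceed 1")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("degenerate config: maf_range must be a non-empty interval in (0, 0.5]")
  if (h2_g < 0 || h2_g > 1) stop("h2_g must lie in [0, 1]")
  if (n_causal > n_snps) stop("n_causal cannot exceed n_snps")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  structure(list(
    n_individuals = n_individuals, n_snps = n_snps,
    n_blocks_ld = as.integer(n_blocks_ld), ld_decay = ld_decay,
    maf_range = as.numeric(maf_range), h2_g = h2_g,
    n_causal = as.integer(n_causal), tau_vector = tau_vector,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d individuals x %d SNPs, %d LD blocks (decay %.2f), h2_g = %.3f, seed %d\n",
              x$n_individuals, x$n_snps, x$n_blocks_ld, x$ld_decay, x$h2_g, x$seed))
  invisible(x)
}

# One haplotype matrix (n_hap x n_snps, 0/1): AR(1) Gaussian latents per LD
# block, thresholded at qnorm(f_j) so allele 1 has frequency f_j.
.haplotypes <- function(n_hap, freqs, block_id, ld_decay) {
  m <- length(freqs)
  z <- matrix(0, n_hap, m)
  s <- sqrt(1 - ld_decay^2)
  z[, 1] <- rnorm(n_hap)
  if (m > 1) for (j in 2:m) {
    e <- rnorm(n_hap)
    z[, j] <- if (block_id[j] == block_id[j - 1]) ld_decay * z[, j - 1] + s * e else e
  }
  z < matrix(qnorm(freqs), n_hap, m, byrow = TRUE)
}

#' Simulate LD-structured diploid genotypes
#'
#' Draws two haplotypes per individual (Gaussian-copula model, see
#' [sim_config()]) and sums them into dosages in `{0, 1, 2}`. Monomorphic
#' SNPs are redrawn so the emitted cohort has empirical MAF in (0, 0.5].
#' SNP ids are `rs<index>`; positions are evenly spaced 1 kb apart (1-based)
#' on a single synthetic chromosome, so interval-annotation arithmetic on
#' simulated variants is deterministic.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: list with `genotypes`
#'   (`n_individuals x n_snps` integer dosage matrix), `variants` (data.frame
#'   `snp, chr, bp, a1, a2, maf`), `phenotype` (`NULL` until
#'   [simulate_phenotype()]), and the `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps; n <- config$n_individuals
  block_id <- rep(seq_len(config$n_blocks_ld), each = ceiling(m / config$n_blocks_ld))[seq_len(m)]
  geno <- with_substream(config$seed, "genotypes", {
    freqs <- runif(m, config$maf_range[1], config$maf_range[2])
    g <- .haplotypes(n, freqs, block_id, config$ld_decay) +
         .haplotypes(n, freqs, block_id, config$ld_decay)
    storage.mode(g) <- "integer"
    # redraw any monomorphic SNP (possible at small n) from independent draws
    for (tries in 1:50) {
      mono <- which(matrixStats_colVars(g) == 0)
      if (!length(mono)) break
      for (j in mono) g[, j] <- rbinom(n, 2L, freqs[j])
    }
    if (any(matrixStats_colVars(g) == 0))
      stop("could not produce polymorphic SNPs; enlarge n_individuals or maf_range")
    g
  })
  p <- colMeans(geno) / 2
  variants <- data.frame(
    snp = paste0("rs", seq_len(m)), chr = "1",
    bp = (seq_len(m) - 1L) * 1000L + 1L,
    a1 = "A", a2 = "G", maf = pmin(p, 1 - p),
    stringsAsFactors = FALSE
  )
  structure(list(genotypes = geno, variants = variants, phenotype = NULL,
                 block_id = block_id, config = config),
            class = "cohort")
}

# column variances without matrixStats (not in Imports); vectorized
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals x %d SNPs%s\n", nrow(x$genotypes),
              ncol(x$genotypes), if (is.null(x$phenotype)) "" else ", phenotype attached"))
  invisible(x)
}

#' Draw per-SNP causal effect sizes
#'
#' Two architectures, both on the standardized-genotype scale:
#' annotation-additive, `beta_j ~ N(0, sum_c a_cj tau_c)` independently, with
#' `tau` taken from `config$tau_vector`; or flat polygenic,
#' `beta ~ N(0, h2_g / n_causal)` for a uniformly drawn causal subset and 0
#' elsewhere, so that `sum_j Var(beta_j) = h2_g` exactly.
#'
#' @param annot An [annotation_matrix()] (or plain numeric matrix, SNPs x
#'   annotations) aligned to the cohort's variants; ignored in flat mode.
#' @param config A [sim_config()]; `tau_vector` selects annotation mode.
#' @param mode `"annotation"` (requires `tau_vector`) or `"flat"`.
#' @return Numeric vector of effect sizes, length `n_snps`.
#' @export
draw_effects <- function(annot = NULL, config, mode = c("annotation", "flat")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (mode == "annotation") {
    if (is.null(config$tau_vector)) stop("annotation mode needs config$tau_vector")
    A <- annot_values(annot)
    if (ncol(A) != length(config$tau_vector))
      stop("tau_vector length must equal the number of annotations")
    v <- drop(A %*% config$tau_vector)
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      stop(sprintf("negative implied per-SNP variance at SNP index %d (%.3g)", bad, v[bad]))
    }
    with_substream(config$seed, "effects", rnorm(length(v), 0, sqrt(v)))
  } else {
    with_substream(config$seed, "effects", {
      beta <- numeric(config$n_snps)
      causal <- sample.int(config$n_snps, config$n_causal)
      beta[causal] <- rnorm(config$n_causal, 0, sqrt(config$h2_g / config$n_causal))
      beta
    })
  }
}

# standardize dosage columns to empirical mean 0 variance 1 (keeps the
# additive model exact); avoids scale()'s double pass over a large matrix
standardize_genotypes <- function(g) {
  mu <- colMeans(g)
  sdv <- sqrt(matrixStats_colVars(g))
  t((t(g) - mu) / sdv)
}

# X %*% beta for standardized X without materializing the standardized matrix
standardized_xb <- function(g, beta) {
  mu <- colMeans(g)
  sdv <- sqrt(matrixStats_colVars(g))
  b <- beta / sdv
  drop(g %*% b) - sum(mu * b)
}

#' Simulate a phenotype under the additive model Y = X beta + e
#'
#' `X` is the column-standardized genotype matrix; environmental noise is
#' i.i.d. `N(0, 1 - h2_g)`, so the phenotype has expected variance 1. The
#' realized genetic variance `var(X beta)` is recorded in the
#' `"realized_h2"` attribute for diagnostics.
#'
#' @param cohort A [simulate_genotypes()] cohort.
#' @param beta Effect sizes on the standardized scale.
#' @param h2_g Total SNP heritability in `[0, 1]`.
#' @param seed Seed for the environmental-noise substream; defaults to the
#'   cohort's config seed. Pass a fresh seed per replicate when drawing many
#'   phenotypes on one genotype panel.
#' @return The cohort with `$phenotype` set (and the realized genetic variance
#'   as an attribute of the phenotype vector).
#' @export
simulate_phenotype <- function(cohort, beta, h2_g = cohort$config$h2_g,
                               seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "cohort"), length(beta) == ncol(cohort$genotypes))
  if (h2_g < 0 || h2_g > 1) stop("h2_g must lie in [0, 1]")
  g <- standardized_xb(cohort$genotypes, beta)
  e <- if (h2_g < 1)
    with_substream(seed, "environment", rnorm(length(g), 0, sqrt(1 - h2_g)))
  else numeric(length(g))
  y <- g + e
  attr(y, "realized_h2") <- var(g)
  cohort$phenotype <- y
  cohort
}

#' Per-SNP marginal GWAS summary statistics
#'
#' Regresses the phenotype on each standardized dosage separately and emits
#' the squared marginal z (`CHISQ`), the signed `Z`, and the sample size `N`,
#' in the whitespace-delimited sumstats dialect (columns
#' `SNP A1 A2 N Z CHISQ`). Zero-variance SNPs are excluded with a message.
#'
#' @param cohort A cohort with a phenotype.
#' @return data.frame of class `sumstats`.
#' @export
gwas_sumstats <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$phenotype)) stop("cohort has no phenotype; run simulate_phenotype() first")
  g <- cohort$genotypes
  vars <- matrixStats_colVars(g)
  keep <- vars > 0
  if (any(!keep)) message(sum(!keep), " zero-variance SNPs excluded from summary statistics")
  n <- nrow(g)
  y <- as.numeric(cohort$phenotype)
  # marginal correlations from cross-moments (single BLAS pass)
  sxy <- (drop(crossprod(g[, keep, drop = FALSE], y)) -
            n * colMeans(g[, keep, drop = FALSE]) * mean(y)) / (n - 1)
  r <- sxy / sqrt(vars[keep] * var(y))
  z <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  out <- data.frame(
    SNP = cohort$variants$snp[keep],
    A1 = cohort$variants$a1[keep], A2 = cohort$variants$a2[keep],
    N = n, Z = z, CHISQ = z^2, stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(chi2) / qchisq(0.5, df = 1)`.
#'
#' @param chisq Vector of chi-square statistics.
#' @return Scalar inflation factor.
#' @export
lambda_gc <- function(chisq) median(chisq) / stats::qchisq(0.5, df = 1)
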