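#' Validate a pipeline run configuration
#'
#' A run config drives [run_pipeline()]: synthetic mode simulates a cohort,
#' builds annotations, scores, fits and reports; real mode loads PLINK
#' reference genotypes, a sumstats file and a thin-annot annotation matrix.
#' Validation happens before any compute: synthetic mode requires a seed,
#' and every referenced path must exist.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$mode <- match.arg(config$mode %||% "synthetic", c("synthetic", "real"))
  if (config$mode == "synthetic") {
    if (is.null(config$seed)) stop("validation: seed is mandatory in synthetic mode")
    config$n_individuals <- config$n_individuals %||% 2000L
    config$n_snps <- config$n_snps %||% 2000L
    config$n_blocks_ld <- config$n_blocks_ld %||% 100L
    config$ld_decay <- config$ld_decay %||% 0.7
    config$h2_g <- config$h2_g %||% 0.2
    config$random_annot_fraction <- config$random_annot_fraction %||% 0.1
    config$tau_vector <- config$tau_vector %||% NULL
  } else {
    for (f in c("ref_prefix", "sumstats", "annot")) {
      if (is.null(config[[f]])) stop("validation: real mode requires '", f, "'")
    }
    paths <- c(paste0(config$ref_prefix, c(".bed", ".bim", ".fam")),
               config$sumstats, config$annot)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("validation: missing input file(s): ",
                              paste(missing, collapse = ", "))
  }
  config$window <- config$window %||% 1e6
  config$n_blocks <- config$n_blocks %||% 200L
  config$n_ref <- config$n_ref %||% 1000L
  config$chisq_cap <- config$chisq_cap %||% TRUE
  config$intercept <- match.arg(config$intercept %||% "free", c("free", "fixed"))
  config$weights <- match.arg(config$weights %||% "default", c("default", "none"))
  structure(config, class = "run_config")
}

#' Run the end-to-end partitioned-heritability pipeline
#'
#' Stages in dependency order: synthesize (or load) cohort and summary
#' statistics; build the annotation matrix; compute partitioned LD scores;
#' apply SNP filters; fit the stratified regression; write the partition
#' result TSV and a JSON run manifest (inputs, filters, counts, seed,
#' package version). Synthetic mode is idempotent: identical config plus
#' seed reproduces byte-identical outputs.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @param out_dir Output directory (created if absent).
#' @return The output directory, invisibly; `results.tsv` and
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  tryCatch({
    if (config$mode == "synthetic") {
      stage <- "simulate"
      sc <- sim_config(config$n_individuals, config$n_snps,
                       n_blocks_ld = config$n_blocks_ld, ld_decay = config$ld_decay,
                       h2_g = config$h2_g, seed = config$seed)
      cohort <- simulate_genotypes(sc)
      stage <- "annotate"
      frac <- config$random_annot_fraction
      focal_vec <- with_substream(config$seed, "pipeline_annot", {
        a <- numeric(config$n_snps)
        a[sample.int(config$n_snps, max(1L, round(frac * config$n_snps)))] <- 1
        a
      })
      annot <- annotation_matrix(cohort$variants, base = rep(1, config$n_snps),
                                 focal = focal_vec, source = "synthetic")
      stage <- "effects"
      beta <- if (!is.null(config$tau_vector)) {
        sc$tau_vector <- config$tau_vector
        draw_effects(annot, sc, mode = "annotation")
      } else draw_effects(config = sc, mode = "flat")
      cohort <- simulate_phenotype(cohort, beta, config$h2_g)
      stage <- "gwas"
      ss <- gwas_sumstats(cohort)
      ref <- cohort
      if (config$n_ref < config$n_individuals) {
        keep <- with_substream(config$seed, "refpanel",
                               sort(sample.int(config$n_individuals, config$n_ref)))
        ref <- cohort; ref$genotypes <- cohort$genotypes[keep, , drop = FALSE]
      }
      variants <- cohort$variants
    } else {
      stage <- "load"
      ref <- read_plink(config$ref_prefix)
      ss <- read_sumstats(config$sumstats)
      variants <- ref$variants
      annot <- read_thin_annot(config$annot, variants)
    }
    stage <- "ldscore"
    ld <- ld_scores(ref, annot, window = config$window)
    stage <- "filter"
    filters <- filter_snps(variants, ss, chisq_cap = config$chisq_cap)
    stage <- "partition"
    focal <- setdiff(annot$meta$name, "base")
    res <- joint_conditional_fit(ss, ld, annot, focal = focal, filters = filters,
                                 n_blocks = config$n_blocks,
                                 intercept = config$intercept,
                                 weights = config$weights, force_observed = TRUE)
    stage <- "write"
    res_path <- file.path(out_dir, "results.tsv")
    out <- as.data.frame(res)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) signif(x, 10))
    write.table(out, res_path, quote = FALSE, row.names = FALSE, sep = "\t")
    manifest <- list(
      mode = config$mode, seed = config$seed %||% NA,
      software = paste0("teldsc ", as.character(packageVersion("teldsc"))),
      counts = filters$counts,
      n_annotations = ncol(annot$values),
      annotations = annot$meta$name,
      window = config$window, n_blocks = config$n_blocks
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline halted at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Small seeded fixtures for tests and examples
#'
#' Builds, in memory, the toy data sets the test suite exercises: a 5-SNP LD
#' cohort for brute-force LD-score checks, the 10-SNP overlap fixture
#' (`|A| = 4`, `|B| = 5`, `|A and B| = 3`, excess overlap 1.5), a random 10
#' kb chromosome for k-mer scans, and a noiseless regression fixture where
#' `chi2 = N * sum_c l(j,c) tau_c + 1` holds exactly. All content is a
#' deterministic function of the seed; `checksums` carries md5 digests of
#' canonical text renderings.
#'
#' @param seed RNG seed (default 1).
#' @return Named list `ld5`, `overlap10`, `fasta10kb`, `noiseless`,
#'   `checksums`.
#' @export
make_fixtures <- function(seed = 1L) {
  ld5 <- simulate_genotypes(sim_config(n_individuals = 50, n_snps = 5,
                                       n_blocks_ld = 1, ld_decay = 0.6,
                                       seed = substream_seed(seed, "ld5")))
  overlap10 <- list(a = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                    b = c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
  fasta10kb <- with_substream(seed, "fasta", {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
    Biostrings::DNAStringSet(setNames(s, "chrS"))
  })
  # noiseless regression fixture
  m <- 100L
  variants <- data.frame(snp = paste0("rs", 1:m), chr = "1",
                         bp = (1:m - 1L) * 1000L + 1L, a1 = "A", a2 = "G",
                         maf = 0.25, stringsAsFactors = FALSE)
  focal <- as.numeric(1:m %in% 1:30)
  annot <- annotation_matrix(variants, base = rep(1, m), focal = focal,
                             source = "fixture")
  scores <- with_substream(seed, "noiseless", cbind(
    base = 1 + runif(m, 0, 4),
    focal = runif(m, 0, 2) * (0.3 + focal)
  ))
  ld <- structure(list(variants = variants, scores = scores, n_ref = Inf,
                       window = 1e6, M = colSums(annot$values),
                       M_5_50 = colSums(annot$values)), class = "ldscore_table")
  tau <- c(base = 2e-4, focal = 3e-4)
  N <- 10000
  chi2 <- drop(N * scores %*% tau + 1)
  ss <- data.frame(SNP = variants$snp, A1 = "A", A2 = "G", N = N,
                   Z = sqrt(chi2), CHISQ = chi2, stringsAsFactors = FALSE)
  class(ss) <- c("sumstats", "data.frame")
  noiseless <- list(variants = variants, annot = annot, ldscores = ld,
                    sumstats = ss, tau = tau, N = N)
  fx <- list(ld5 = ld5, overlap10 = overlap10, fasta10kb = fasta10kb,
             noiseless = noiseless)
  fx$checksums <- vapply(list(
    ld5 = ld5$genotypes,
    overlap10 = unlist(overlap10),
    fasta10kb = as.character(fasta10kb),
    noiseless = chi2
  ), .text_md5, character(1))
  fx
}

# md5 of a canonical text rendering (deterministic across platforms)
.text_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                   collapse = ","), f)
  unname(tools::md5sum(f))
}
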