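# shared in-code fixtures for the suite

toy_variants <- function(n, chr = "1", spacing = 1000L, maf = 0.25) {
  data.frame(snp = paste0("rs", seq_len(n)), chr = chr,
             bp = (seq_len(n) - 1L) * spacing + 1L,
             a1 = "A", a2 = "G", maf = maf, stringsAsFactors = FALSE)
}

# small cohort + all-ones/focal annotation + sumstats, one call
quick_study <- function(seed, n = 2000, m = 500, h2 = 0.5, decay = 0.5,
                        focal_frac = 0.2, tau_mult = 4, flat = FALSE) {
  sc <- sim_config(n_individuals = n, n_snps = m,
                   n_blocks_ld = max(1L, m %/% 20L), ld_decay = decay,
                   h2_g = h2, seed = seed)
  co <- simulate_genotypes(sc)
  fv <- numeric(m)
  fv[with_seed(seed + 1, sample.int(m, round(focal_frac * m)))] <- 1
  annot <- annotation_matrix(co$variants, base = rep(1, m), focal = fv)
  if (flat) {
    beta <- draw_effects(config = sc, mode = "flat")
  } else {
    v <- h2 / (m * (1 - focal_frac + focal_frac * (1 + tau_mult)))
    sc$tau_vector <- c(v, tau_mult * v)
    beta <- draw_effects(annot, sc, mode = "annotation")
  }
  co <- simulate_phenotype(co, beta, h2)
  list(cohort = co, annot = annot, sumstats = gwas_sumstats(co),
       config = sc, focal = fv, beta = beta)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# naive both-strand Hamming scan, the independent oracle for kmer_annotation
naive_kmer_scan <- function(seqs, query, max_mismatch) {
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  k <- nchar(query)
  pats <- unique(c(query, revcomp(query)))
  hits <- data.frame(chr = character(0), start1 = integer(0))
  for (chr in names(seqs)) {
    s <- as.character(seqs[[chr]])
    L <- nchar(s)
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      wch <- strsplit(w, "")[[1]]
      for (p in pats) {
        if (sum(wch != strsplit(p, "")[[1]]) <= max_mismatch) {
          hits <- rbind(hits, data.frame(chr = chr, start1 = i))
          break
        }
      }
    }
  }
  hits
}

# small fixtures legitimately trip the regression-SNP-count advisory
fit_quiet <- function(...) suppressWarnings(sldsc_fit(...))
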