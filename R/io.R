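#' Read a BED track (3-6 columns, optional score)
#'
#' BED is 0-based half-open; the returned `GRanges` follows the package's
#' internal convention (see [interval_set()]). Column 4 is stored as
#' `element_name`, column 5 as `score`, column 6 as strand. Malformed lines
#' are rejected with their line number.
#'
#' @param path BED file (optionally gzipped).
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t| +")
  nf <- lengths(parts)
  bad <- which(nf < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stop("malformed BED line ", bad[1], ": bad coordinates")
  gr <- interval_set(
    chrom = vapply(parts, `[`, "", 1), start = start, end = end,
    element_name = ifelse(nf >= 4, vapply(parts, function(p) p[4] %||% NA_character_, ""), NA_character_),
    strand = ifelse(nf >= 6, vapply(parts, function(p) if (length(p) >= 6) p[6] else "*", ""), "*")
  )
  if (any(nf >= 5))
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(
      vapply(parts, function(p) if (length(p) >= 5) p[5] else NA_character_, "")))
  gr
}

#' Read a RepeatMasker .out file
#'
#' Parses the whitespace-delimited RepeatMasker annotation format (3 header
#' lines, then one row per element). The divergence column (`milliDiv`,
#' mutations per thousand bases, column 2 of the table) is the element-age
#' proxy; `class/family` (column 11) is split on `/` into class and family
#' names. Coordinates in .out are 1-based inclusive and are converted to the
#' internal 0-based half-open convention.
#'
#' @param path RepeatMasker .out file.
#' @return `GRanges` with `element_name`, `class_name`, `family_name`,
#'   `milli_div` metadata.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # drop the banner: keep lines whose first token is a number (the SW score)
  first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)
  lines <- lines[!is.na(suppressWarnings(as.numeric(first_tok)))]
  if (!length(lines)) stop("no element records found in the RepeatMasker file")
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 11)) stop("malformed RepeatMasker line ", which(nf < 11)[1])
  f <- function(i) vapply(parts, `[`, "", i)
  cf <- strsplit(f(11), "/")
  interval_set(
    chrom = f(5),
    start = as.integer(f(6)) - 1L,        # 1-based inclusive -> 0-based half-open
    end = as.integer(f(7)),
    element_name = f(10),
    class_name = vapply(cf, `[`, "", 1),
    family_name = vapply(cf, function(x) if (length(x) > 1) x[2] else x[1], ""),
    milli_div = as.numeric(f(2)),
    strand = ifelse(f(9) == "C", "-", "+")
  )
}

#' Write / read PLINK binary genotypes
#'
#' Minimal PLINK 1 .bed/.bim/.fam support (SNP-major, 2-bit codes) for
#' exchanging the synthetic cohort with external tools. Dosage is the count
#' of the A1 allele; no missing genotypes are written.
#'
#' @param cohort A [simulate_genotypes()] cohort.
#' @param prefix Output path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  g <- cohort$genotypes; v <- cohort$variants
  n <- nrow(g); m <- ncol(g)
  fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                    pat = 0L, mat = 0L, sex = 0L,
                    phe = if (is.null(cohort$phenotype)) -9 else cohort$phenotype)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  bim <- data.frame(chr = v$chr, snp = v$snp, cm = 0, bp = v$bp, a1 = v$a1, a2 = v$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  # PLINK codes per 2 bits: 00 = hom A1 (dosage 2), 10 = het, 11 = hom A2 (dosage 0)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(m)) {
    cj <- code[as.character(g[, j])]
    length(cj) <- bytes_per_snp * 4L
    cj[is.na(cj)] <- 0L
    quads <- matrix(cj, nrow = 4)
    writeBin(as.raw(quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @param phenotype Read the .fam phenotype column into the cohort?
#' @export
read_plink <- function(prefix, phenotype = TRUE) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                    col.names = c("chr", "snp", "cm", "bp", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "phe"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- raw[-(1:3)]
  dose <- c(`0` = 2L, `2` = 1L, `3` = 0L, `1` = NA_integer_)
  bytes_per_snp <- ceiling(n / 4)
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    b <- as.integer(body[((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)])
    quads <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
    g[, j] <- dose[as.character(as.vector(quads)[seq_len(n)])]
  }
  p <- colMeans(g) / 2
  variants <- data.frame(snp = bim$snp, chr = as.character(bim$chr), bp = bim$bp,
                         a1 = bim$a1, a2 = bim$a2, maf = pmin(p, 1 - p),
                         stringsAsFactors = FALSE)
  structure(list(genotypes = g, variants = variants,
                 phenotype = if (phenotype && any(fam$phe != -9)) fam$phe else NULL,
                 config = NULL), class = "cohort")
}

#' Write / read GWAS summary statistics (sumstats dialect)
#'
#' Whitespace-delimited with a header row; columns `SNP A1 A2 N Z` (plus
#' `CHISQ` on write).
#'
#' @param sumstats A [gwas_sumstats()] data.frame.
#' @param path Output file.
#' @export
write_sumstats <- function(sumstats, path) {
  write.table(sumstats, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  out <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("SNP", "N") %in% names(out))) stop("sumstats must have SNP and N columns")
  if (is.null(out$CHISQ)) {
    if (is.null(out$Z)) stop("sumstats must have Z or CHISQ")
    out$CHISQ <- out$Z^2
  }
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write / read an annotation matrix (thin-annot dialect)
#'
#' One row per SNP, one column per annotation, header = annotation names;
#' gzip-compressed TSV.
#'
#' @param annot An [annotation_matrix()].
#' @param path Output `.gz` path.
#' @export
write_thin_annot <- function(annot, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(annot$values), con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_thin_annot
#' @param variants Variant table the stored columns align to.
#' @export
read_thin_annot <- function(path, variants) {
  vals <- as.matrix(read.table(path, header = TRUE, check.names = FALSE))
  if (nrow(vals) != nrow(variants)) stop("annotation rows do not match the variant table")
  do.call(annotation_matrix, c(list(variants), as.list(as.data.frame(vals))))
}

#' Write partitioned LD scores (ldscore dialect)
#'
#' `CHR SNP BP` plus one `L2` column per annotation, gzip-compressed, with
#' `<prefix>.M` and `<prefix>.M_5_50` sidecar files carrying the per-annotation
#' SNP counts (all reference SNPs, and common MAF >= 0.05 SNPs).
#'
#' @param ldscores An [ld_scores()] table.
#' @param prefix Output prefix (writes `<prefix>.l2.ldscore.gz`, `.M`, `.M_5_50`).
#' @export
write_ldscores <- function(ldscores, prefix) {
  df <- data.frame(CHR = ldscores$variants$chr, SNP = ldscores$variants$snp,
                   BP = ldscores$variants$bp, ldscores$scores, check.names = FALSE)
  con <- gzfile(paste0(prefix, ".l2.ldscore.gz"), "w")
  write.table(df, con, quote = FALSE, row.names = FALSE, sep = "\t")
  close(con)
  cat(paste(ldscores$M, collapse = "\t"), "\n", sep = "",
      file = paste0(prefix, ".l2.M"))
  cat(paste(ldscores$M_5_50, collapse = "\t"), "\n", sep = "",
      file = paste0(prefix, ".l2.M_5_50"))
  invisible(prefix)
}
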