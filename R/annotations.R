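#' Build an interval set for genomic elements
#'
#' Intervals are handled as BED-style 0-based half-open `[start, end)`
#' coordinates and stored internally as `GRanges`. SNP positions are 1-based
#' (variant-format convention); a SNP at 1-based position `p` lies in
#' `[start, end)` iff `start < p <= end`. Metadata columns carry the element,
#' class and family names, the milliDiv divergence score (mutations per
#' thousand bases relative to the element consensus, a proxy for element
#' age), and strand.
#'
#' @param chrom,start,end Vectors of chromosome names and 0-based half-open
#'   coordinates.
#' @param element_name,class_name,family_name Optional element identifiers.
#' @param milli_div Optional per-element divergence scores.
#' @param strand Optional strand (`"+"`, `"-"`, `"*"`).
#' @return A `GRanges` with metadata columns.
#' @export
interval_set <- function(chrom, start, end, element_name = NA_character_,
                         class_name = NA_character_, family_name = NA_character_,
                         milli_div = NA_real_, strand = "*") {
  if (any(start >= end)) stop("interval start must be < end (0-based half-open)")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end)),
    strand = strand
  )
  S4Vectors::mcols(gr)$element_name <- element_name
  S4Vectors::mcols(gr)$class_name <- class_name
  S4Vectors::mcols(gr)$family_name <- family_name
  S4Vectors::mcols(gr)$milli_div <- milli_div
  gr
}

# variants as a GPos-like GRanges of width-1 positions
.variant_ranges <- function(variants) {
  GenomicRanges::GRanges(as.character(variants$chr),
                         IRanges::IRanges(variants$bp, width = 1L))
}

.check_chrom_match <- function(variants, gr) {
  vs <- unique(as.character(variants$chr))
  is <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  if (!length(intersect(vs, is)))
    stop("chromosome names do not match between variants and intervals; unmatched: ",
         paste(union(setdiff(vs, is), setdiff(is, vs)), collapse = ", "))
  invisible(TRUE)
}

#' Binary SNP annotation from an interval set
#'
#' Marks each SNP whose 1-based position falls inside the union of the
#' intervals (membership rule `start < pos <= end` against the 0-based
#' half-open intervals).
#'
#' @param variants Variant table (`snp`, `chr`, `bp`, optionally `maf`).
#' @param intervals A `GRanges` from [interval_set()] or a reader.
#' @return Numeric 0/1 vector, one value per variant row.
#' @export
snps_in_intervals <- function(variants, intervals) {
  a <- numeric(nrow(variants))
  if (!length(intervals)) return(a)
  .check_chrom_match(variants, intervals)
  hits <- GenomicRanges::findOverlaps(.variant_ranges(variants),
                                      GenomicRanges::reduce(intervals, ignore.strand = TRUE))
  a[unique(S4Vectors::queryHits(hits))] <- 1
  a
}

#' Flanking-region annotation
#'
#' Marks SNPs within `width` bases of an element boundary but outside every
#' element body. The default 500 bp flank guards the stratified regression
#' against model misspecification at element edges; the sensitivity grid
#' 100/200/500/1000 bp is available through `width`. Flanks running past the
#' chromosome start are clipped at 0.
#'
#' @param variants Variant table.
#' @param intervals Element `GRanges`.
#' @param width Flank width in bases (> 0).
#' @return Numeric 0/1 vector per variant.
#' @export
flank_annotation <- function(variants, intervals, width = 500L) {
  if (!is.numeric(width) || width <= 0) stop("flank width must be > 0")
  body <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  ext <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(body),
    IRanges::IRanges(start = pmax(IRanges::start(body) - as.integer(width), 1L),
                     end = IRanges::end(body) + as.integer(width)))
  if (any(IRanges::start(body) - width < 1L))
    message("flanks extending past the chromosome start were clipped at position 1")
  flank <- GenomicRanges::setdiff(ext, body, ignore.strand = TRUE)
  snps_in_intervals(variants, flank)
}

#' Element-age quintile annotations
#'
#' Each TE-resident SNP inherits its element's milliDiv divergence (a SNP
#' covered by several dated elements takes the larger, i.e. older, value by
#' default). SNPs are then cut into five quintiles of the per-SNP milliDiv
#' distribution; the five resulting binary annotations are disjoint and
#' their union is the dated-TE annotation.
#'
#' @param variants Variant table.
#' @param intervals Element `GRanges`; every contributing interval must have
#'   `milli_div`.
#' @param tie How to resolve a SNP covered by elements with different
#'   milliDiv: `"older"` (larger value, default), `"younger"`, `"mean"`.
#' @param by Compute quintile boundaries over SNPs (default) or elements.
#' @return Numeric matrix (`n_snps x 5`), columns `age_q1` (youngest) ..
#'   `age_q5` (oldest).
#' @export
age_quintile_annotations <- function(variants, intervals,
                                     tie = c("older", "younger", "mean"),
                                     by = c("snp", "element")) {
  tie <- match.arg(tie); by <- match.arg(by)
  md <- S4Vectors::mcols(intervals)$milli_div
  if (is.null(md) || any(is.na(md))) stop("every interval must carry milli_div")
  .check_chrom_match(variants, intervals)
  hits <- GenomicRanges::findOverlaps(.variant_ranges(variants), intervals)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  agg <- switch(tie, older = max, younger = min, mean = mean)
  snp_div <- tapply(md[s], q, agg)
  multi <- tapply(md[s], q, function(v) length(unique(v)) > 1)
  if (any(multi)) message(sum(multi), " SNPs covered by elements with differing milli_div; tie -> ", tie)
  idx <- as.integer(names(snp_div))
  ref <- if (by == "snp") as.numeric(snp_div) else md
  rk <- rank(ref, ties.method = "average")
  qgrid <- ceiling(5 * rk / length(rk))
  quint <- if (by == "snp") qgrid else {
    # element quintile boundaries, applied to per-SNP values
    brk <- quantile(md, probs = seq(0.2, 0.8, 0.2), type = 7)
    findInterval(as.numeric(snp_div), vec = brk, left.open = TRUE) + 1L
  }
  out <- matrix(0, nrow(variants), 5, dimnames = list(NULL, paste0("age_q", 1:5)))
  for (k in 1:5) out[idx[quint == k], k] <- 1
  out
}

#' All k-mers at Hamming distance exactly one
#'
#' Enumerates the `3 * k` words over `{A,C,G,T}` differing from the query at
#' exactly one position, in deterministic lexicographic order.
#'
#' @param query A k-mer string over `{A,C,G,T}`.
#' @param distance Must be 1.
#' @return Character vector of length `3 * nchar(query)`.
#' @export
hamming_neighbors <- function(query, distance = 1L) {
  if (distance != 1L) stop("only distance 1 is supported")
  q <- strsplit(toupper(query), "")[[1]]
  if (!all(q %in% c("A", "C", "G", "T"))) stop("query must be over {A,C,G,T}")
  out <- character(0)
  for (i in seq_along(q)) for (b in c("A", "C", "G", "T")) if (b != q[i]) {
    w <- q; w[i] <- b
    out <- c(out, paste(w, collapse = ""))
  }
  sort(out)
}

#' Mismatch-tolerant k-mer footprint annotation
#'
#' Scans the genome (both strands: the query and its reverse complement are
#' matched against the forward sequence) for windows within `max_mismatch`
#' Hamming distance of the query; every matching window becomes an interval,
#' and SNPs inside the union of footprints are annotated 1. Ambiguity codes
#' in the genome count as mismatches.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences; names are chromosome names, sequence position 1 is
#'   chromosome position 1.
#' @param query The k-mer (e.g. a 9-mer from the Alu consensus).
#' @param max_mismatch 0 or 1.
#' @param variants Optional variant table; when given, the binary SNP
#'   annotation is returned alongside the intervals.
#' @return List with `intervals` (`GRanges`, 0-based half-open via
#'   [interval_set()] semantics) and `annotation` (or `NULL`).
#' @export
kmer_annotation <- function(genome, query, max_mismatch = 1L, variants = NULL) {
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  query <- toupper(query)
  if (!all(strsplit(query, "")[[1]] %in% c("A", "C", "G", "T")))
    stop("query must be over {A,C,G,T}")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named by chromosome")
  pat <- Biostrings::DNAString(query)
  rc <- Biostrings::reverseComplement(pat)
  pats <- if (as.character(rc) == query) list(pat) else list(pat, rc)
  grs <- list()
  for (chr in names(genome)) {
    subj <- genome[[chr]]
    for (p in pats) {
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch, fixed = TRUE)
      if (length(m))
        grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(
          chr, IRanges::IRanges(IRanges::start(m), IRanges::end(m)))
    }
  }
  hitsets <- if (length(grs)) GenomicRanges::reduce(do.call(c, grs)) else GenomicRanges::GRanges()
  ann <- if (!is.null(variants) && length(hitsets)) snps_in_intervals(variants, hitsets)
         else if (!is.null(variants)) numeric(nrow(variants)) else NULL
  list(intervals = hitsets, annotation = ann)
}

#' Union of chromatin (or any interval) tracks as a SNP annotation
#'
#' Unions any number of BED-style tracks (e.g. active-chromatin calls across
#' cell types and marks) and intersects the union with the SNP positions.
#'
#' @param tracks List of `GRanges` (at least one).
#' @param variants Variant table.
#' @return Numeric 0/1 vector per variant.
#' @export
chromatin_union <- function(tracks, variants) {
  if (!length(tracks)) stop("at least one track is required")
  u <- GenomicRanges::reduce(do.call(c, lapply(tracks, function(g) {
    S4Vectors::mcols(g) <- NULL; GenomicRanges::granges(g)
  })), ignore.strand = TRUE)
  snps_in_intervals(variants, u)
}

#' Restrict an annotation to uniquely mappable SNPs
#'
#' Retains annotation value 1 only at SNPs whose mappability at the SNP
#' position equals 1 (e.g. the ENCODE 35-mer track: value 1 means the 35-mer
#' at that position is unique in the genome). Positions missing from the
#' track are treated as non-unique and counted.
#'
#' @param annotation Numeric 0/1 vector per variant.
#' @param variants Variant table.
#' @param mappability `GRanges` with a numeric `score` metadata column
#'   covering the annotated chromosomes (0-based half-open input via
#'   [interval_set()] or [read_bed()] with a score column).
#' @return Numeric 0/1 vector (the `-unique` companion annotation).
#' @export
mappability_restrict <- function(annotation, variants, mappability) {
  stopifnot(length(annotation) == nrow(variants))
  sc <- S4Vectors::mcols(mappability)$score
  if (is.null(sc)) stop("mappability track needs a 'score' column")
  vr <- .variant_ranges(variants)
  hits <- GenomicRanges::findOverlaps(vr, mappability)
  val <- rep(NA_real_, nrow(variants))
  val[S4Vectors::queryHits(hits)] <- sc[S4Vectors::subjectHits(hits)]
  missing_n <- sum(annotation == 1 & is.na(val))
  if (missing_n) message(missing_n, " annotated SNPs missing from the mappability track; treated as non-unique")
  out <- annotation
  out[is.na(val) | val != 1] <- 0
  out
}

#' Size-matched random control annotation
#'
#' Places intervals with the template's exact length multiset uniformly at
#' random on the covered chromosomes and annotates SNPs inside them. The
#' draw is repeated (up to `max_tries`) until the control's %SNPs is within
#' 10% relative of the template annotation's %SNPs, mirroring the
#' size-matched random-region null used to check that enrichment estimates
#' are calibrated.
#'
#' @param variants Variant table.
#' @param template Template element `GRanges`.
#' @param seed RNG seed.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   maximum SNP position per chromosome.
#' @param max_tries Resampling cap (default 100).
#' @return Numeric 0/1 vector with the control `GRanges` in attribute
#'   `"intervals"`.
#' @export
random_control_annotation <- function(variants, template, seed,
                                      chrom_lengths = NULL, max_tries = 100L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(variants$bp, as.character(variants$chr), max)
  }
  lens <- GenomicRanges::width(template)
  chrs <- as.character(GenomeInfoDb::seqnames(template))
  target_chr <- unique(chrs)
  if (any(max(lens) > chrom_lengths[target_chr]))
    stop("a chromosome is too short for the longest template interval")
  tmpl_ann <- snps_in_intervals(variants, template)
  target_pct <- mean(tmpl_ann)
  with_substream(seed, "controls", {
    for (i in seq_len(max_tries)) {
      # keep each interval on a uniformly chosen covered chromosome that fits it
      chr_i <- vapply(lens, function(L) {
        ok <- target_chr[chrom_lengths[target_chr] >= L]
        ok[sample.int(length(ok), 1L)]
      }, character(1))
      start0 <- vapply(seq_along(lens), function(k) {
        as.integer(runif(1, 0, chrom_lengths[chr_i[k]] - lens[k] + 1))
      }, integer(1))
      ctrl <- interval_set(chr_i, start0, start0 + lens)
      ann <- snps_in_intervals(variants, ctrl)
      if (target_pct == 0 || abs(mean(ann) - target_pct) <= 0.10 * target_pct) {
        attr(ann, "intervals") <- ctrl
        return(ann)
      }
    }
    stop("could not match template %SNPs within 10% relative in ", max_tries, " tries")
  })
}

#' Assemble SNP annotations into an annotation matrix
#'
#' Container aligning annotation value vectors `a_cj` (binary or continuous)
#' to a variant table, with per-annotation metadata: source, the proportion
#' of common SNPs covered (`pct_snps`, computed over SNPs with MAF >= 0.05
#' when MAF is available, else over all SNPs), and the parent annotation for
#' flanks. Annotations smaller than 0.4% of common SNPs are tagged
#' `expected_only`: the stratified regression is unreliable for very small
#' annotations, so only model-implied (expected) enrichment should be
#' reported for them.
#'
#' @param variants Variant table.
#' @param ... Named numeric vectors or matrices of annotation values (each of
#'   length / row count `nrow(variants)`).
#' @param source Optional character, recycled per annotation.
#' @param flank_of Named character vector mapping flank-annotation names to
#'   their parents.
#' @param size_gate Fraction of common SNPs under which an annotation is
#'   tagged expected-only (default 0.004).
#' @return Object of class `annot_matrix`: list(`snps`, `values` matrix,
#'   `meta` data.frame).
#' @export
annotation_matrix <- function(variants, ..., source = NA_character_,
                              flank_of = character(0), size_gate = 0.004) {
  parts <- list(...)
  if (!length(parts)) stop("no annotations supplied")
  pn <- names(parts) %||% rep("", length(parts))
  cols <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (is.matrix(p)) {
      if (is.null(colnames(p))) stop("matrix annotations must have column names")
      for (cn in colnames(p)) cols[[cn]] <- p[, cn]
    } else {
      if (!nzchar(pn[i])) stop("vector annotations must be named")
      cols[[pn[i]]] <- as.numeric(p)
    }
  }
  vals <- do.call(cbind, cols)
  if (nrow(vals) != nrow(variants)) stop("annotation length must match the variant table")
  common <- if (!is.null(variants$maf)) variants$maf >= 0.05 else rep(TRUE, nrow(variants))
  pct <- colMeans(vals[common, , drop = FALSE] != 0)
  fo <- setNames(rep(NA_character_, ncol(vals)), colnames(vals))
  fo[names(flank_of)] <- flank_of
  if (any(!is.na(fo) & !(fo %in% colnames(vals))))
    stop("flank_of references a parent annotation that is not present")
  meta <- data.frame(
    name = colnames(vals), source = source,
    pct_snps = as.numeric(pct), flank_of = fo,
    expected_only = pct < size_gate,
    row.names = NULL, stringsAsFactors = FALSE
  )
  binary <- apply(vals, 2, function(v) all(v %in% c(0, 1)))
  structure(list(snps = variants$snp, values = vals, meta = meta, binary = binary),
            class = "annot_matrix")
}

#' @export
print.annot_matrix <- function(x, ...) {
  cat(sprintf("annot_matrix: %d SNPs x %d annotations\n", nrow(x$values), ncol(x$values)))
  print(x$meta)
  invisible(x)
}

# values matrix from an annot_matrix or plain matrix/vector
annot_values <- function(a) {
  if (inherits(a, "annot_matrix")) a$values
  else if (is.matrix(a)) a
  else matrix(as.numeric(a), ncol = 1, dimnames = list(NULL, "annot"))
}
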