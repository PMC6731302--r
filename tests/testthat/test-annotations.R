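test_that("interval membership follows the 0-based half-open / 1-based SNP convention", {
  v <- data.frame(snp = c("a", "b", "c"), chr = "1", bp = c(100L, 150L, 200L),
                  maf = 0.3, stringsAsFactors = FALSE)
  iv <- interval_set("1", 100, 200)
  # start < pos <= end: 0-based [100,200) covers 1-based 101..200
  expect_equal(snps_in_intervals(v, iv), c(0, 1, 1))
  expect_equal(snps_in_intervals(v, GenomicRanges::GRanges()), c(0, 0, 0))
  whole <- interval_set("1", 0, 10000)
  am <- annotation_matrix(v, all = snps_in_intervals(v, whole))
  expect_equal(am$meta$pct_snps, 1)
  expect_error(snps_in_intervals(v, interval_set("chr9", 1, 50)), "chr9")
  expect_error(interval_set("1", 10, 10), "start")
})

test_that("flank annotations are the set difference of widened and body intervals", {
  v <- toy_variants(30, spacing = 100L)  # positions 1, 101, ..., 2901
  v$bp <- c(400L, 700L, 900L, 1500L, 2300L, 2600L, seq(3001L, by = 100L, length.out = 24L))
  iv <- interval_set("1", 1000, 2000)
  fl <- flank_annotation(v, iv, width = 500)
  # flank = 0-based [500,1000) u [2000,2500) = 1-based 501..1000 u 2001..2500
  expect_equal(fl[1:6], c(0, 1, 1, 0, 1, 0))
  expect_error(flank_annotation(v, iv, width = 0), "width")
  # elements closer than 2 x width: flank still excludes both bodies
  iv2 <- interval_set(c("1", "1"), c(1000, 2400), c(2000, 3000))
  fl2 <- flank_annotation(v, iv2, width = 500)
  pos <- function(p) which(v$bp == p)
  expect_equal(fl2[pos(1500)], 0)  # inside first body
  expect_equal(fl2[pos(2600)], 0)  # inside second body
  expect_equal(fl2[pos(2300)], 1)  # in the gap, flank of both
  expect_equal(fl2[pos(3001)], 1)  # downstream flank of the second element
})

test_that("age quintiles slice the per-SNP milliDiv distribution into disjoint fifths", {
  v <- toy_variants(100, spacing = 1000L)
  iv <- interval_set("1", v$bp - 1, v$bp, milli_div = 1:100)
  q <- age_quintile_annotations(v, iv)
  expect_equal(which(q[, "age_q1"] == 1), 1:20)
  expect_equal(which(q[, "age_q5"] == 1), 81:100)
  expect_true(all(rowSums(q) <= 1))              # disjoint
  expect_equal(rowSums(q), snps_in_intervals(v, iv))  # partition of the dated set
  # all elements share one value -> a single occupied quintile
  iv2 <- interval_set("1", v$bp - 1, v$bp, milli_div = rep(7, 100))
  q2 <- age_quintile_annotations(v, iv2)
  expect_equal(sum(colSums(q2) > 0), 1L)
  # overlap tie -> older element wins
  v3 <- toy_variants(1); v3$bp <- 50L
  iv3 <- interval_set(c("1", "1"), c(0, 10), c(100, 90), milli_div = c(5, 50))
  expect_message(q3 <- age_quintile_annotations(v3, iv3), "differing milli_div")
  expect_error(age_quintile_annotations(v3, interval_set("1", 0, 100)), "milli_div")
})

test_that("hamming_neighbors enumerates exactly the distance-1 words", {
  nb <- hamming_neighbors("GCGGTGGCT")
  expect_length(nb, 27)
  expect_false(any(duplicated(nb)))
  expect_equal(hamming_neighbors("A"), c("C", "G", "T"))
  dist1 <- vapply(nb, function(w)
    sum(strsplit(w, "")[[1]] != strsplit("GCGGTGGCT", "")[[1]]), numeric(1))
  expect_true(all(dist1 == 1))
  expect_equal(nb, sort(nb))
  expect_true("GTGGTGGCT" %in% nb)
})

test_that("kmer_annotation finds mismatch-tolerant hits on both strands", {
  g <- c(chrA = "GCGGTGGCT")
  hit <- kmer_annotation(g, "GCGGTGGCT", max_mismatch = 0)
  expect_length(hit$intervals, 1)
  expect_equal(IRanges::width(hit$intervals), 9)
  # GTGGTGGCT is a 1-mismatch neighbor of GCGGTGGCT
  g2 <- c(chrA = "AAAAGTGGTGGCTAAAA")
  expect_length(kmer_annotation(g2, "GCGGTGGCT", max_mismatch = 0)$intervals, 0)
  expect_length(kmer_annotation(g2, "GCGGTGGCT", max_mismatch = 1)$intervals, 1)
  # reverse-complement hits count
  g3 <- c(chrA = paste0("TTTT", "AGCCACCGC", "TTTT"))  # revcomp of GCGGTGGCT
  expect_length(kmer_annotation(g3, "GCGGTGGCT", max_mismatch = 0)$intervals, 1)
})

test_that("kmer_annotation agrees with a naive full scan on random sequence", {
  for (seed in c(101, 202)) {
    seqs <- with_seed(seed, Biostrings::DNAStringSet(setNames(
      paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = ""), "chrR")))
    q <- with_seed(seed + 1, paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = ""))
    res <- kmer_annotation(seqs, q, max_mismatch = 1)
    oracle <- naive_kmer_scan(seqs, q, 1)
    got <- sort(IRanges::start(res$intervals))
    # oracle reports window starts; implementation reports merged footprints:
    # every oracle hit must be covered, and footprint bases = union of oracle windows
    cov_impl <- sort(unique(unlist(lapply(seq_along(res$intervals), function(i)
      seq(IRanges::start(res$intervals)[i], IRanges::end(res$intervals)[i])))))
    cov_oracle <- sort(unique(unlist(lapply(oracle$start1, function(s) seq(s, s + 4)))))
    expect_equal(cov_impl, cov_oracle)
  }
})

test_that("chromatin_union behaves as interval-set algebra", {
  v <- toy_variants(50, spacing = 100L)
  t1 <- interval_set("1", 0, 1000)
  t2 <- interval_set("1", 2000, 3000)
  nested <- interval_set("1", 200, 800)
  expect_equal(chromatin_union(list(t1), v), snps_in_intervals(v, t1))
  u <- chromatin_union(list(t1, t2), v)
  expect_equal(mean(u), mean(snps_in_intervals(v, t1)) + mean(snps_in_intervals(v, t2)))
  expect_equal(chromatin_union(list(t1, nested), v), snps_in_intervals(v, t1))
  expect_error(chromatin_union(list(), v), "at least one")
})

test_that("mappability restriction keeps only uniquely mappable SNPs", {
  v <- toy_variants(10, spacing = 100L)
  ann <- rep(1, 10)
  all1 <- interval_set("1", 0, 2000); S4Vectors::mcols(all1)$score <- 1
  expect_equal(mappability_restrict(ann, v, all1), ann)
  all0 <- all1; S4Vectors::mcols(all0)$score <- 0
  expect_equal(mappability_restrict(ann, v, all0), rep(0, 10))
  # mixed track: unique only over the first 5 SNPs (positions 1..401)
  mixed <- interval_set(c("1", "1"), c(0, 450), c(450, 2000))
  S4Vectors::mcols(mixed)$score <- c(1, 0)
  expect_equal(mappability_restrict(ann, v, mixed), c(rep(1, 5), rep(0, 5)))
  # position missing from the track -> non-unique, message
  part <- interval_set("1", 0, 450); S4Vectors::mcols(part)$score <- 1
  expect_message(out <- mappability_restrict(ann, v, part), "missing")
  expect_equal(out, c(rep(1, 5), rep(0, 5)))
})

test_that("random controls match the template's length multiset and %SNPs", {
  v <- toy_variants(1000, spacing = 1000L)
  tmpl <- interval_set(rep("1", 10), seq(0, by = 50000, length.out = 10),
                       seq(0, by = 50000, length.out = 10) + c(rep(10000, 5), rep(20000, 5)))
  ctrl <- random_control_annotation(v, tmpl, seed = 7)
  ivs <- attr(ctrl, "intervals")
  expect_equal(sort(GenomicRanges::width(ivs)), sort(GenomicRanges::width(tmpl)))
  pct_t <- mean(snps_in_intervals(v, tmpl))
  expect_lte(abs(mean(ctrl) - pct_t), 0.10 * pct_t)
  expect_identical(ctrl, random_control_annotation(v, tmpl, seed = 7))
  # chromosome shorter than the longest template interval
  huge <- interval_set("1", 0, 5e6)
  expect_error(random_control_annotation(v, huge, seed = 1), "too short")
})

test_that("annotation matrix metadata: union bounds, size gate and flank registration", {
  v <- toy_variants(1000)
  a <- with_seed(41, as.numeric(runif(1000) < 0.2))
  b <- with_seed(42, as.numeric(runif(1000) < 0.3))
  uni <- as.numeric(a | b)
  am <- annotation_matrix(v, A = a, B = b, ALL = uni, tiny = c(1, rep(0, 999)),
                          fl = as.numeric(runif(1000) < 0.1),
                          flank_of = c(fl = "A"))
  pct <- setNames(am$meta$pct_snps, am$meta$name)
  expect_gte(pct["ALL"], max(pct["A"], pct["B"]))
  expect_lte(pct["ALL"], pct["A"] + pct["B"])
  expect_true(am$meta$expected_only[am$meta$name == "tiny"])
  expect_false(any(am$meta$expected_only[am$meta$name %in% c("A", "B")]))
  expect_equal(am$meta$flank_of[am$meta$name == "fl"], "A")
  expect_error(annotation_matrix(v, A = a, fl = b, flank_of = c(fl = "missing")),
               "parent")
})
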