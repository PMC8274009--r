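test_that("align_sequence matches brute-force local alignment", {
  ref <- rand_ref(8000L, seed = 11L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -4)
  for (s in 1:5) {
    set.seed(100 + s)
    o <- sample(1000:6000, 1)
    q <- substr(ref[["chr1"]], o, o + 59)
    if (s > 2) {  # inject one mismatch
      p <- sample(10:50, 1)
      substr(q, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, p, p))[1]
    }
    hits <- align_sequence(q, ref)
    oracle <- Biostrings::pairwiseAlignment(
      q, ref[["chr1"]], type = "local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(hits$score[1], oracle)
  }
})

test_that("uniqueness determines effective mapq", {
  ref <- rand_ref(4000L, seed = 2L)
  q <- substr(ref[["chr1"]], 1001, 1060)
  h <- align_sequence(q, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$mapq, 60L)
  expect_equal(h$qstart, 1L); expect_equal(h$qend, 60L)
  # duplicated locus: identical best scores -> mapq 0
  ref2 <- c(chr1 = paste0(ref[["chr1"]], q))
  h2 <- align_sequence(q, ref2)
  expect_true(all(h2$mapq == 0L))
})

test_that("compound realignment resolves multi-part contigs", {
  ref <- rand_ref(10000L, seed = 21L)
  A <- substr(ref[["chr1"]], 2001, 2150)
  B <- substr(ref[["chr1"]], 7001, 7150)
  origin <- list(chrom = "chr1", start = 2001L, end = 2150L)
  ch <- compound_realign(paste0(A, B), origin, ref)
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$rstart, c(2001L, 7001L))
  # 25 bp novel sequence between the parts stays unaligned (insert)
  set.seed(5); novel <- svkit:::random_dna(25)
  ch2 <- compound_realign(paste0(A, novel, B), origin, ref)
  expect_equal(nrow(ch2), 2L)
  expect_equal(ch2$qend[1], 150L)
  expect_equal(ch2$qstart[2], 176L)
  # contig not overlapping its origin locus is discarded
  expect_null(compound_realign(paste0(A, B),
                               list(chrom = "chr1", start = 9000L,
                                    end = 9100L), ref))
})

test_that("split-bound adjustment minimises edit distance, leftmost ties", {
  # junction with perfect 3 bp microhomology: B's start repeats A's tail
  set.seed(77)
  left <- svkit:::random_dna(150)
  hom <- "GCA"
  right <- svkit:::random_dna(150)
  refseq <- paste0(left, hom, svkit:::random_dna(200), hom, right)
  ref <- c(chr1 = refseq)
  # derivative joins left+hom directly to hom+right (deletion-like)
  contig <- paste0(left, hom, right)
  origin <- list(chrom = "chr1", start = 1L, end = 153L)
  ch <- compound_realign(contig, origin, ref)
  ch <- adjust_split_bounds(ch, contig, ref)
  expect_equal(nrow(ch), 2L)
  # oracle: evaluate total mismatches at every candidate split point; the
  # B part always ends at reference position 506
  splits <- 147:156
  cost <- vapply(splits, function(sp) {
    blen <- 303L - sp
    svkit:::hamming(substr(contig, 1, sp), substr(refseq, 1, sp)) +
      svkit:::hamming(substr(contig, sp + 1, 303),
                      substr(refseq, 507 - blen, 506))
  }, 1)
  best <- splits[which(cost == min(cost))]
  expect_equal(ch$qend[1], min(best))  # leftmost among ties
  # adjustment never increases the total mismatch count
  expect_lte(cost[splits == ch$qend[1]], cost[splits == 153])
})

test_that("exact homology matches placement enumeration", {
  # deletion inside a sequence with 3 bp of junction homology: enumerate
  # all equal-length deletions producing an identical alternate sequence
  ref <- c(chr1 = "TTTTGATCCCCGATAAAA")
  del_len <- 7L
  alt_of <- function(s) paste0(substr(ref[["chr1"]], 1, s - 1),
                               substr(ref[["chr1"]], s + del_len, 18))
  base_alt <- alt_of(8L)   # delete bases 8..14
  same <- vapply(2:11, function(s) alt_of(s) == base_alt, TRUE)
  n_equiv <- sum(same)
  h <- exact_homology("chr1", 7L, "HEAD", "chr1", 15L, "TAIL", ref)
  expect_equal(h$homlen, n_equiv - 1L)
  expect_equal(h$homlen, 3L)
  s_min <- (2:11)[which(same)[1]]
  expect_equal(h$pos1, s_min - 1L)   # leftmost placement (delete 5..11)
  expect_equal(h$pos2, s_min + 7L)
  expect_equal(h$cipos, c(0L, 3L))
  expect_equal(h$cirpos, c(0L, 3L))
  # blunt junction between unrelated chromosomes
  r2 <- rand_ref(500L, seed = 31L, chroms = c("chrA", "chrB"))
  hb <- exact_homology("chrA", 250L, "HEAD", "chrB", 250L, "TAIL", r2)
  expect_equal(hb$homlen, 0L)
  expect_equal(hb$cipos, c(0L, 0L))
  # non-template insert suppresses homology
  hi <- exact_homology("chr1", 7L, "HEAD", "chr1", 15L, "TAIL", ref,
                       insert_len = 2L)
  expect_equal(hi$homlen, 0L)
})

test_that("tandem duplication junction inside a repeat has its length as homology", {
  set.seed(41)
  L <- 6L
  m <- svkit:::random_dna(L)
  # motif at a..a+5 and again at b+1..b+6: the duplication junction
  # (b HEAD) -> (a TAIL) can slide across the whole motif
  a <- 201L; b <- 399L
  refseq <- paste0(svkit:::random_dna(a - 1L), m,
                   svkit:::random_dna(b - (a + L) + 1L), m,
                   svkit:::random_dna(200L))
  ref <- c(chr1 = refseq)
  h <- exact_homology("chr1", b, "HEAD", "chr1", a, "TAIL", ref)
  expect_gte(h$homlen, L)
})

test_that("exact homology is symmetric across breakends", {
  ref <- rand_ref(2000L, seed = 15L)
  # 300 bp deletion
  h1 <- exact_homology("chr1", 800L, "HEAD", "chr1", 1101L, "TAIL", ref)
  # same junction described from the partner end (flipped roles)
  h2 <- exact_homology("chr1", 1101L, "TAIL", "chr1", 800L, "HEAD", ref)
  expect_equal(h1$homlen, h2$homlen)
  expect_equal(h1$cipos[2] - h1$cipos[1], h2$cipos[2] - h2$cipos[1])
  expect_error(exact_homology("chrX", 1L, "HEAD", "chr1", 2L, "TAIL", ref),
               "outside reference")
})

test_that("inexact homology covers exact homology and scores by SW", {
  # engineered 5 bp exact homology
  set.seed(51)
  hom <- "ACGTC"
  a <- svkit:::random_dna(400); b <- svkit:::random_dna(400)
  refseq <- paste0(a, hom, svkit:::random_dna(295), hom, b)
  ref <- c(chr1 = refseq)
  p1 <- 405L          # X ends with hom at 401..405
  p2 <- 706L          # Y starts at b; ref[701..705] is hom again
  ih <- inexact_homology("chr1", p1, "HEAD", "chr1", p2, "TAIL", ref)
  expect_gte(ih[2] - ih[1], 5L)
  # random unrelated flanks: near-zero inexact homology across seeds
  widths <- vapply(1:20, function(s) {
    r <- rand_ref(1500L, seed = 200L + s)
    ih <- inexact_homology("chr1", 400L, "HEAD", "chr1", 1100L, "TAIL", r)
    ih[2] - ih[1]
  }, 1L)
  expect_lte(median(widths), 2L)
  expect_lte(max(widths), 10L)
})

test_that("SW extension stops where cumulative score goes negative", {
  # partner flank matches the reference continuation for 4 bp, then
  # mismatches: under (1, -4) scoring the alignment ends at 4 matches
  set.seed(61)
  X <- svkit:::random_dna(300)
  contA <- svkit:::random_dna(200)      # reference continuation past X
  # partner side Y: first 4 bases equal contA, 5th differs, rest unrelated
  y5 <- setdiff(c("A", "C", "G", "T"), substr(contA, 5, 5))[1]
  Y <- paste0(substr(contA, 1, 4), y5, svkit:::random_dna(295))
  refseq <- paste0(X, contA, strrep("T", 5), Y, svkit:::random_dna(100))
  ref <- c(chr1 = refseq)
  p1 <- 300L                       # X | contA boundary
  p2 <- 300L + 200L + 5L + 1L      # start of Y
  ih <- inexact_homology("chr1", p1, "HEAD", "chr1", p2, "TAIL", ref)
  expect_equal(ih[2], 4L)
})

test_that("inexact homology contains the exact interval on random junctions", {
  for (s in 1:8) {
    r <- rand_ref(3000L, seed = 300L + s)
    p1 <- 1000L + s * 37L
    p2 <- p1 + 501L
    h <- exact_homology("chr1", p1, "HEAD", "chr1", p2, "TAIL", r)
    ih <- inexact_homology("chr1", h$pos1, "HEAD", "chr1", h$pos2, "TAIL", r)
    expect_gte(ih[2] - ih[1], h$cipos[2] - h$cipos[1])
    expect_lte(ih[1], h$cipos[1])
    expect_gte(ih[2], h$cipos[2])
  }
})
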