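test_that("fragment-size bounds are the central 99.5% quantiles", {
  # degenerate distribution
  rd <- rbindlist(lapply(1:200, function(i)
    make_pair(paste0("p", i), pos1 = 100L + i, pos2 = 300L + i,
              tlen = 300L)))
  m <- estimate_library_metrics(rd)
  expect_equal(m$concordant_lo, 300L)
  expect_equal(m$concordant_hi, 300L)

  # uniform template lengths: oracle = direct sorting with ceiling indexing
  set.seed(42)
  tl <- sample(200:599, 4000, replace = TRUE)
  rd <- rbindlist(lapply(seq_along(tl), function(i)
    make_pair(paste0("q", i), pos1 = 1000L, pos2 = 1000L + tl[i] - 100L,
              tlen = tl[i])))
  m <- estimate_library_metrics(rd)
  srt <- sort(tl)
  expect_equal(m$concordant_lo, srt[ceiling(0.0025 * length(srt))])
  expect_equal(m$concordant_hi, srt[ceiling(0.9975 * length(srt))])
  expect_equal(sum(m$fragment_size_hist), 1)

  # no proper pairs
  bad <- make_read(proper = FALSE, tlen = 0L)
  expect_error(estimate_library_metrics(bad), "fragment distribution")
})

test_that("sequence entropy matches direct evaluation", {
  expect_equal(sequence_entropy("AAAAAAAA"), 0)
  expect_equal(sequence_entropy("ACGTACGT"), 2)
  expect_equal(sequence_entropy("AACC"), 1)
  expect_error(sequence_entropy(""))
})

test_that("adapter clip detection is end-anchored with overlap floor", {
  ad <- default_adapters()
  expect_true(is_adapter_clip(substr(ad[[1]], 1, 20), ad))
  # random sequence far from any adapter prefix
  expect_false(is_adapter_clip("TTTTTTTTTTGGGGGGGGGG", ad))
  # below the overlap floor
  expect_false(is_adapter_clip(substr(ad[[1]], 1, 5), ad, min_overlap = 12L))
})

test_that("read classification applies the admission thresholds", {
  m <- make_metrics()
  seq96 <- strrep("ACGT", 24)
  # 4 bp clip: reference-consistent
  r4 <- make_read(cigar = "96M4S", seq = strrep("ACGT", 25))
  expect_equal(nrow(classify_reads(rbind(r4, make_read(qname = "r1",
    flag = 147L, pos = 300L, strand = "-")), m)[kind == "SOFT_CLIP"]), 0L)
  # 5 bp clip admitted, HEAD side at the last aligned base
  r5 <- make_read(cigar = "95M5S", seq = paste0(strrep("ACGT", 23), "AAA",
                                                "GATCC"))
  ev <- classify_reads(rbind(r5, make_read(qname = "r1", flag = 147L,
    pos = 300L, strand = "-")), m)
  sc <- ev[kind == "SOFT_CLIP"]
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$dir1, "HEAD")
  expect_equal(sc$start1, 100L + 95L - 1L)
  expect_equal(sc$seq, "GATCC")
  # indels under 5 bp are reference-consistent
  rd4 <- make_read(cigar = "50M4D50M")
  rd5 <- make_read(cigar = "50M5D50M")
  mate <- make_read(qname = "r1", flag = 147L, pos = 300L, strand = "-")
  expect_equal(nrow(classify_reads(rbind(rd4, mate), m)[kind == "INDEL"]), 0L)
  idl <- classify_reads(rbind(rd5, mate), m)[kind == "INDEL"]
  expect_equal(nrow(idl), 1L)
  expect_equal(idl$start1, 149L)   # last M base before the gap
  expect_equal(idl$start2, 155L)   # first M base after the gap
  # mapq below 20 is treated as unmapped: mapped mate gains UNMAPPED_MATE
  lowq <- make_read(qname = "z", mapq = 19L, cigar = "100M")
  partner <- make_read(qname = "z", flag = 147L, pos = 300L, strand = "-",
                       mate_mapq = 19L)
  ev <- classify_reads(rbind(lowq, partner), m)
  expect_equal(nrow(ev[kind == "UNMAPPED_MATE"]), 1L)
  expect_equal(ev[kind == "UNMAPPED_MATE", fragment_id], "z")
  expect_equal(nrow(ev[fragment_id == "z" & kind == "SOFT_CLIP"]), 0L)
})

test_that("classification is deterministic and idempotent", {
  m <- make_metrics()
  rd <- rbind(make_read(cigar = "90M10S",
                        seq = paste0(strrep("ACGT", 22), "AT",
                                     "GGATCCGGAT")),
              make_read(qname = "r1", flag = 147L, pos = 300L,
                        strand = "-"))
  e1 <- classify_reads(rd, m)
  e2 <- classify_reads(rd, m)
  expect_identical(e1, e2)
})

test_that("high-coverage positions are excluded from evidence", {
  m <- make_metrics()
  # 30 stacked reads at one locus
  rd <- rbindlist(lapply(1:30, function(i)
    make_pair(paste0("s", i), pos1 = 1000L, pos2 = 1200L, tlen = 300L,
              cigar1 = "95M5S")))
  ev <- classify_reads(rd, m)
  expect_gt(nrow(ev), 0L)
  kept <- exclude_high_coverage(ev, rd, threshold = 50000L)
  expect_equal(nrow(kept), nrow(ev))
  expect_message(dropped <- exclude_high_coverage(ev, rd, threshold = 10L),
                 "dropped")
  expect_equal(nrow(dropped), 0L)
})

test_that("unique soft clips are realigned into split reads", {
  ref <- rand_ref(4000L, seed = 3L)
  clip <- substr(ref[["chr1"]], 3001, 3030)
  anchored <- substr(ref[["chr1"]], 501, 570)
  m <- make_metrics()
  rd <- rbind(
    make_read(qname = "u", pos = 501L, cigar = "70M30S",
              seq = paste0(anchored, clip)),
    make_read(qname = "u", flag = 147L, pos = 700L, strand = "-",
              seq = strrep("ACGT", 25)))
  ev <- classify_reads(rd, m)
  out <- realign_soft_clips(ev, ref)
  sr <- out[kind == "SPLIT_READ"]
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$chrom2, "chr1")
  expect_equal(sr$start2, 3001L)   # TAIL breakend at the clip's alignment
  expect_equal(sr$dir2, "TAIL")
  # ambiguous clip (present at many loci) stays a soft clip
  rep5 <- paste(rep(substr(ref[["chr1"]], 101, 130), 5), collapse = "")
  ref2 <- c(chr1 = paste0(ref[["chr1"]], rep5))
  rda <- rbind(
    make_read(qname = "a", pos = 501L, cigar = "70M30S",
              seq = paste0(anchored, substr(ref[["chr1"]], 101, 130))),
    make_read(qname = "a", flag = 147L, pos = 700L, strand = "-",
              seq = strrep("ACGT", 25)))
  eva <- classify_reads(rda, m)
  outa <- realign_soft_clips(eva, ref2)
  expect_equal(outa[fragment_id == "a" & nchar(seq) == 30L, kind],
               "SOFT_CLIP")
})

test_that("concordant libraries yield at most ~0.5% discordant pairs", {
  g <- synth_genome(c(chr1 = 30000L), seed = 12)
  sim <- simulate_sv_reads(sim_config(
    g, sv_table(character(0), character(0), integer(0))[0],
    cov_tumour = 20, cov_normal = 10, seed = 5))
  m <- estimate_library_metrics(sim$tumour)
  ev <- classify_reads(sim$tumour, m)
  n_pairs <- length(unique(sim$tumour$qname))
  frac <- nrow(ev[kind == "DISCORDANT_PAIR"]) / n_pairs
  # quantile construction leaves ~0.5% outside the bounds + binomial noise
  expect_lt(frac, 0.005 + 3 * sqrt(0.005 / n_pairs))
})
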