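test_that("normal-support hard filter triggers at exactly 3%", {
  expect_equal(hard_filter(make_call(t_vf = 32L, n_vf = 1L)),
               "normalSupport")                       # 1/33 = 3.03%
  expect_length(hard_filter(make_call(t_vf = 40L, n_vf = 1L)), 0L)  # 2.4%
  # short deletion with any direct split read support in the normal
  expect_true("normalSplitRead" %in% hard_filter(
    make_call(t_vf = 100L, n_vf = 0L, svtype = "DEL", size = 800L,
              n_sr = 1L)))
  expect_length(hard_filter(
    make_call(t_vf = 100L, n_vf = 0L, svtype = "DEL", size = 1200L,
              n_sr = 1L)), 0L)
})

test_that("each low-confidence rule fires at its printed threshold", {
  lc <- function(...) classify_confidence(make_call(...))
  # imprecise
  expect_true("imprecise" %in% lc(imprecise = TRUE))
  # normal breakend coverage < 8 fragments
  expect_true("normalCoverage" %in% lc(n_vf = 0L, n_ref = 5L,
                                       n_refpair = 2L))
  expect_false("normalCoverage" %in% lc(n_vf = 0L, n_ref = 5L,
                                        n_refpair = 3L))
  # tumour allele fraction < 0.5%
  expect_true("lowAF" %in% lc(t_vf = 1L, t_ref = 200L, t_refpair = 51L))
  expect_false("lowAF" %in% lc(t_vf = 1L, t_ref = 150L, t_refpair = 49L))
  # single breakend without a discordant-pair-containing assembly
  expect_true("noAssemblyRP" %in% classify_confidence(
    make_be_call(t_basrp = 0L)))
  expect_false("noAssemblyRP" %in% classify_confidence(
    make_be_call(t_basrp = 1L)))
  # poly-C/G run of at least 16 bp in the breakend sequence
  expect_true("polyGC" %in% classify_confidence(
    make_be_call(breakend_seq = paste0("ACGT", strrep("G", 16), "ACGT"))))
  expect_false("polyGC" %in% classify_confidence(
    make_be_call(breakend_seq = paste0("ACGT", strrep("G", 15), "ACGT"))))
  # short del/dup split-read strand bias >= 0.95 (both poles)
  expect_true("strandBias" %in% lc(svtype = "DEL", size = 500L, sb = 0.96))
  expect_true("strandBias" %in% lc(svtype = "DEL", size = 500L, sb = 0.95))
  expect_false("strandBias" %in% lc(svtype = "DEL", size = 500L, sb = 0.94))
  expect_false("strandBias" %in% lc(svtype = "DEL", size = 1500L,
                                    sb = 0.99))
  # microhomology over 50 bp
  expect_true("homologyLength" %in% lc(homlen = 51L))
  expect_false("homologyLength" %in% lc(homlen = 50L))
  # inexact homology over 50 bp, exempting short del/dup
  expect_true("inexactHomology" %in% lc(svtype = "CTX", size = NA_integer_,
                                        chrom2 = "chr2",
                                        ihompos_lo = -30L, ihompos_hi = 21L))
  expect_false("inexactHomology" %in% lc(svtype = "DEL", size = 500L,
                                         ihompos_lo = -30L,
                                         ihompos_hi = 21L))
  # short del/dup with no split-read support (direct or assembled)
  expect_true("shortNoSplitRead" %in% lc(svtype = "DUP", size = 500L,
                                         t_sr = 0L, t_assr = 0L))
  expect_false("shortNoSplitRead" %in% lc(svtype = "DUP", size = 500L,
                                          t_sr = 0L, t_assr = 3L))
  # non-short breakpoints need discordant-pair support
  expect_true("noDiscordantPair" %in% lc(svtype = "DEL", size = 5000L,
                                         t_rp = 0L, t_asrp = 0L))
  expect_false("noDiscordantPair" %in% lc(svtype = "DEL", size = 500L,
                                          t_rp = 0L, t_asrp = 0L))
  # 100-800 bp deletions with inexact homology >= 6 bp
  expect_true("shortDelInexactHomology" %in% lc(
    svtype = "DEL", size = 300L, ihompos_lo = 0L, ihompos_hi = 6L))
  expect_false("shortDelInexactHomology" %in% lc(
    svtype = "DEL", size = 300L, ihompos_lo = 0L, ihompos_hi = 5L))
  expect_false("shortDelInexactHomology" %in% lc(
    svtype = "DEL", size = 900L, ihompos_lo = 0L, ihompos_hi = 6L))
  # inversion-like breakpoints <= 40 bp with >= 6 bp microhomology
  expect_true("shortInversionHomology" %in% lc(
    svtype = "INV", dir2 = "HEAD", size = 40L, homlen = 6L))
  expect_false("shortInversionHomology" %in% lc(
    svtype = "INV", dir2 = "HEAD", size = 41L, homlen = 6L))
  expect_false("shortInversionHomology" %in% lc(
    svtype = "INV", dir2 = "HEAD", size = 40L, homlen = 5L))
})

test_that("pseudo-deletion insert rule respects the edit-distance exemption", {
  ref <- rand_ref(2000L, seed = 44L)
  delseq <- substr(ref[["chr1"]], 1001, 1100)   # deleted bases (100 bp)
  base <- function(ins) make_call(svtype = "INS", pos1 = 1000L,
                                  pos2 = 1101L, size = nchar(ins),
                                  insert = ins)
  # insert length within 5 bp of deletion length and similar sequence
  r <- classify_confidence(base(substr(delseq, 1, 98)), reference = ref)
  expect_true("pseudoDeletion" %in% r)
  # the retro-style exemption: insert far from the deleted bases but close
  # to their reverse complement
  rc <- revcomp(delseq)
  r2 <- classify_confidence(base(rc), reference = ref)
  expect_false("pseudoDeletion" %in% r2)
  # insert length differing by more than 5 bp: rule does not apply
  r3 <- classify_confidence(base(substr(delseq, 1, 90)), reference = ref)
  expect_false("pseudoDeletion" %in% r3)
})

test_that("panel of normals aggregation honours quality thresholds", {
  ncalls <- rbind(
    make_call(id = "a", qual = 74, pos1 = 100L, pos2 = 500L),
    make_call(id = "b", qual = 75, pos1 = 1000L, pos2 = 1500L),
    make_call(id = "c", qual = 500, pos1 = 2000L, pos2 = 2500L,
              imprecise = TRUE),
    make_be_call(id = "d", qual = 428, pos1 = 3000L),
    make_be_call(id = "e", qual = 427, pos1 = 4000L))
  pon <- build_pon(list(ncalls))
  expect_equal(pon$bp$pos1, 1000L)      # QUAL 74 and imprecise excluded
  expect_equal(pon$be$pos1, 3000L)      # 428 in, 427 out
})

test_that("PON matching is within 2 bp with matching orientation", {
  pon <- build_pon(list(make_call(id = "p", qual = 100, pos1 = 1000001L,
                                  pos2 = 1200000L)))
  expect_true(pon_filter(make_call(pos1 = 1000003L, pos2 = 1200001L), pon))
  expect_false(pon_filter(make_call(pos1 = 1000004L, pos2 = 1200001L), pon))
  expect_false(pon_filter(make_call(pos1 = 1000003L, pos2 = 1200001L,
                                    dir1 = "TAIL", dir2 = "HEAD"), pon))
  # one matching breakend only: kept
  expect_false(pon_filter(make_call(pos1 = 1000003L, pos2 = 1250000L), pon))
})

test_that("simple-event annotations follow the geometric predicates", {
  # equivalent single breakends: within 5 bp, matching sequences
  s <- strrep("ACGGT", 6)
  eq <- annotate_events(rbind(
    make_be_call(id = "u", pos1 = 1000L, breakend_seq = s),
    make_be_call(id = "v", pos1 = 1003L, breakend_seq = s)))
  expect_true("EQUIVALENT" %in% eq$kind)
  eq2 <- annotate_events(rbind(
    make_be_call(id = "u", pos1 = 1000L, breakend_seq = s),
    make_be_call(id = "v", pos1 = 1006L, breakend_seq = s)))
  expect_false("EQUIVALENT" %in% eq2$kind)
  # simple inversion: INV-like pair within 35 bp, support ratio <= 3
  inv_pair <- function(vf2) rbind(
    make_call(id = "i1", svtype = "INV", dir1 = "HEAD", dir2 = "HEAD",
              pos1 = 9999L, pos2 = 15000L, t_vf = 10L),
    make_call(id = "i2", svtype = "INV", dir1 = "TAIL", dir2 = "TAIL",
              pos1 = 10000L, pos2 = 15001L, t_vf = vf2))
  expect_true("SIMPLE_INVERSION" %in% annotate_events(inv_pair(29L))$kind)
  expect_false("SIMPLE_INVERSION" %in% annotate_events(inv_pair(31L))$kind)
  # reciprocal translocation: interchromosomal, opposite orientations
  rt <- rbind(
    make_call(id = "t1", svtype = "CTX", chrom2 = "chr2", dir1 = "HEAD",
              dir2 = "TAIL", size = NA_integer_),
    make_call(id = "t2", svtype = "CTX", chrom2 = "chr2", dir1 = "TAIL",
              dir2 = "HEAD", pos1 = 10005L, pos2 = 15003L,
              size = NA_integer_))
  expect_true("RECIPROCAL_TRANSLOCATION" %in% annotate_events(rt)$kind)
  # templated insertion: intrachromosomal opposite-orientation pair
  ti <- rbind(
    make_call(id = "a", svtype = "DEL", dir1 = "HEAD", dir2 = "TAIL"),
    make_call(id = "b", svtype = "DUP", dir1 = "TAIL", dir2 = "HEAD",
              pos1 = 10010L, pos2 = 15010L))
  expect_true("TEMPLATED_INSERTION" %in% annotate_events(ti)$kind)
})

test_that("quality filter rescues linked calls but never via equivalence", {
  calls <- rbind(make_call(id = "lo", qual = 349),
                 make_call(id = "hi", qual = 400, pos1 = 12000L,
                           pos2 = 17000L),
                 make_be_call(id = "be", qual = 999, pos1 = 30000L))
  st <- rep("PASS", 3L)
  # unlinked: 349 < 350 fails, 400 passes, BE 999 < 1000 fails
  q0 <- quality_filter_with_rescue(calls, svkit:::empty_links(), st)
  expect_equal(q0, c(FALSE, TRUE, FALSE))
  # assembly link to the passing call rescues
  l1 <- data.table(link_id = "L1", kind = "ASSEMBLY_CIS", id1 = "hi",
                   id2 = "lo", provenance = "asm")
  expect_equal(quality_filter_with_rescue(calls, l1, st),
               c(TRUE, TRUE, FALSE))
  # equivalence links never rescue
  l2 <- data.table(link_id = "L2", kind = "EQUIVALENT", id1 = "hi",
                   id2 = "be", provenance = "eq")
  expect_equal(quality_filter_with_rescue(calls, l2, st),
               c(FALSE, TRUE, FALSE))
  # rescue closes transitively over the link graph
  calls4 <- rbind(calls,
                  make_call(id = "lo2", qual = 100, pos1 = 40000L,
                            pos2 = 45000L))
  l3 <- rbind(l1, data.table(link_id = "L3", kind = "TRANSITIVE",
                             id1 = "lo", id2 = "lo2", provenance = "x"))
  expect_equal(quality_filter_with_rescue(calls4, l3, rep("PASS", 4L)),
               c(TRUE, TRUE, FALSE, TRUE))
})

test_that("filter results are order-invariant pure predicates", {
  calls <- rbind(make_call(id = "a", qual = 1500),
                 make_call(id = "b", qual = 349, pos1 = 30000L,
                           pos2 = 36000L),
                 make_call(id = "c", t_vf = 10L, n_vf = 5L, pos1 = 50000L,
                           pos2 = 56000L))
  f1 <- somatic_filter(calls)
  f2 <- somatic_filter(calls[c(3, 1, 2)])
  m <- merge(f1[, .(id, filter_status)],
             f2[, .(id, st2 = filter_status)], by = "id")
  expect_equal(m$filter_status, m$st2)
})

test_that("output sets follow the two-file contract", {
  calls <- rbind(make_call(id = "pass", qual = 1500),
                 make_call(id = "lowaf", qual = 1500, pos1 = 30000L,
                           pos2 = 36000L, t_vf = 1L, t_ref = 300L,
                           t_refpair = 0L),
                 make_call(id = "germ", qual = 1500, pos1 = 50000L,
                           pos2 = 56000L, t_vf = 10L, n_vf = 10L))
  f <- somatic_filter(calls)
  sets <- emit_call_sets(f)
  expect_equal(sets$high$id, "pass")
  expect_setequal(sets$low$id, c("pass", "lowaf"))   # hard-filtered absent
})
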