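test_that("evidence quality combines empirical rates with mapq caps", {
  m <- make_metrics(n_mapped = 100000L,
                    cigar_rates = data.table(op = "S", len = 20L,
                                             count = 100L))
  # soft clip: rate 1e-3 -> 30 phred, below the mapq 60 cap
  it <- data.table(kind = "SOFT_CLIP", seq = strrep("A", 20),
                   mapq_local = 60L, mapq_remote = NA_integer_,
                   chrom = "chr1", chrom2 = NA_character_,
                   dir1 = "HEAD", dir2 = NA_character_,
                   start1 = 1L, end1 = 1L, start2 = NA_integer_,
                   end2 = NA_integer_)
  expect_equal(evidence_quality(it, m), 30)
  # mapq 20 binds as cap
  it20 <- copy(it)[, mapq_local := 20L]
  expect_equal(evidence_quality(it20, m), 20)
  # split read capped by both mapqs
  m2 <- make_metrics(n_mapped = 100000L,
                     cigar_rates = data.table(op = "S", len = 20L,
                                              count = 1L))
  sr <- copy(it)[, `:=`(kind = "SPLIT_READ", mapq_local = 60L,
                        mapq_remote = 25L, chrom2 = "chr1", dir2 = "TAIL",
                        start2 = 500L, end2 = 500L)]
  expect_lte(evidence_quality(sr, m2), 25)
  # zero-rate floor: 1 per observed read count
  um <- copy(it)[, kind := "UNMAPPED_MATE"]
  m3 <- make_metrics(n_mapped = 1000L, um_rate = 0)
  expect_equal(evidence_quality(um, m3), 30)  # floor 1e-3
})

mk_item <- function(eid, s1, e1, s2 = NA_integer_, e2 = NA_integer_,
                    qual = 10, frag = eid, d1 = "HEAD", d2 = "TAIL") {
  data.table(eid = eid, fragment_id = frag, sample = "T", kind = "X",
             qual = qual, c1 = "chr1", s1 = s1, e1 = e1, d1 = d1,
             c2 = if (is.na(s2)) NA_character_ else "chr1",
             s2 = s2, e2 = e2, d2 = if (is.na(s2)) NA_character_ else d2)
}

test_that("maximal cliques match exhaustive enumeration", {
  # three mutually overlapping items plus one disjoint
  it <- rbind(mk_item("a", 100L, 300L, 600L, 800L),
              mk_item("b", 150L, 350L, 650L, 850L),
              mk_item("c", 200L, 400L, 700L, 900L),
              mk_item("d", 1000L, 1200L, 2000L, 2200L))
  enum <- enumerate_candidates(it)
  sets <- lapply(enum$membership, sort)
  expect_setequal(vapply(sets, paste, "", collapse = ","),
                  c("a,b,c", "d"))
  # chain A-B, B-C with A,C disjoint -> two maximal cliques
  it2 <- rbind(mk_item("A", 100L, 200L, 600L, 700L),
               mk_item("B", 150L, 250L, 650L, 750L),
               mk_item("C", 201L, 300L, 701L, 800L))
  enum2 <- enumerate_candidates(it2)
  expect_setequal(vapply(lapply(enum2$membership, sort), paste, "",
                         collapse = ","), c("A,B", "B,C"))
  # randomized oracle equivalence on <= 12 items
  for (s in 1:6) {
    set.seed(700 + s)
    n <- sample(5:12, 1)
    st <- sample(1:500, n, replace = TRUE)
    it3 <- rbindlist(lapply(seq_len(n), function(i)
      mk_item(sprintf("v%02d", i), st[i], st[i] + sample(50:200, 1))))
    enum3 <- enumerate_candidates(it3)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) if (i != j)
      adj[i, j] <- it3$s1[i] <= it3$e1[j] && it3$s1[j] <= it3$e1[i]
    oracle <- brute_max_cliques(adj)
    got <- lapply(enum3$membership, function(e)
      sort(match(e, it3$eid)))
    expect_setequal(vapply(oracle, paste, "", collapse = ","),
                    vapply(got, paste, "", collapse = ","))
  }
})

test_that("evidence is allocated uniquely with documented preferences", {
  it <- rbind(mk_item("x", 100L, 300L, 600L, 800L, qual = 40),
              mk_item("y", 100L, 300L, 600L, 800L, qual = 80),
              mk_item("z", 250L, 450L, 750L, 950L, qual = 40))
  # x is compatible with y (clique {x,y}, score 120) and z ({x,z}, 80)
  enum <- enumerate_candidates(it)
  alloc <- allocate_evidence(enum$candidates, enum$membership, it)
  # every item allocated exactly once (partition property)
  expect_equal(sort(alloc$eid), c("x", "y", "z"))
  cand_of <- function(e) alloc[eid == e, cand]
  expect_equal(cand_of("x"), cand_of("y"))   # highest scoring clique
  # assembly preference overrides score
  asm_frags <- setNames(list("x"), as.character(cand_of("z")))
  alloc2 <- allocate_evidence(enum$candidates, enum$membership, it,
                              asm_frags)
  expect_equal(alloc2[eid == "x", cand], unname(cand_of("z")))
  # deterministic under symmetric tie
  t1 <- allocate_evidence(enum$candidates, enum$membership, it)
  t2 <- allocate_evidence(enum$candidates, enum$membership, it)
  expect_identical(t1, t2)
})

test_that("minimum fragment and event-size rules gate calls", {
  g <- synth_genome(c(chr1 = 30000L), seed = 17)
  svs <- rbind(sv_table("DEL", "chr1", 10000L, size = 9L),
               sv_table("DEL", "chr1", 20000L, size = 300L))
  sim <- simulate_sv_reads(sim_config(g, svs, cov_tumour = 40,
                                      cov_normal = 25, seed = 6))
  res <- call_structural_variants(sim$tumour, sim$normal, g)
  sizes <- res$calls[svtype %in% c("DEL", "INS") & !imprecise, size]
  expect_true(300L %in% sizes)
  expect_false(any(sizes < 10L))   # 9 bp deletion suppressed

  # 9 bp foldback inversion is exempt from the minimum size
  svf <- sv_table("FOLDBACK", "chr1", 25000L, size = 9L)
  simf <- simulate_sv_reads(sim_config(g, svf, cov_tumour = 40,
                                       cov_normal = 25, seed = 8))
  resf <- call_structural_variants(simf$tumour, simf$normal, g)
  inv <- resf$calls[svtype == "INV" & !imprecise]
  expect_gte(nrow(inv), 1L)
  expect_true(any(abs(inv$pos1 - 24991L) <= inv$homlen + 1L &
                    abs(inv$pos2 - 25000L) <= inv$homlen + 1L))
})

test_that("QUAL equals the sum of its per-category components", {
  g <- synth_genome(c(chr1 = 30000L), seed = 19)
  svs <- sv_table("DEL", "chr1", 15000L, size = 2000L)
  sim <- simulate_sv_reads(sim_config(g, svs, cov_tumour = 35,
                                      cov_normal = 25, seed = 4))
  res <- call_structural_variants(sim$tumour, sim$normal, g)
  bp <- res$calls[type == "BP"]
  expect_gt(nrow(bp), 0L)
  for (i in seq_len(nrow(bp))) {
    expect_equal(bp$qual[i], bp$t_qual[i] + bp$n_qual[i])
    expect_equal(bp$t_qual[i],
                 bp$t_asq[i] + bp$t_srq[i] + bp$t_rpq[i] + bp$t_iq[i])
  }
  # VF counts unique fragments within each call (no double counting of a
  # fragment supporting both directly and via assembly)
  fr <- lapply(strsplit(bp$t_frags, ","), function(x) x[nzchar(x)])
  for (f in fr) expect_equal(anyDuplicated(f), 0L)
  expect_equal(bp$t_vf, vapply(fr, length, 1L))
})

test_that("planted junctions are recovered with exact coordinates", {
  g <- synth_genome(c(chr1 = 40000L, chr2 = 15000L), seed = 23)
  svs <- rbind(sv_table("DEL", "chr1", 8000L, size = 700L),
               sv_table("DUP", "chr1", 16000L, size = 90L),
               sv_table("INV", "chr1", 24000L, size = 500L),
               sv_table("TRA", "chr1", 36000L, "chr2", 6000L))
  sim <- simulate_sv_reads(sim_config(g, svs, cov_tumour = 40,
                                      cov_normal = 28, seed = 13))
  res <- call_structural_variants(sim$tumour, sim$normal, g)
  prec <- res$calls[imprecise == FALSE]
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i]
    hit <- prec[chrom1 == t$chrom1 & chrom2 == t$chrom2 &
                  dir1 == t$dir1 & dir2 == t$dir2 &
                  pos1 >= t$pos1 + cipos1_lo - 1L &
                  pos1 <= t$pos1 + 1L &
                  abs(pos2 - t$pos2) <= homlen + 1L]
    expect_gte(nrow(hit), 1L)
  }
})
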