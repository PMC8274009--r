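# helper: precise breakpoint call rows for phasing tests
ph_call <- function(id, p1, d1, p2, d2, chrom = "chr1", chromB = chrom,
                    imprecise = FALSE, cip = 0L, qual = 1500) {
  make_call(id = id, chrom1 = chrom, pos1 = as.integer(p1), dir1 = d1,
            chrom2 = chromB, pos2 = as.integer(p2), dir2 = d2,
            imprecise = imprecise, cipos1_lo = -cip, cipos1_hi = cip,
            cipos2_lo = -cip, cipos2_hi = cip, qual = qual,
            svtype = if (chrom == chromB) "DEL" else "CTX",
            size = if (chrom == chromB) abs(p2 - p1) else NA_integer_)
}

test_that("contigs with three alignments phase their junctions cis", {
  calls <- rbind(ph_call("A", 1000L, "HEAD", 2000L, "TAIL"),
                 ph_call("B", 2100L, "HEAD", 5000L, "TAIL"))
  cj <- data.table(contig_id = "asm0001",
                   chrom1 = c("chr1", "chr1"), pos1 = c(1000L, 2100L),
                   dir1 = "HEAD", chrom2 = c("chr1", "chr1"),
                   pos2 = c(2000L, 5000L), dir2 = "TAIL", homlen = 0L,
                   seg_index = 1:2, n_segs = 3L)
  chains <- list(asm0001 = data.table(
    chrom = "chr1", rstart = c(700L, 2000L, 5000L),
    rend = c(1000L, 2100L, 5300L), strand = "+",
    qstart = c(1L, 302L, 403L), qend = c(301L, 402L, 703L), score = 300,
    mapq = 60L))
  links <- assembly_links(chains, cj, calls)
  cis <- links[kind == "ASSEMBLY_CIS"]
  expect_equal(nrow(cis), 1L)
  expect_setequal(c(cis$id1, cis$id2), c("A", "B"))
  expect_equal(cis$provenance, "asm0001")
  # a two-alignment chain produces no multi-junction link
  chains2 <- list(asm0002 = chains$asm0001[1:2])
  cj2 <- cj[1][, `:=`(contig_id = "asm0002", n_segs = 2L)]
  expect_equal(nrow(assembly_links(chains2, cj2, calls)[
    kind == "ASSEMBLY_CIS"]), 0L)
})

test_that("a chain spanning another call's locus phases trans", {
  calls <- rbind(ph_call("X", 1000L, "HEAD", 5000L, "TAIL"),
                 ph_call("Y", 800L, "HEAD", 4000L, "TAIL"))
  cj <- data.table(contig_id = "asm0001", chrom1 = "chr1", pos1 = 1000L,
                   dir1 = "HEAD", chrom2 = "chr1", pos2 = 5000L,
                   dir2 = "TAIL", homlen = 0L, seg_index = 1L, n_segs = 2L)
  # the chain's first alignment crosses Y's breakend at 800 with reference
  # bases on both sides
  chains <- list(asm0001 = data.table(
    chrom = "chr1", rstart = c(700L, 5000L), rend = c(1000L, 5300L),
    strand = "+", qstart = c(1L, 302L), qend = c(301L, 602L), score = 300,
    mapq = 60L))
  links <- assembly_links(chains, cj, calls)
  tr <- links[kind == "ASSEMBLY_TRANS"]
  expect_equal(nrow(tr), 1L)
  expect_setequal(c(tr$id1, tr$id2), c("X", "Y"))
})

test_that("soft-clip anchors crossing a junction by 10 bp phase trans", {
  # A's HEAD anchor is 200 bp (reaches 801..1000); B's junction at 816
  # leaves 15 bp of A's anchor beyond it
  base <- rbind(ph_call("A", 1000L, "HEAD", 5000L, "TAIL"),
                ph_call("B", 816L, "HEAD", 4000L, "TAIL"))
  expect_equal(nrow(sc_trans_links(base)[id1 == "A" & id2 == "B"]), 1L)
  # only 9 bp of anchor beyond the junction: no link
  base9 <- rbind(ph_call("A", 1000L, "HEAD", 5000L, "TAIL"),
                 ph_call("B", 810L, "HEAD", 4000L, "TAIL"))
  expect_equal(nrow(sc_trans_links(base9)[id1 == "A" & id2 == "B"]), 0L)
  # calls 5 kb apart are not "nearby"
  far <- rbind(ph_call("A", 10000L, "HEAD", 30000L, "TAIL"),
               ph_call("B", 15000L, "HEAD", 35000L, "TAIL"))
  expect_equal(nrow(sc_trans_links(far, window = 600L)), 0L)
})

test_that("transitive calls collapse onto precise chains", {
  # precise A:1000->2000 and 2050->5000; imprecise spanning 1000->5000
  calls <- rbind(
    ph_call("P1", 1000L, "HEAD", 2000L, "TAIL"),
    ph_call("P2", 2050L, "HEAD", 5000L, "TAIL"),
    ph_call("IM", 1000L, "HEAD", 5000L, "TAIL", imprecise = TRUE,
            cip = 100L))
  tc <- transitive_collapse(calls)
  expect_equal(tc$collapsed, "IM")
  expect_equal(nrow(tc$links[kind == "TRANSITIVE"]), 1L)
  expect_setequal(c(tc$links$id1, tc$links$id2), c("P1", "P2"))
  # middle segment below 20 bp: no collapse
  calls15 <- rbind(
    ph_call("P1", 1000L, "HEAD", 2000L, "TAIL"),
    ph_call("P2", 2015L, "HEAD", 5000L, "TAIL"),
    ph_call("IM", 1000L, "HEAD", 5000L, "TAIL", imprecise = TRUE,
            cip = 100L))
  expect_length(transitive_collapse(calls15)$collapsed, 0L)
  # a chain needing 5 junctions (hops across 6 chromosomes, so no shorter
  # subpath exists) exceeds the 4-segment budget: rejected
  hop <- function(i) ph_call(paste0("P", i), 1050L, "HEAD", 1000L, "TAIL",
                             chrom = paste0("chr", i),
                             chromB = paste0("chr", i + 1L))
  ps <- rbindlist(lapply(1:5, hop))
  calls5 <- rbind(ps, ph_call("IM", 1050L, "HEAD", 1000L, "TAIL",
                              chrom = "chr1", chromB = "chr6",
                              imprecise = TRUE, cip = 10L))
  expect_length(transitive_collapse(calls5)$collapsed, 0L)
  # the same chain with 3 hops is within budget and collapses
  calls3 <- rbind(rbindlist(lapply(1:3, hop)),
                  ph_call("IM", 1050L, "HEAD", 1000L, "TAIL",
                          chrom = "chr1", chromB = "chr4",
                          imprecise = TRUE, cip = 10L))
  expect_equal(transitive_collapse(calls3)$collapsed, "IM")
  # total path length above 1000 bp: rejected
  far <- rbind(
    ph_call("P1", 1000L, "HEAD", 2000L, "TAIL"),
    ph_call("P2", 3200L, "HEAD", 6000L, "TAIL"),
    ph_call("IM", 1000L, "HEAD", 6000L, "TAIL", imprecise = TRUE,
            cip = 100L))
  expect_length(transitive_collapse(far)$collapsed, 0L)
})

test_that("collapsing is idempotent and emitted paths obey constraints", {
  calls <- rbind(
    ph_call("P1", 1000L, "HEAD", 2000L, "TAIL"),
    ph_call("P2", 2050L, "HEAD", 5000L, "TAIL"),
    ph_call("IM", 1000L, "HEAD", 5000L, "TAIL", imprecise = TRUE,
            cip = 100L))
  tc <- transitive_collapse(calls)
  kept <- calls[!id %in% tc$collapsed]
  tc2 <- transitive_collapse(kept)
  expect_length(tc2$collapsed, 0L)
  expect_equal(nrow(tc2$links), 0L)
})

test_that("transitive search matches exhaustive path enumeration", {
  # oracle: recursive enumeration of all traversal paths over <= 8 precise
  # junctions with the documented constraints
  oracle_collapses <- function(precise, imp, max_len = 1000L,
                               max_segs = 4L, min_seg = 20L) {
    bends <- rbind(
      precise[, .(id, endno = 1L, chrom = chrom1, pos = pos1, dir = dir1)],
      precise[, .(id, endno = 2L, chrom = chrom2, pos = pos2, dir = dir2)])
    found <- FALSE
    recur <- function(cur_id, cur_endno, total, used, start) {
      land <- bends[id == cur_id & endno != cur_endno]
      end <- land
      e1 <- c(imp$pos1 + imp$cipos1_lo - 50L, imp$pos1 + imp$cipos1_hi + 50L)
      e2 <- c(imp$pos2 + imp$cipos2_lo - 50L, imp$pos2 + imp$cipos2_hi + 50L)
      if (length(used) >= 2L) {
        ok <- (start$chrom == imp$chrom1 && start$dir == imp$dir1 &&
                 start$pos >= e1[1] && start$pos <= e1[2] &&
                 end$chrom == imp$chrom2 && end$dir == imp$dir2 &&
                 end$pos >= e2[1] && end$pos <= e2[2]) ||
              (start$chrom == imp$chrom2 && start$dir == imp$dir2 &&
                 start$pos >= e2[1] && start$pos <= e2[2] &&
                 end$chrom == imp$chrom1 && end$dir == imp$dir1 &&
                 end$pos >= e1[1] && end$pos <= e1[2])
        if (ok) found <<- TRUE
      }
      if (length(used) >= max_segs) return()
      nxt <- if (land$dir == "HEAD")
        bends[chrom == land$chrom & dir == "TAIL" & pos <= land$pos &
                !id %in% used][, seg := land$pos - pos]
      else
        bends[chrom == land$chrom & dir == "HEAD" & pos >= land$pos &
                !id %in% used][, seg := pos - land$pos]
      nxt <- nxt[seg >= min_seg & total + seg <= max_len]
      for (j in seq_len(nrow(nxt)))
        recur(nxt$id[j], nxt$endno[j], total + nxt$seg[j],
              c(used, nxt$id[j]), start)
    }
    for (i in seq_len(nrow(bends)))
      recur(bends$id[i], bends$endno[i], 0L, bends$id[i], bends[i])
    found
  }
  for (s in 1:6) {
    set.seed(900 + s)
    n <- sample(3:8, 1)
    pos <- sort(sample(seq(1000L, 4000L, by = 10L), 2L * n))
    precise <- rbindlist(lapply(seq_len(n), function(i)
      ph_call(paste0("P", i), pos[2 * i - 1], "HEAD", pos[2 * i], "TAIL")))
    imp <- ph_call("IM", pos[1], "HEAD", pos[2 * n], "TAIL",
                   imprecise = TRUE, cip = 60L)
    calls <- rbind(precise, imp)
    got <- "IM" %in% transitive_collapse(calls)$collapsed
    expect_equal(got, oracle_collapses(precise, imp), info = paste("seed", s))
  }
})

test_that("phasability matches the Poisson-spacing closed form", {
  # two facing junctions 400 bp apart
  b <- data.table(chrom = "chr1", pos = c(1000L, 1400L),
                  dir = c("TAIL", "HEAD"))
  ph <- phasability(b, max_phase_distance = 1000L)
  expect_equal(ph$distances, c(400, 400))
  # junctions on different chromosomes only: no finite distances
  b2 <- data.table(chrom = c("chr1", "chr2"), pos = c(1000L, 1000L),
                   dir = c("HEAD", "TAIL"))
  expect_length(phasability(b2)$distances, 0L)
  # uniform random placement: fraction within d ~ 1 - exp(-n*d/L)
  L <- 2e6; n <- 400L; d <- 1000L
  for (s in 1:3) {
    sim <- svkit:::with_seed(s, data.table(
      chrom = "sim", pos = as.integer(sort(floor(runif(n, 1, L)))),
      dir = sample(c("HEAD", "TAIL"), n, replace = TRUE)))
    frac <- phasability(sim, max_phase_distance = d)$fraction
    expected <- 1 - exp(-n * d / (2 * L))
    # n/2 junctions of each direction scan toward each other
    expect_lt(abs(frac - expected), 4 * sqrt(expected * (1 - expected) / n))
  }
})
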