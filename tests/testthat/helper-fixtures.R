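library(data.table)

# minimal read record constructor (simulator-table shape)
make_read <- function(qname = "r1", flag = 99L, chrom = "chr1", pos = 100L,
                      mapq = 60L, cigar = "100M", mchrom = chrom,
                      mpos = 300L, tlen = 300L,
                      seq = strrep("ACGT", 25), strand = "+",
                      mate_mapq = 60L, mate_mapped = TRUE, proper = TRUE) {
  data.table(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, mchrom = mchrom, mpos = mpos,
             tlen = tlen, seq = seq, strand = strand, mate_mapq = mate_mapq,
             mate_mapped = mate_mapped, proper = proper)
}

# a read pair with controllable geometry
make_pair <- function(qname = "p1", chrom = "chr1", pos1 = 100L,
                      pos2 = 300L, tlen = 300L, seq1 = strrep("ACGT", 25),
                      seq2 = strrep("TGCA", 25), mapq1 = 60L, mapq2 = 60L,
                      cigar1 = "100M", cigar2 = "100M", proper = TRUE) {
  rbind(
    make_read(qname, 99L, chrom, pos1, mapq1, cigar1, chrom, pos2, tlen,
              seq1, "+", mapq2, TRUE, proper),
    make_read(qname, 147L, chrom, pos2, mapq2, cigar2, chrom, pos1, -tlen,
              seq2, "-", mapq1, TRUE, proper))
}

# default metrics for unit tests that do not estimate from reads
make_metrics <- function(lo = 200L, hi = 400L, maxf = 420L, read_len = 100L,
                         n_mapped = 100000L,
                         cigar_rates = data.table(op = "S", len = 20L,
                                                  count = 100L),
                         um_rate = 1e-3, disc_rate = 1e-3) {
  hist <- table(rep(300L, 100)) / 100
  structure(list(fragment_size_hist = hist, concordant_lo = lo,
                 concordant_hi = hi, max_fragment = maxf,
                 cigar_rates = cigar_rates, n_mapped = n_mapped,
                 unmapped_mate_rate = um_rate, discordant_rate = disc_rate,
                 read_length = read_len), class = "svkit_metrics")
}

# a call-table row passing every somatic filter by default; override fields
make_call <- function(...) {
  base <- list(
    id = "c1", type = "BP", chrom1 = "chr1", pos1 = 10000L, dir1 = "HEAD",
    chrom2 = "chr1", pos2 = 15000L, dir2 = "TAIL", insert = "",
    imprecise = FALSE, cipos1_lo = 0L, cipos1_hi = 0L, cipos2_lo = 0L,
    cipos2_hi = 0L, homlen = 0L, homseq = "", ihompos_lo = 0L,
    ihompos_hi = 0L, svtype = "DEL", size = 4999L, qual = 1500,
    cq = 1500, sb = 0.5, beid = "asm0001", anchor1 = 200L, anchor2 = 200L,
    breakend_seq = "", bealn = "",
    t_as = 2L, t_assr = 20L, t_asrp = 10L, t_sr = 10L, t_rp = 10L,
    t_ic = 0L, t_asq = 800, t_srq = 400, t_rpq = 300, t_iq = 0,
    t_qual = 1500, t_vf = 30L, t_ref = 10L, t_refpair = 5L, t_ref2 = 10L,
    t_refpair2 = 5L, t_frags = "", t_ba = 0L, t_bassr = 0L, t_basrp = 0L,
    t_bsc = 0L, t_bum = 0L, t_baq = 0, t_bscq = 0, t_bumq = 0, t_bvf = 0L,
    n_as = 0L, n_assr = 0L, n_asrp = 0L, n_sr = 0L, n_rp = 0L, n_ic = 0L,
    n_asq = 0, n_srq = 0, n_rpq = 0, n_iq = 0, n_qual = 0, n_vf = 0L,
    n_ref = 20L, n_refpair = 10L, n_ref2 = 20L, n_refpair2 = 10L,
    n_frags = "", n_ba = 0L, n_bassr = 0L, n_basrp = 0L, n_bsc = 0L,
    n_bum = 0L, n_baq = 0, n_bscq = 0, n_bumq = 0, n_bvf = 0L)
  override <- list(...)
  for (k in names(override)) base[[k]] <- override[[k]]
  as.data.table(base)
}

# a single-breakend call row passing filters by default
make_be_call <- function(...) {
  args <- list(...)
  base <- list(type = "BE", chrom2 = NA_character_, pos2 = NA_integer_,
               dir2 = NA_character_, svtype = "BND", size = NA_integer_,
               qual = 1500, t_ba = 2L, t_basrp = 5L, t_bassr = 20L,
               t_bsc = 20L, t_bum = 10L, t_bvf = 30L, t_vf = 30L,
               breakend_seq = strrep("ACGGT", 20),
               ihompos_lo = NA_integer_, ihompos_hi = NA_integer_)
  do.call(make_call, c(args, base[!names(base) %in% names(args)]))
}

# small random reference genome as named character vector
rand_ref <- function(len = 5000L, seed = 1L, chroms = "chr1") {
  with_seed <- svkit:::with_seed
  with_seed(seed, {
    out <- vapply(chroms, function(C)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    out
  })
}

# brute-force maximal clique enumeration over a compatibility matrix
brute_max_cliques <- function(adj) {
  n <- nrow(adj)
  subsets <- list()
  for (m in seq_len(2^n) - 1L) {
    v <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L)
    if (length(v) == 0L) next
    ok <- TRUE
    if (length(v) > 1L) {
      pr <- combn(v, 2L)
      ok <- all(adj[t(pr)])
    }
    if (ok) subsets[[length(subsets) + 1L]] <- v
  }
  # keep maximal only
  keep <- vapply(subsets, function(s)
    !any(vapply(subsets, function(t2)
      length(t2) > length(s) && all(s %in% t2), TRUE)), TRUE)
  lapply(subsets[keep], sort)
}

# random call generator covering the full ledger
random_calls <- function(n, seed = 1L) {
  svkit:::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      bp <- runif(1) < 0.75
      chrom1 <- sample(c("chr1", "chr2"), 1)
      pos1 <- sample(1000:900000, 1)
      d1 <- sample(c("HEAD", "TAIL"), 1)
      if (bp) {
        chrom2 <- sample(c("chr1", "chr2"), 1)
        pos2 <- sample(1000:900000, 1)
        if (chrom2 < chrom1 || (chrom2 == chrom1 && pos2 < pos1)) {
          tmp <- chrom1; chrom1 <- chrom2; chrom2 <- tmp
          tmp <- pos1; pos1 <- pos2; pos2 <- tmp
        }
        hl <- sample(0:12, 1)
        make_call(id = sprintf("rc%03d", i), chrom1 = chrom1,
                  pos1 = as.integer(pos1), dir1 = d1, chrom2 = chrom2,
                  pos2 = as.integer(pos2),
                  dir2 = sample(c("HEAD", "TAIL"), 1),
                  insert = if (runif(1) < 0.3)
                    svkit:::random_dna(sample(1:20, 1)) else "",
                  imprecise = runif(1) < 0.2,
                  homlen = hl, homseq = if (hl) svkit:::random_dna(hl) else "",
                  cipos1_lo = 0L, cipos1_hi = hl, cipos2_lo = 0L,
                  cipos2_hi = hl,
                  ihompos_lo = -sample(0:5, 1), ihompos_hi = hl,
                  qual = round(runif(1, 10, 5000), 3),
                  sb = round(runif(1), 4),
                  svtype = sample(c("DEL", "DUP", "INV", "CTX"), 1),
                  size = sample(50:100000, 1),
                  t_vf = sample(0:99, 1), n_vf = sample(0:9, 1),
                  t_sr = sample(0:50, 1), t_rp = sample(0:50, 1),
                  t_asq = round(runif(1, 0, 2000), 3))
      } else {
        make_be_call(id = sprintf("rc%03d", i), chrom1 = chrom1,
                     pos1 = as.integer(pos1), dir1 = d1,
                     breakend_seq = svkit:::random_dna(sample(30:200, 1)),
                     bealn = "chr2:12345|+|60",
                     qual = round(runif(1, 10, 5000), 3),
                     t_bvf = sample(2:80, 1), t_bsc = sample(0:40, 1))
      }
    })
    rbindlist(rows, use.names = TRUE, fill = TRUE)
  })
}

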