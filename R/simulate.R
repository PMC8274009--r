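# ---------------------------------------------------------------------------
# Synthetic tumour/normal genome + paired-end read simulator.
#
# The simulator emits truth-aligned SAM records: every read is placed at its
# true reference location with the soft-clip CIGAR a correct aligner would
# produce for a junction-crossing read.  Reads falling wholly inside a repeat
# array are reported at a uniformly random repeat unit with mapq 0, modelling
# ambiguous mapping and producing single-breakend evidence downstream.
# ---------------------------------------------------------------------------

#' Construct a synthetic reference genome
#'
#' Chromosomes are random uniform ACGT sequence. A repeat array may be embedded
#' in a chromosome: `copies` tandem copies of a random `unit_len` bp unit
#' (identical copies, so placement within the array is truly ambiguous),
#' flanked by unique sequence.
#'
#' @param chrom_lengths named integer vector of unique-sequence chromosome
#'   lengths (bp).
#' @param repeat_array optional list(chrom=, flank=, unit_len=, copies=):
#'   creates an extra chromosome `flank + unit_len*copies + flank` bp long with
#'   the array in the middle.
#' @param seed integer RNG seed.
#' @return a `svkit_genome` list: `seqs` (named character), `repeats`
#'   (data.table chrom/start/end/unit_len/copies).
#' @export
synth_genome <- function(chrom_lengths = c(chr1 = 100000L),
                         repeat_array = NULL, seed = 1L) {
  with_seed(seed, {
    seqs <- lapply(chrom_lengths, random_dna)
    reps <- data.table(chrom = character(), start = integer(), end = integer(),
                       unit_len = integer(), copies = integer())
    if (!is.null(repeat_array)) {
      unit <- random_dna(repeat_array$unit_len)
      fl1 <- random_dna(repeat_array$flank)
      fl2 <- random_dna(repeat_array$flank)
      arr <- paste(rep(unit, repeat_array$copies), collapse = "")
      seqs[[repeat_array$chrom]] <- paste0(fl1, arr, fl2)
      reps <- data.table(
        chrom = repeat_array$chrom,
        start = repeat_array$flank + 1L,
        end = repeat_array$flank + repeat_array$unit_len * repeat_array$copies,
        unit_len = as.integer(repeat_array$unit_len),
        copies = as.integer(repeat_array$copies))
    }
    structure(list(seqs = lapply(seqs, as.character), repeats = reps),
              class = "svkit_genome")
  })
}

#' Simulation configuration
#'
#' Defaults follow the study conditions the package is exercised under:
#' 100 bp paired-end reads, 300 +/- 30 bp fragments, 60x tumour and 40x normal
#' coverage, full tumour purity, error-free bases.
#' @param genome a `svkit_genome`
#' @param svs rearrangement table (see [sv_table()])
#' @param read_length,frag_mean,frag_sd read/fragment geometry (bp)
#' @param cov_tumour,cov_normal haploid coverage of each sample
#' @param purity fraction of tumour-sample fragments drawn from the tumour
#'   haplotypes; the remainder are drawn from the normal haplotypes
#' @param base_error per-base substitution error rate
#' @param seed integer RNG seed; all randomness derives from it
#' @export
sim_config <- function(genome, svs, read_length = 100L, frag_mean = 300,
                       frag_sd = 30, cov_tumour = 60, cov_normal = 40,
                       purity = 1.0, base_error = 0, seed = 1L,
                       tumour_segments = NULL, truth = NULL) {
  stopifnot(purity > 0, purity <= 1, read_length >= 20L)
  list(genome = genome, svs = svs, read_length = as.integer(read_length),
       frag_mean = frag_mean, frag_sd = frag_sd, cov_tumour = cov_tumour,
       cov_normal = cov_normal, purity = purity, base_error = base_error,
       seed = as.integer(seed), tumour_segments = tumour_segments,
       truth = truth)
}

#' Build a rearrangement table
#'
#' Types: DEL, DUP (tandem), INV, INS (novel sequence), TRA (non-reciprocal
#' translocation), BND_INTO_REPEAT (junction into a repeat array; its expected
#' call class is SINGLE_BREAKEND). TRA/BND_INTO_REPEAT consume the chromosome
#' tail and must lie to the right of all other events on their chromosome;
#' their target chromosome must carry no other event.
#' @param type,chrom1,pos1,chrom2,pos2,size,germline vectors (recycled)
#' @export
sv_table <- function(type, chrom1, pos1, chrom2 = NA_character_,
                     pos2 = NA_integer_, size = NA_integer_,
                     germline = FALSE) {
  data.table(type = type, chrom1 = chrom1, pos1 = as.integer(pos1),
             chrom2 = chrom2, pos2 = as.integer(pos2),
             size = as.integer(size), germline = germline)
}

# Expand rearrangements to their constituent truth junctions.
truth_junctions <- function(svs) {
  if (nrow(svs) == 0L)
    return(data.table(chrom1 = character(), pos1 = integer(), dir1 = character(),
                      chrom2 = character(), pos2 = integer(), dir2 = character(),
                      type = character(), size = integer(),
                      expected_class = character(), germline = logical()))
  rows <- lapply(seq_len(nrow(svs)), function(i) {
    v <- svs[i]
    a <- v$pos1; b <- v$pos1 + v$size - 1L
    switch(v$type,
      DEL = data.table(chrom1 = v$chrom1, pos1 = a - 1L, dir1 = DIR_HEAD,
                       chrom2 = v$chrom1, pos2 = b + 1L, dir2 = DIR_TAIL,
                       type = "DEL", size = v$size,
                       expected_class = "BREAKPOINT", germline = v$germline),
      DUP = data.table(chrom1 = v$chrom1, pos1 = a, dir1 = DIR_TAIL,
                       chrom2 = v$chrom1, pos2 = b, dir2 = DIR_HEAD,
                       type = "DUP", size = v$size,
                       expected_class = "BREAKPOINT", germline = v$germline),
      INV = data.table(chrom1 = v$chrom1, pos1 = c(a - 1L, a),
                       dir1 = c(DIR_HEAD, DIR_TAIL),
                       chrom2 = v$chrom1, pos2 = c(b, b + 1L),
                       dir2 = c(DIR_HEAD, DIR_TAIL),
                       type = "INV", size = v$size,
                       expected_class = "BREAKPOINT", germline = v$germline),
      INS = data.table(chrom1 = v$chrom1, pos1 = a, dir1 = DIR_HEAD,
                       chrom2 = v$chrom1, pos2 = a + 1L, dir2 = DIR_TAIL,
                       type = "INS", size = v$size,
                       expected_class = "BREAKPOINT", germline = v$germline),
      TRA = data.table(chrom1 = v$chrom1, pos1 = v$pos1, dir1 = DIR_HEAD,
                       chrom2 = v$chrom2, pos2 = v$pos2, dir2 = DIR_TAIL,
                       type = "TRA", size = NA_integer_,
                       expected_class = "BREAKPOINT", germline = v$germline),
      FOLDBACK = data.table(chrom1 = v$chrom1, pos1 = v$pos1 - v$size,
                       dir1 = DIR_HEAD, chrom2 = v$chrom1, pos2 = v$pos1,
                       dir2 = DIR_HEAD, type = "INV", size = v$size,
                       expected_class = "BREAKPOINT", germline = v$germline),
      BND_INTO_REPEAT = data.table(chrom1 = v$chrom1, pos1 = v$pos1,
                       dir1 = DIR_HEAD, chrom2 = v$chrom2, pos2 = v$pos2,
                       dir2 = DIR_TAIL, type = "BND",
                       size = NA_integer_,
                       expected_class = "SINGLE_BREAKEND",
                       germline = v$germline),
      stop("unknown SV type: ", v$type))
  })
  rbindlist(rows)
}

# Build derivative haplotype segment maps for a set of rearrangements.
# Returns list of data.tables (chrom, start, end, strand); chrom "INS:<i>"
# denotes the i-th novel insertion sequence (stored in attr "ins_seqs").
derive_haplotypes <- function(genome, svs, ins_seed = 99L) {
  chroms <- names(genome$seqs)
  lens <- vapply(genome$seqs, nchar, 1L)
  ins_seqs <- character(0)
  if (nrow(svs) > 0L) {
    svs <- copy(svs)[, idx := .I]
    # pre-generate insertion sequences deterministically
    with_seed(ins_seed, {
      for (i in svs[type == "INS", idx]) {
        ins_seqs[[as.character(i)]] <- random_dna(svs$size[i])
      }
    })
    tail_targets <- svs[type == "TRA", chrom2]
    if (any(tail_targets %in% svs$chrom1[svs$type %in% c("DEL","DUP","INV","INS")]))
      stop("tail-event target chromosome must carry no other rearrangement")
  }
  consumed_tail <- list()  # chrom -> truncation point (keep [1, p-1])
  haps <- list()
  for (C in chroms) {
    ev <- if (nrow(svs) > 0L) svs[chrom1 == C][order(pos1)] else svs
    segs <- data.table(chrom = character(), start = integer(),
                       end = integer(), strand = character())
    cur <- 1L
    if (!is.null(ev) && nrow(ev) > 0L) {
      # overlap check
      iv <- ev[type %in% c("DEL", "DUP", "INV"),
               .(s = pos1, e = pos1 + size - 1L)]
      if (nrow(iv) > 1L && any(iv$s[-1] <= cummax(iv$e)[-nrow(iv)]))
        stop("overlapping rearrangements are not supported")
      for (i in seq_len(nrow(ev))) {
        v <- ev[i]
        a <- v$pos1; b <- v$pos1 + v$size - 1L
        add <- function(s, e, ch = C, st = "+")
          segs <<- rbind(segs, data.table(chrom = ch, start = s, end = e, strand = st))
        if (v$type == "DEL") { if (cur <= a - 1L) add(cur, a - 1L); cur <- b + 1L }
        else if (v$type == "DUP") { add(cur, b); add(a, b); cur <- b + 1L }
        else if (v$type == "INV") { if (cur <= a - 1L) add(cur, a - 1L); add(a, b, st = "-"); cur <- b + 1L }
        else if (v$type == "INS") { add(cur, a); add(1L, v$size, ch = paste0("INS:", v$idx)); cur <- a + 1L }
        else if (v$type %in% c("TRA", "BND_INTO_REPEAT")) {
          if (i != nrow(ev)) stop("tail event must be rightmost on its chromosome")
          add(cur, v$pos1)
          add(v$pos2, lens[[v$chrom2]], ch = v$chrom2)
          # a translocation consumes the target tail; a breakend into a
          # repeat array leaves the target chromosome intact (net gain)
          if (v$type == "TRA") consumed_tail[[v$chrom2]] <- v$pos2
          cur <- NA_integer_
        }
        else if (v$type == "FOLDBACK") {
          if (i != nrow(ev)) stop("tail event must be rightmost on its chromosome")
          add(cur, v$pos1)
          add(max(1L, v$pos1 - v$size - 3000L), v$pos1 - v$size, st = "-")
          cur <- NA_integer_
        }
      }
    }
    if (!is.na(cur) && cur <= lens[[C]])
      segs <- rbind(segs, data.table(chrom = C, start = cur, end = lens[[C]], strand = "+"))
    haps[[C]] <- segs
  }
  # truncate tail-consumed target chromosomes
  for (C in names(consumed_tail)) {
    p <- consumed_tail[[C]]
    segs <- haps[[C]]
    # the target chromosome has a single full-length segment by construction
    if (p <= 1L) haps[[C]] <- segs[0] else haps[[C]][1, end := p - 1L]
  }
  attr(haps, "ins_seqs") <- ins_seqs
  haps
}

hap_sequence <- function(genome, segs, ins_seqs = character(0)) {
  if (nrow(segs) == 0L) return("")
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    ch <- segs$chrom[i]
    s <- if (startsWith(ch, "INS:")) ins_seqs[[sub("INS:", "", ch)]] else genome$seqs[[ch]]
    sub <- substr(s, segs$start[i], segs$end[i])
    if (segs$strand[i] == "-") revcomp(sub) else sub
  }, character(1))
  paste(parts, collapse = "")
}

# Map haplotype intervals [a,b] to reference blocks.
# segs must carry hs/he cumulative haplotype offsets.
seg_offsets <- function(segs) {
  w <- segs$end - segs$start + 1L
  segs[, `:=`(hs = cumsum(c(0L, head(w, -1L))) + 1L, he = cumsum(w))]
  segs
}

# one read's reference blocks: data.table(chrom,start,end,strand,qs,qe)
# where qs/qe are offsets within the read along haplotype-forward orientation
read_blocks <- function(segs, a, b) {
  hit <- segs[hs <= b & he >= a]
  out <- hit[, {
    ha <- pmax(hs, a); hb <- pmin(he, b)
    if (strand == "+") {
      rs <- start + (ha - hs); re <- start + (hb - hs)
    } else {
      re <- end - (ha - hs); rs <- end - (hb - hs)
    }
    .(chrom = chrom, start = rs, end = re, strand = strand,
      qs = ha - a + 1L, qe = hb - a + 1L)
  }, by = seq_len(nrow(hit))]
  out[, seq_len := NULL]
  merge_adjacent_blocks(out[order(qs)])
}

# merge blocks that are contiguous in both query and reference (a derivative
# junction between reference-adjacent segments is not a real junction)
merge_adjacent_blocks <- function(b) {
  if (nrow(b) < 2L) return(b)
  keep <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))[-1]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    contig <- b$chrom[i] == b$chrom[j] && b$strand[i] == b$strand[j] &&
      b$qs[i] == b$qe[j] + 1L &&
      ((b$strand[i] == "+" && b$start[i] == b$end[j] + 1L) ||
       (b$strand[i] == "-" && b$end[i] == b$start[j] - 1L))
    if (contig) {
      if (b$strand[i] == "+") b[j, end := b$end[i]] else b[j, start := b$start[i]]
      b[j, qe := b$qe[i]]
      keep[i] <- FALSE
    }
  }
  b[keep]
}

# ambiguous-placement adjustment for blocks wholly inside a repeat array
maybe_randomize_repeat <- function(blocks, repeats) {
  blocks[, ambiguous := FALSE]
  if (nrow(repeats) == 0L) return(blocks)
  for (i in seq_len(nrow(blocks))) {
    r <- repeats[chrom == blocks$chrom[i] & start <= blocks$start[i] & end >= blocks$end[i]]
    if (nrow(r) == 1L) {
      k <- (blocks$start[i] - r$start) %/% r$unit_len
      kmax <- r$copies - 1L
      kp <- sample.int(kmax + 1L, 1L) - 1L
      shift <- (kp - k) * r$unit_len
      if (blocks$end[i] + shift <= r$end && blocks$start[i] + shift >= r$start) {
        blocks[i, `:=`(start = start + shift, end = end + shift)]
      }
      blocks[i, ambiguous := TRUE]
    }
  }
  if (!"ambiguous" %in% names(blocks)) blocks[, ambiguous := FALSE]
  blocks[is.na(ambiguous), ambiguous := FALSE]
  blocks[]
}

# ---------------------------------------------------------------------------

#' Simulate a tumour/normal read pair dataset
#'
#' @param config from [sim_config()]
#' @param out_dir optional directory; if given, writes `ref.fa`,
#'   `normal.sam`, `tumour.sam`, `truth.tsv` there.
#' @return list with `tumour`, `normal` (read record data.tables),
#'   `truth` (junction table), `genome`, and file paths if written.
#' @export
simulate_sv_reads <- function(config, out_dir = NULL) {
  g <- config$genome
  if (!is.null(config$tumour_segments)) {
    # explicit derivative segment maps (e.g. clustered chains)
    norm_haps <- derive_haplotypes(g, config$svs[germline == TRUE],
                                   ins_seed = config$seed + 7L)
    tum_haps <- config$tumour_segments
    truth <- config$truth
  } else {
    norm_haps <- derive_haplotypes(g, config$svs[germline == TRUE],
                                   ins_seed = config$seed + 7L)
    tum_haps <- derive_haplotypes(g, config$svs, ins_seed = config$seed + 7L)
    truth <- truth_junctions(config$svs)
  }

  reads <- with_seed(config$seed, {
    n_reads <- sim_sample_reads(g, norm_haps, config$cov_normal, config,
                                prefix = "nrm")
    t_tum <- sim_sample_reads(g, tum_haps, config$cov_tumour * config$purity,
                              config, prefix = "tum")
    t_con <- if (config$purity < 1)
      sim_sample_reads(g, norm_haps, config$cov_tumour * (1 - config$purity),
                       config, prefix = "tcn")
    else NULL
    list(normal = n_reads, tumour = rbindlist(list(t_tum, t_con)))
  })

  res <- list(tumour = reads$tumour, normal = reads$normal, truth = truth,
              genome = g)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ref_fa <- file.path(out_dir, "ref.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(g$seqs)), ref_fa)
    res$ref_fasta <- ref_fa
    res$normal_sam <- file.path(out_dir, "normal.sam")
    res$tumour_sam <- file.path(out_dir, "tumour.sam")
    write_sam(reads$normal, g, res$normal_sam)
    write_sam(reads$tumour, g, res$tumour_sam)
    res$truth_tsv <- file.path(out_dir, "truth.tsv")
    fwrite(truth, res$truth_tsv, sep = "\t")
  }
  res
}

# simulate one sample's reads across all haplotypes (uses current RNG state)
sim_sample_reads <- function(genome, haps, cov, config, prefix) {
  ins_seqs <- attr(haps, "ins_seqs") %||% character(0)
  L <- config$read_length
  out <- list()
  for (C in names(haps)) {
    segs <- copy(haps[[C]])
    if (nrow(segs) == 0L) next
    segs <- seg_offsets(segs)
    hseq <- hap_sequence(genome, segs, ins_seqs)
    hl <- nchar(hseq)
    if (hl < 2L * L + 20L) next
    nfrag <- round(hl * cov / (2 * L))
    if (nfrag < 1L) next
    fs <- pmin(hl, pmax(2L * L, round(rnorm(nfrag, config$frag_mean, config$frag_sd))))
    st <- 1L + floor(runif(nfrag) * (hl - fs + 1L))
    out[[C]] <- build_fragment_records(genome, segs, hseq, st, fs, L,
                                       paste0(prefix, "_", C), config)
  }
  rbindlist(out)
}

build_fragment_records <- function(genome, segs, hseq, st, fs, L, prefix, config) {
  nfrag <- length(st)
  qn <- paste0(prefix, "_", seq_len(nfrag))
  # read haplotype intervals: r1 forward at fragment start, r2 revcomp at end
  rd <- data.table(
    qname = c(qn, qn), first = rep(c(TRUE, FALSE), each = nfrag),
    a = c(st, st + fs - L), b = c(st + L - 1L, st + fs - 1L),
    horient = rep(c("+", "-"), each = nfrag))
  # fast path: reads wholly within one haplotype segment
  si <- findInterval(rd$a, segs$hs)
  single <- rd$b <= segs$he[si] & !startsWith(segs$chrom[si], "INS:")
  fastr <- place_reads_fast(genome, segs, hseq, rd[single], si[single])
  slow <- rd[!single]
  recs <- lapply(seq_len(nrow(slow)), function(i) {
    r <- place_read(genome, segs, hseq, slow$a[i], slow$b[i], slow$horient[i])
    r$qname <- slow$qname[i]; r$first <- slow$first[i]
    r
  })
  dt <- rbindlist(c(list(fastr), recs), use.names = TRUE, fill = TRUE)
  if (config$base_error > 0) dt <- add_base_errors(dt, config$base_error)
  finalize_pairs(dt, config)
}

# vectorized placement of reads contained in a single segment
place_reads_fast <- function(genome, segs, hseq, rd, si) {
  if (nrow(rd) == 0L)
    return(data.table(qname = character(), first = logical(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      strand = character(), mapped = logical()))
  L <- rd$b - rd$a + 1L
  sg <- segs[si]
  plus <- sg$strand == "+"
  pos <- ifelse(plus, sg$start + (rd$a - sg$hs), sg$end - (rd$b - sg$hs))
  hsub <- substring(hseq, rd$a, rd$b)
  seq_f <- hsub
  need_rc <- !plus
  if (any(need_rc)) seq_f[need_rc] <- revcomp(hsub[need_rc])
  rev_flag <- ifelse(plus, rd$horient == "-", rd$horient == "+")
  mapq <- rep(60L, nrow(rd))
  # ambiguous placement inside repeat arrays
  if (nrow(genome$repeats) > 0L) {
    for (k in seq_len(nrow(genome$repeats))) {
      rp <- genome$repeats[k]
      inarr <- sg$chrom == rp$chrom & pos >= rp$start & (pos + L - 1L) <= rp$end
      if (any(inarr)) {
        idx <- which(inarr)
        kk <- (pos[idx] - rp$start) %/% rp$unit_len
        kp <- sample.int(rp$copies, length(idx), replace = TRUE) - 1L
        shift <- (kp - kk) * rp$unit_len
        ok <- pos[idx] + shift >= rp$start &
          pos[idx] + L[idx] - 1L + shift <= rp$end
        pos[idx[ok]] <- pos[idx[ok]] + shift[ok]
        mapq[idx] <- 0L
      }
    }
  }
  data.table(qname = rd$qname, first = rd$first, chrom = sg$chrom, pos = pos,
             mapq = mapq, cigar = paste0(L, "M"), seq = seq_f,
             strand = ifelse(rev_flag, "-", "+"), mapped = TRUE)
}

# place one read; returns a 1-row list of SAM-ish fields
place_read <- function(genome, segs, hseq, a, b, horient) {
  L <- b - a + 1L
  blocks <- read_blocks(segs, a, b)
  blocks <- blocks[!startsWith(chrom, "INS:")]
  hsub <- substr(hseq, a, b)
  if (nrow(blocks) == 0L) {
    # read entirely within novel insertion: emit as unmapped-style record is
    # not needed at the insert sizes simulated; anchor it nowhere
    return(list(chrom = "*", pos = 0L, mapq = 0L, cigar = "*",
                seq = if (horient == "+") hsub else revcomp(hsub),
                strand = "+", qs = NA_integer_, qe = NA_integer_,
                ambiguous = FALSE, mapped = FALSE))
  }
  blocks <- maybe_randomize_repeat(blocks, genome$repeats)
  pi <- which.max(blocks$qe - blocks$qs)
  pb <- blocks[pi]
  # stored (reference-forward) orientation follows the primary block
  if (pb$strand == "+") {
    seq_f <- hsub
    qs <- pb$qs; qe <- pb$qe
    rev_flag <- horient == "-"
  } else {
    seq_f <- revcomp(hsub)
    qs <- L - pb$qe + 1L; qe <- L - pb$qs + 1L
    rev_flag <- horient == "+"
  }
  cig <- paste0(if (qs > 1L) paste0(qs - 1L, "S") else "",
                qe - qs + 1L, "M",
                if (qe < L) paste0(L - qe, "S") else "")
  list(chrom = pb$chrom, pos = pb$start, mapq = if (pb$ambiguous) 0L else 60L,
       cigar = cig, seq = seq_f, strand = if (rev_flag) "-" else "+",
       qs = qs, qe = qe, ambiguous = pb$ambiguous, mapped = TRUE)
}

add_base_errors <- function(dt, rate) {
  seqs <- dt$seq
  n <- nchar(seqs)
  k <- rbinom(length(seqs), n, rate)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(n[i], k[i])
    s <- strsplit(seqs[i], "")[[1]]
    s[pos] <- sample(bases, k[i], replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  dt$seq <- seqs
  dt
}

# pair mates, compute flags/tlen/mate fields
finalize_pairs <- function(dt, config) {
  dt <- as.data.table(dt)
  dt[, end := pos + ifelse(mapped, cigar_ref_span_vec(cigar), 0L) - 1L]
  m <- dt[, .(qname, first, chrom, pos, end, mapq, strand, mapped)]
  mate <- merge(dt[, .(qname, first)],
                m[, .(qname, mfirst = first, mchrom = chrom, mpos = pos,
                      mend = end, mate_mapq = mapq, mstrand = strand,
                      mate_mapped = mapped)],
                by = "qname", allow.cartesian = TRUE)
  mate <- mate[first != mfirst]
  dt <- merge(dt, mate[, .(qname, first, mchrom, mpos, mend, mate_mapq,
                           mstrand, mate_mapped)],
              by = c("qname", "first"), sort = FALSE)
  dt[, tlen := 0L]
  same <- dt$mapped & dt$mate_mapped & dt$chrom == dt$mchrom
  lo <- pmin(dt$pos, dt$mpos); hi <- pmax(dt$end, dt$mend)
  span <- hi - lo + 1L
  dt[same, tlen := ifelse(pos <= mpos, span[same], -span[same])]
  dt[, proper := same & strand != mstrand & mapq > 0L & mate_mapq > 0L &
       abs(tlen) <= config$frag_mean + 8 * config$frag_sd]
  dt[, flag := 1L +
       ifelse(proper, 2L, 0L) +
       ifelse(strand == "-", 16L, 0L) +
       ifelse(mstrand == "-", 32L, 0L) +
       ifelse(first, 64L, 128L) +
       ifelse(!mapped, 4L, 0L) + ifelse(!mate_mapped, 8L, 0L)]
  dt[, .(qname, flag, chrom, pos, mapq, cigar, mchrom, mpos, tlen, seq,
         strand, mate_mapq, mate_mapped, proper)]
}

cigar_ref_span_vec <- function(cigs) {
  out <- integer(length(cigs))
  simple <- grepl("^\\d+M$", cigs)
  out[simple] <- as.integer(sub("M$", "", cigs[simple]))
  # soft-clipped primaries: <a>S<m>M<b>S
  rest <- which(!simple & cigs != "*")
  if (length(rest))
    out[rest] <- vapply(cigs[rest], cigar_ref_span, 1L)
  out
}

cigar_ref_span <- function(cig) {
  if (cig == "*") return(0L)
  ops <- cigar_ops(cig)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

cigar_ops <- function(cig) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
  data.table(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks))
}

#' Write read records as a SAM file
#' @param reads read record data.table from the simulator
#' @param genome the `svkit_genome` providing header lengths
#' @param path output .sam path
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           vapply(names(genome$seqs), function(C)
             sprintf("@SQ\tSN:%s\tLN:%d", C, nchar(genome$seqs[[C]])),
             character(1)))
  r <- copy(reads)[order(chrom, pos)]
  qual <- vapply(nchar(r$seq), function(n) strrep("F", n), character(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tMQ:i:%d",
                   r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                   ifelse(r$mchrom == r$chrom, "=", r$mchrom), r$mpos,
                   r$tlen, r$seq, qual, r$mate_mapq)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' In-silico purity downsampling of a tumour read set
#'
#' Each tumour fragment is kept with probability `purity`; dropped fragments
#' are replaced by fragments sampled (without replacement) from a pool of
#' normal-haplotype reads, so total coverage is preserved while junction
#' coverage scales linearly with purity.
#' @param tumour_reads,normal_pool read record tables
#' @param purity in (0, 1]
#' @param seed RNG seed
#' @export
downsample_mix <- function(tumour_reads, normal_pool, purity, seed = 1L) {
  stopifnot(purity > 0, purity <= 1)
  if (purity == 1) return(copy(tumour_reads))
  with_seed(seed, {
    frags <- unique(tumour_reads$qname)
    keep <- frags[runif(length(frags)) <= purity]
    ndrop <- length(frags) - length(keep)
    pool <- unique(normal_pool$qname)
    repl <- sample(pool, min(ndrop, length(pool)))
    rbindlist(list(tumour_reads[qname %in% keep],
                   normal_pool[qname %in% repl]))
  })
}
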