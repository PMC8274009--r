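# ---------------------------------------------------------------------------
# Library metrics and SV-supporting evidence extraction.
# ---------------------------------------------------------------------------

#' Estimate library metrics from read records
#'
#' Fragment-size bounds cover the central `central_mass` of proper-pair
#' template lengths (0.25%/99.75% empirical quantiles at the default 0.995,
#' computed by direct sorting with ceiling indexing). Also tabulates the
#' empirical per-read rates of clip/indel CIGAR operators, the unmapped-mate
#' rate and the discordant-pair rate used by the probabilistic caller.
#'
#' @param reads read record table (or SAM path)
#' @param max_reads use at most this many records
#' @param central_mass central fragment-size mass treated as concordant
#' @return `svkit_metrics` list
#' @export
estimate_library_metrics <- function(reads, max_reads = 10000000L,
                                     central_mass = 0.995) {
  reads <- as_read_table(reads)
  if (nrow(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  tl <- reads[proper == TRUE & tlen > 0L, tlen]
  if (length(tl) == 0L) stop("cannot estimate fragment distribution")
  tl <- sort(tl)
  n <- length(tl)
  qlo <- (1 - central_mass) / 2
  qhi <- 1 - qlo
  lo <- tl[max(1L, ceiling(qlo * n))]
  hi <- tl[max(1L, ceiling(qhi * n))]
  hist <- table(tl) / n

  mapped <- reads[mapped == TRUE]
  nm <- nrow(mapped)
  # per-(operator, length) counts over mapped reads
  ops <- rbindlist(lapply(c("S", "I", "D"), function(o) {
    pat <- paste0("\\d+", o)
    m <- regmatches(mapped$cigar, gregexpr(pat, mapped$cigar))
    lens <- as.integer(sub(o, "", unlist(m)))
    if (length(lens) == 0L)
      data.table(op = character(), len = integer(), count = integer())
    else {
      t <- as.data.table(table(lens))
      data.table(op = o, len = as.integer(t$lens), count = as.integer(t$N))
    }
  }))
  unmapped_mate_rate <- mapped[, mean(!mate_mapped |
                                        (!is.na(mate_mapq) & mate_mapq < 20L))]
  both <- mapped[mate_mapped == TRUE]
  discordant_rate <- if (nrow(both)) both[, mean(chrom != mchrom |
      (proper == FALSE))] else 0

  structure(list(
    fragment_size_hist = hist,
    concordant_lo = as.integer(lo), concordant_hi = as.integer(hi),
    max_fragment = as.integer(max(tl)),
    cigar_rates = ops, n_mapped = nm,
    unmapped_mate_rate = unmapped_mate_rate,
    discordant_rate = discordant_rate,
    read_length = as.integer(max(nchar(reads$seq)))),
    class = "svkit_metrics")
}

# tail rate of a CIGAR operator at length >= len, floored at 1/n_mapped
cigar_tail_rate <- function(metrics, op_kind, min_len) {
  cr <- metrics$cigar_rates
  cnt <- cr[op == op_kind & len >= min_len, sum(count)]
  max(cnt, 1L) / max(metrics$n_mapped, 1L)
}

# fragment-size tail probability of a template length (two-sided tail)
fragment_tail_prob <- function(metrics, tlen) {
  h <- metrics$fragment_size_hist
  sizes <- as.integer(names(h))
  p <- min(sum(h[sizes >= tlen]), sum(h[sizes <= tlen]))
  max(p, 1 / max(metrics$n_mapped, 1L))
}

#' Shannon entropy of base composition
#' @param seq nucleotide string (A/C/G/T/N)
#' @return entropy in bits per base
#' @export
sequence_entropy <- function(seq) {
  stopifnot(is.character(seq))
  if (any(nchar(seq) == 0L)) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                   c("A", "C", "G", "T", "N"))
  p <- f / rowSums(f)
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  unname(ent)
}

#' Bundled sequencing adapter sequences (Illumina TruSeq/Nextera)
#' @export
default_adapters <- function() c(
  truseq_r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
  truseq_r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
  nextera = "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC")

#' Test whether a clipped sequence is adapter read-through
#'
#' True iff a prefix of any adapter aligns end-anchored to the clip with
#' mismatch rate at most `max_mismatch_rate` over at least `min_overlap`
#' bases (exact match required below 12 bp of overlap).
#' @param clip_seq clipped bases (as stored, reference-forward)
#' @param adapters character vector of adapter sequences
#' @param min_overlap minimum compared prefix length
#' @param max_mismatch_rate tolerated mismatch fraction for overlaps >= 12 bp
#' @export
is_adapter_clip <- function(clip_seq, adapters = default_adapters(),
                            min_overlap = 6L, max_mismatch_rate = 0.1) {
  stopifnot(nchar(clip_seq) > 0L)
  cand <- c(clip_seq, revcomp(clip_seq))
  for (s in cand) {
    for (ad in adapters) {
      o <- min(nchar(s), nchar(ad))
      if (o < min_overlap) next
      mm <- hamming(substr(s, 1L, o), substr(ad, 1L, o))
      tol <- if (o >= 12L) floor(max_mismatch_rate * o) else 0L
      if (mm <= tol) return(TRUE)
    }
  }
  FALSE
}

empty_evidence <- function() data.table(
  eid = character(), fragment_id = character(), sample = character(),
  kind = character(), chrom = character(), start1 = integer(),
  end1 = integer(), dir1 = character(), chrom2 = character(),
  start2 = integer(), end2 = integer(), dir2 = character(),
  seq = character(), anchor_start = integer(), anchor_end = integer(),
  read_strand = character(), mapq_local = integer(), mapq_remote = integer(),
  read_seq = character())

#' Classify reads into SV-supporting evidence items
#'
#' Applies the admission filters: clips and indels must be at least
#' `min_clip`/`min_indel` bp; reads (and split segments) with mapq below
#' `min_mapq` are treated as unmapped and contribute only as unmapped mates
#' of their partner; low-entropy reads and adapter clips are suppressed.
#' Duplicate and secondary records never yield evidence.
#'
#' @param reads read record table (or SAM path)
#' @param metrics from [estimate_library_metrics()]
#' @param sample sample label attached to each item
#' @param min_clip,min_indel,min_mapq,entropy_threshold admission thresholds
#' @param adapters adapter set for clip suppression
#' @return evidence data.table; one row per item. Breakend convention:
#'   position = last anchored base; HEAD items anchor left of the breakend,
#'   TAIL items anchor right.
#' @export
classify_reads <- function(reads, metrics, sample = "S1", min_clip = 5L,
                           min_indel = 5L, min_mapq = 20L,
                           entropy_threshold = 0.5,
                           adapters = default_adapters()) {
  rd <- as_read_table(reads)
  rd <- rd[duplicate == FALSE & secondary == FALSE]
  # mate sequence lookup (for unmapped-mate assembly evidence)
  mt <- rd[, .(qname, first, mseq = seq, m_strand = strand)]
  rd <- merge(rd, mt[, .(qname, mfirst = first, mseq, m_strand)],
              by = "qname", allow.cartesian = TRUE)
  rd <- rd[first != mfirst]
  usable <- rd[mapped == TRUE & mapq >= min_mapq]
  usable <- usable[sequence_entropy(seq) >= entropy_threshold]
  if (nrow(usable) == 0L) return(empty_evidence())

  hi <- metrics$concordant_hi; lo <- metrics$concordant_lo
  L <- metrics$read_length
  items <- list()

  # --- soft clips ------------------------------------------------------
  lefts <- ifelse(grepl("^\\d+S", usable$cigar),
                  suppressWarnings(as.integer(sub("^(\\d+)S.*$", "\\1",
                                                  usable$cigar))), 0L)
  rights <- ifelse(grepl("\\d+S$", usable$cigar),
                   suppressWarnings(as.integer(sub("^.*?(\\d+)S$", "\\1",
                                                   usable$cigar))), 0L)
  rc <- usable[rights >= min_clip]
  if (nrow(rc)) {
    cl <- rights[rights >= min_clip]
    cseq <- substr(rc$seq, nchar(rc$seq) - cl + 1L, nchar(rc$seq))
    keep <- !vapply(cseq, is_adapter_clip, TRUE, adapters = adapters)
    items$sc_r <- data.table(
      fragment_id = rc$qname, sample = sample, kind = "SOFT_CLIP",
      chrom = rc$chrom, start1 = rc$end, end1 = rc$end, dir1 = DIR_HEAD,
      chrom2 = NA_character_, start2 = NA_integer_, end2 = NA_integer_,
      dir2 = NA_character_, seq = cseq,
      anchor_start = rc$pos, anchor_end = rc$end,
      read_strand = rc$strand, mapq_local = rc$mapq,
      mapq_remote = NA_integer_, read_seq = rc$seq)[keep]
  }
  lc <- usable[lefts >= min_clip]
  if (nrow(lc)) {
    cl <- lefts[lefts >= min_clip]
    cseq <- substr(lc$seq, 1L, cl)
    keep <- !vapply(cseq, is_adapter_clip, TRUE, adapters = adapters)
    items$sc_l <- data.table(
      fragment_id = lc$qname, sample = sample, kind = "SOFT_CLIP",
      chrom = lc$chrom, start1 = lc$pos, end1 = lc$pos, dir1 = DIR_TAIL,
      chrom2 = NA_character_, start2 = NA_integer_, end2 = NA_integer_,
      dir2 = NA_character_, seq = cseq,
      anchor_start = lc$pos, anchor_end = lc$end,
      read_strand = lc$strand, mapq_local = lc$mapq,
      mapq_remote = NA_integer_, read_seq = lc$seq)[keep]
  }

  # --- indels ----------------------------------------------------------
  hasid <- usable[grepl("\\d+[ID]", cigar)]
  if (nrow(hasid)) {
    idr <- rbindlist(lapply(seq_len(nrow(hasid)), function(i) {
      r <- hasid[i]
      ops <- cigar_ops(r$cigar)
      refpos <- r$pos
      out <- list()
      for (j in seq_len(nrow(ops))) {
        o <- ops[j]
        if (o$op %in% c("I", "D") && o$len >= min_indel) {
          # local breakend = last ref base before the gap
          p1 <- refpos - 1L
          p2 <- if (o$op == "D") refpos + o$len else refpos
          out[[length(out) + 1L]] <- data.table(
            fragment_id = r$qname, sample = sample, kind = "INDEL",
            chrom = r$chrom, start1 = p1, end1 = p1, dir1 = DIR_HEAD,
            chrom2 = r$chrom, start2 = p2, end2 = p2, dir2 = DIR_TAIL,
            seq = "", anchor_start = r$pos, anchor_end = r$end,
            read_strand = r$strand, mapq_local = r$mapq,
            mapq_remote = r$mapq, read_seq = r$seq)
        }
        if (o$op %in% c("M", "D", "N", "=", "X")) refpos <- refpos + o$len
      }
      rbindlist(out)
    }))
    items$indel <- idr
  }

  # --- split reads (SA chain present) ----------------------------------
  sa <- usable[!is.na(sa_tag) & sa_tag != ""]
  if (nrow(sa)) {
    items$split <- rbindlist(lapply(seq_len(nrow(sa)), function(i)
      split_read_evidence(sa[i], sample, min_mapq)), fill = TRUE)
  }

  # --- discordant pairs and unmapped mates -----------------------------
  pair_info <- rd[, .(qname, first, mapped, mapq, chrom, pos, end, strand,
                      mchrom, mpos, tlen, mate_mapped, mate_mapq, proper,
                      mseq, m_strand, seq)]
  anch <- pair_info[mapped & mapq >= min_mapq]
  mate_bad <- !anch$mate_mapped | (!is.na(anch$mate_mapq) & anch$mate_mapq < min_mapq)
  um <- anch[mate_bad]
  if (nrow(um)) {
    dirn <- ifelse(um$strand == "+", DIR_HEAD, DIR_TAIL)
    s1 <- ifelse(dirn == DIR_HEAD, um$end,
                 pmax(1L, um$pos - (hi - (um$end - um$pos + 1L))))
    e1 <- ifelse(dirn == DIR_HEAD, um$end + (hi - (um$end - um$pos + 1L)),
                 um$pos)
    # orient mate sequence to derivative-forward continuation
    mseq_f <- ifelse(dirn == DIR_HEAD,
                     ifelse(um$m_strand == "-", um$mseq, revcomp(um$mseq)),
                     ifelse(um$m_strand == "+", um$mseq, revcomp(um$mseq)))
    items$um <- data.table(
      fragment_id = um$qname, sample = sample, kind = "UNMAPPED_MATE",
      chrom = um$chrom, start1 = as.integer(s1), end1 = as.integer(e1),
      dir1 = dirn, chrom2 = NA_character_, start2 = NA_integer_,
      end2 = NA_integer_, dir2 = NA_character_, seq = mseq_f,
      anchor_start = um$pos, anchor_end = um$end,
      read_strand = um$strand, mapq_local = um$mapq,
      mapq_remote = NA_integer_, read_seq = um$seq)
  }
  dp <- anch[!mate_bad]
  disc <- dp$chrom != dp$mchrom | dp$strand == dp$m_strand |
    abs(dp$tlen) < lo | abs(dp$tlen) > hi
  dp <- dp[disc]
  if (nrow(dp)) {
    # one item per fragment: keep the record whose (chrom,pos) is smaller
    key <- paste(dp$chrom, formatC(dp$pos, width = 12, flag = "0"))
    mkey <- paste(dp$mchrom, formatC(dp$mpos, width = 12, flag = "0"))
    dp <- dp[key < mkey | (key == mkey & first)]
    dirn <- ifelse(dp$strand == "+", DIR_HEAD, DIR_TAIL)
    span1 <- dp$end - dp$pos + 1L
    s1 <- ifelse(dirn == DIR_HEAD, dp$end, pmax(1L, dp$pos - (hi - span1)))
    e1 <- ifelse(dirn == DIR_HEAD, dp$end + (hi - span1), dp$pos)
    dirm <- ifelse(dp$m_strand == "+", DIR_HEAD, DIR_TAIL)
    # the mate's aligned span is unknown here (it may itself be clipped), so
    # the remote breakend interval conservatively spans the fragment bound
    s2 <- ifelse(dirm == DIR_HEAD, dp$mpos, pmax(1L, dp$mpos - hi + 1L))
    e2 <- ifelse(dirm == DIR_HEAD, dp$mpos + hi - 1L, dp$mpos + L - 1L)
    items$dp <- data.table(
      fragment_id = dp$qname, sample = sample, kind = "DISCORDANT_PAIR",
      chrom = dp$chrom, start1 = as.integer(s1), end1 = as.integer(e1),
      dir1 = dirn, chrom2 = dp$mchrom, start2 = as.integer(s2),
      end2 = as.integer(e2), dir2 = dirm, seq = dp$mseq,
      anchor_start = dp$pos, anchor_end = dp$end,
      read_strand = dp$strand, mapq_local = dp$mapq,
      mapq_remote = dp$mate_mapq, read_seq = dp$seq,
      mate_strand = dp$m_strand)
  }
  ev <- rbindlist(items, use.names = TRUE, fill = TRUE)
  if (nrow(ev) == 0L) return(empty_evidence())
  ev[, eid := paste0(sample, "e", .I)]
  setcolorder(ev, "eid")
  ev[]
}

# split-read evidence from an SA chain (primary record view)
split_read_evidence <- function(r, sample, min_mapq) {
  segs <- strsplit(r$sa_tag, ";")[[1]]
  segs <- segs[nzchar(segs)]
  parts <- tstrsplit(segs, ",")
  sa_mapq <- as.integer(parts[[5]])
  if (any(sa_mapq < min_mapq) || r$mapq < min_mapq) return(NULL)
  # local side: use the primary clip geometry; remote from the first SA seg
  sa_chrom <- parts[[1]][1]; sa_pos <- as.integer(parts[[2]][1])
  sa_strand <- parts[[3]][1]; sa_cigar <- parts[[4]][1]
  span <- cigar_ref_span(sa_cigar)
  lefts <- if (grepl("^\\d+S", r$cigar))
    as.integer(sub("^(\\d+)S.*$", "\\1", r$cigar)) else 0L
  rights <- if (grepl("\\d+S$", r$cigar))
    as.integer(sub("^.*?(\\d+)S$", "\\1", r$cigar)) else 0L
  if (rights >= lefts) {
    d1 <- DIR_HEAD; p1 <- r$end
    if (sa_strand == r$strand) { d2 <- DIR_TAIL; p2 <- sa_pos }
    else { d2 <- DIR_HEAD; p2 <- sa_pos + span - 1L }
  } else {
    d1 <- DIR_TAIL; p1 <- r$pos
    if (sa_strand == r$strand) { d2 <- DIR_HEAD; p2 <- sa_pos + span - 1L }
    else { d2 <- DIR_TAIL; p2 <- sa_pos }
  }
  data.table(
    fragment_id = r$qname, sample = sample, kind = "SPLIT_READ",
    chrom = r$chrom, start1 = p1, end1 = p1, dir1 = d1,
    chrom2 = sa_chrom, start2 = p2, end2 = p2, dir2 = d2,
    seq = if (d1 == DIR_HEAD) substr(r$seq, nchar(r$seq) - rights + 1L, nchar(r$seq))
          else substr(r$seq, 1L, lefts),
    anchor_start = r$pos, anchor_end = r$end,
    read_strand = r$strand, mapq_local = r$mapq,
    mapq_remote = min(sa_mapq), read_seq = r$seq)
}

#' Drop evidence in ultra-high-coverage regions
#' @param evidence evidence table
#' @param reads read record table used to compute per-position depth
#' @param threshold fold-coverage cutoff (default 50000)
#' @return filtered evidence; drop count reported via message
#' @export
exclude_high_coverage <- function(evidence, reads, threshold = 50000L) {
  if (nrow(evidence) == 0L) return(evidence)
  rd <- as_read_table(reads)[mapped == TRUE]
  keep <- rep(TRUE, nrow(evidence))
  for (C in unique(evidence$chrom)) {
    rr <- rd[chrom == C]
    if (nrow(rr) == 0L) next
    cov <- IRanges::coverage(IRanges::IRanges(rr$pos, rr$end))
    mid <- pmin((evidence[chrom == C, start1] + evidence[chrom == C, end1]) %/% 2L,
                length(cov))
    mid <- pmax(mid, 1L)
    d <- as.integer(cov[mid])
    keep[evidence$chrom == C] <- d <= threshold
  }
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("exclude_high_coverage: dropped %d items above %dx",
                    dropped, threshold))
  evidence[keep]
}

#' Realign soft clips into split-read evidence
#'
#' Clipped sequences that align uniquely (effective mapq >= `min_mapq`) gain a
#' remote breakend and become SPLIT_READ items; ambiguous or unalignable
#' clips are returned unchanged.
#' @param evidence evidence table (SOFT_CLIP rows are candidates)
#' @param reference named character vector of chromosome sequences
#' @param min_mapq uniqueness threshold
#' @export
realign_soft_clips <- function(evidence, reference, min_mapq = 20L) {
  sc <- which(evidence$kind == "SOFT_CLIP" & nchar(evidence$seq) >= 20L)
  if (length(sc) == 0L) return(evidence)
  ev <- copy(evidence)
  # realign unique clip sequences once
  useq <- unique(ev$seq[sc])
  hitmap <- lapply(useq, function(s) {
    h <- align_sequence(s, reference)
    if (nrow(h) == 0L) return(NULL)
    best <- h[1]
    if (best$mapq < min_mapq || best$qend - best$qstart + 1L < nchar(s) - 2L)
      return(NULL)
    best
  })
  names(hitmap) <- useq
  for (i in sc) {
    h <- hitmap[[ev$seq[i]]]
    if (is.null(h)) next
    d1 <- ev$dir1[i]
    if (d1 == DIR_HEAD) {
      if (h$strand == "+") { d2 <- DIR_TAIL; p2 <- h$rstart }
      else { d2 <- DIR_HEAD; p2 <- h$rend }
    } else {
      if (h$strand == "+") { d2 <- DIR_HEAD; p2 <- h$rend }
      else { d2 <- DIR_TAIL; p2 <- h$rstart }
    }
    ev[i, `:=`(kind = "SPLIT_READ", chrom2 = h$chrom,
               start2 = as.integer(p2), end2 = as.integer(p2), dir2 = d2,
               mapq_remote = as.integer(h$mapq))]
  }
  ev
}
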