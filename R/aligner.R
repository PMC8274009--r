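# ---------------------------------------------------------------------------
# Built-in alignment engine: exact full-length search with a seeded
# Smith-Waterman fallback. Adequate for the multi-hundred-kilobase synthetic
# references this package targets; an external aligner can be substituted by
# providing hits in the same shape.
# ---------------------------------------------------------------------------

SW_MATCH <- 1; SW_MISMATCH <- -4; SW_GAP_OPEN <- 6; SW_GAP_EXT <- 1

sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = SW_MATCH,
                                           mismatch = SW_MISMATCH,
                                           baseOnly = FALSE)
}

#' Align a query sequence against the reference (clip-penalty-free local)
#'
#' Finds local alignments with no clipping penalty. Effective mapq encodes
#' uniqueness: 60 * (1 - second_best_score/best_score), clamped to [0, 60];
#' identical best hits at two loci give mapq 0.
#'
#' @param query DNA string
#' @param reference named character vector of chromosome sequences
#' @param max_candidates cap on candidate loci scored by Smith-Waterman
#' @return data.table(chrom, rstart, rend, strand, qstart, qend, score, mapq)
#'   sorted by decreasing score; zero rows if no hit
#' @export
align_sequence <- function(query, reference, max_candidates = 8L) {
  n <- nchar(query)
  empty <- data.table(chrom = character(), rstart = integer(),
                      rend = integer(), strand = character(),
                      qstart = integer(), qend = integer(),
                      score = numeric(), mapq = integer())
  if (n < 11L) return(empty)
  hits <- exact_hits(query, reference)
  if (nrow(hits) > 0L) {
    hits[, `:=`(qstart = 1L, qend = n, score = as.numeric(n))]
    nh <- nrow(hits)
    hits[, mapq := if (nh > 1L) 0L else 60L]
    return(hits[order(chrom, rstart)])
  }
  # seeded Smith-Waterman fallback
  slen <- min(20L, n)
  seed_offsets <- unique(pmax(1L, c(1L, (n - slen) %/% 2L + 1L, n - slen + 1L)))
  cands <- rbindlist(lapply(seed_offsets, function(o) {
    s <- substr(query, o, o + slen - 1L)
    h <- exact_hits(s, reference)
    if (nrow(h) == 0L) return(NULL)
    h[, seed_off := o]
    h
  }))
  if (is.null(cands) || nrow(cands) == 0L) return(empty)
  # candidate windows (dedupe by projected query start)
  cands[, wstart := ifelse(strand == "+", rstart - seed_off - 10L,
                           rstart - (n - (seed_off + slen - 1L)) - 10L)]
  cands <- unique(cands[, .(chrom, strand, wstart)])
  cands <- cands[, .(wstart = sort(unique(wstart))), by = .(chrom, strand)]
  cands <- cands[, .SD[c(TRUE, diff(wstart) > 15L)], by = .(chrom, strand)]
  many <- nrow(cands) > max_candidates
  cands <- head(cands, max_candidates)
  mat <- sw_submat()
  out <- rbindlist(lapply(seq_len(nrow(cands)), function(i) {
    C <- cands$chrom[i]; st <- cands$strand[i]
    ws <- max(1L, cands$wstart[i])
    we <- min(nchar(reference[[C]]), ws + n + 20L)
    win <- substr(reference[[C]], ws, we)
    q <- if (st == "+") query else revcomp(query)
    al <- Biostrings::pairwiseAlignment(q, win, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = SW_GAP_OPEN,
                                        gapExtension = SW_GAP_EXT)
    sc <- Biostrings::score(al)
    if (sc <= 0) return(NULL)
    # decompose the alignment into gapless blocks: a hit must be colinear
    # (an internal gap is a candidate junction/insert, not part of a hit)
    bl <- gapless_blocks(al, ws)
    if (is.null(bl) || nrow(bl) == 0L) return(NULL)
    if (st == "-") {
      bl[, `:=`(qs2 = n - qend + 1L, qe2 = n - qstart + 1L)]
      bl[, `:=`(qstart = qs2, qend = qe2)][, c("qs2", "qe2") := NULL]
    }
    bl[, `:=`(chrom = C, strand = st)]
    bl[, .(chrom, rstart, rend, strand, qstart, qend, score)]
  }))
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(-score, chrom, rstart)]
  # drop duplicate hits found through overlapping candidate windows
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prev <- out[which(keep[seq_len(i - 1L)])]
    ov <- prev[chrom == out$chrom[i] & strand == out$strand[i] &
                 pmin(rend, out$rend[i]) - pmax(rstart, out$rstart[i]) + 1L >=
                 0.8 * (out$rend[i] - out$rstart[i] + 1L)]
    if (nrow(ov)) keep[i] <- FALSE
  }
  out <- out[keep]
  # mapq compares only hits competing for the same query bases
  out[, mapq := 0L]
  for (i in seq_len(nrow(out))) {
    qi <- c(out$qstart[i], out$qend[i])
    comp <- out[-i][pmin(qend, qi[2]) - pmax(qstart, qi[1]) + 1L >=
                      0.5 * (qi[2] - qi[1] + 1L)]
    second <- if (nrow(comp)) max(comp$score) else 0
    if (many) second <- max(second, out$score[i])
    if (second < out$score[i] || (second == 0 && !many))
      out[i, mapq := as.integer(max(0, min(60,
        60 * (1 - second / out$score[i]))))]
  }
  out[]
}

# decompose a pairwiseAlignment into maximal gapless blocks; coordinates in
# pattern space (qstart/qend) and absolute subject space (rstart/rend)
gapless_blocks <- function(al, ws, min_block = 11L) {
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qp <- Biostrings::start(Biostrings::pattern(al)) + cumsum(pa != "-") - 1L
  sp <- Biostrings::start(Biostrings::subject(al)) + cumsum(sa != "-") - 1L
  gap <- pa == "-" | sa == "-"
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (b in which(!r$values)) {
    i1 <- starts[b]; i2 <- ends[b]
    len <- i2 - i1 + 1L
    if (len < min_block) next
    nmatch <- sum(pa[i1:i2] == sa[i1:i2])
    out[[length(out) + 1L]] <- data.table(
      qstart = qp[i1], qend = qp[i2],
      rstart = ws + sp[i1] - 1L, rend = ws + sp[i2] - 1L,
      score = nmatch * SW_MATCH + (len - nmatch) * SW_MISMATCH)
  }
  if (length(out) == 0L) return(NULL)
  rbindlist(out)
}

# exact full matches of pattern on both strands across all chromosomes
exact_hits <- function(pat, reference) {
  n <- nchar(pat)
  res <- list()
  for (C in names(reference)) {
    subj <- Biostrings::DNAString(reference[[C]])
    for (st in c("+", "-")) {
      p <- if (st == "+") pat else revcomp(pat)
      m <- Biostrings::matchPattern(Biostrings::DNAString(p), subj)
      if (length(m) > 0L)
        res[[length(res) + 1L]] <- data.table(
          chrom = C, rstart = Biostrings::start(m),
          rend = Biostrings::end(m), strand = st)
    }
  }
  if (length(res) == 0L)
    return(data.table(chrom = character(), rstart = integer(),
                      rend = integer(), strand = character()))
  rbindlist(res)
}

#' Compound realignment of a contig into a split-alignment chain
#'
#' The contig is aligned; soft-clipped remainders are fed back to the aligner
#' until all bases are aligned or no further alignment is found. Segments
#' shorter than `min_segment` bp are left unaligned (insert sequence).
#' Chains with no segment overlapping the originating locus are discarded.
#'
#' @param contig_seq contig sequence
#' @param origin list(chrom=, start=, end=) of the assembly origin
#' @param reference named character reference
#' @param min_segment minimum aligned segment length (default 30)
#' @param min_mapq segments below this effective mapq stay unaligned
#' @param origin_margin tolerance for the origin-overlap test (bp)
#' @return data.table chain of hits sorted by qstart (with mapq), or NULL if
#'   discarded; attr "unaligned" lists unaligned query intervals
#' @export
compound_realign <- function(contig_seq, origin, reference, min_segment = 30L,
                             min_mapq = 20L, origin_margin = NULL) {
  n <- nchar(contig_seq)
  if (is.null(origin_margin)) origin_margin <- 50L
  queue <- list(c(1L, n))
  hits <- list(); unaligned <- list()
  while (length(queue) > 0L) {
    iv <- queue[[1]]; queue <- queue[-1]
    len <- iv[2] - iv[1] + 1L
    if (len < min_segment) { unaligned[[length(unaligned) + 1L]] <- iv; next }
    al <- align_sequence(substr(contig_seq, iv[1], iv[2]), reference)
    if (nrow(al) == 0L || al$mapq[1] < min_mapq ||
        al$qend[1] - al$qstart[1] + 1L < min_segment) {
      unaligned[[length(unaligned) + 1L]] <- iv
      next
    }
    h <- al[1]
    h[, `:=`(qstart = iv[1] + qstart - 1L, qend = iv[1] + qend - 1L)]
    hits[[length(hits) + 1L]] <- h
    if (h$qstart > iv[1]) queue <- c(queue, list(c(iv[1], h$qstart - 1L)))
    if (h$qend < iv[2]) queue <- c(queue, list(c(h$qend + 1L, iv[2])))
  }
  if (length(hits) == 0L) return(NULL)
  chain <- rbindlist(hits)[order(qstart)]
  ok <- chain[chrom == origin$chrom &
                rstart <= origin$end + origin_margin &
                rend >= origin$start - origin_margin]
  if (nrow(ok) == 0L) return(NULL)
  attr(chain, "unaligned") <- unaligned
  chain
}

#' Adjust split bounds to minimise edit distance to the reference
#'
#' For each adjacent hit pair the query split point is moved within a window;
#' the placement minimising (mismatches in both flanks + unaligned insert
#' length) is chosen, ties broken leftmost. Never increases edit distance.
#'
#' @param chain from [compound_realign()] (>= 2 hits)
#' @param contig_seq the contig sequence
#' @param reference named character reference
#' @param window maximum shift considered per side (bp)
#' @export
adjust_split_bounds <- function(chain, contig_seq, reference, window = 10L) {
  chain <- copy(chain)
  if (nrow(chain) < 2L) return(chain)
  for (i in seq_len(nrow(chain) - 1L)) {
    A <- chain[i]; B <- chain[i + 1L]
    # mismatch cost of extending/trimming A's end by dA (query positions)
    costA <- function(dA) seg_mismatches(contig_seq, reference, A,
                                         side = "end", delta = dA)
    costB <- function(dB) seg_mismatches(contig_seq, reference, B,
                                         side = "start", delta = dB)
    best <- NULL
    for (dA in -window:window) {
      aend <- A$qend + dA
      if (aend < A$qstart) next
      cA <- costA(dA)
      if (is.na(cA)) next
      for (dB in -window:window) {
        bstart <- B$qstart + dB
        if (bstart > B$qend || bstart <= aend) next
        cB <- costB(dB)
        if (is.na(cB)) next
        cost <- cA + cB + (bstart - aend - 1L)
        key <- c(cost, aend)
        if (is.null(best) || cost < best$cost ||
            (cost == best$cost && aend < best$aend)) {
          if (is.null(best) || cost < best$cost ||
              (cost == best$cost && (aend < best$aend ||
               (aend == best$aend && bstart < best$bstart))))
            best <- list(cost = cost, dA = dA, dB = dB,
                         aend = aend, bstart = bstart)
        }
      }
    }
    if (!is.null(best) && (best$dA != 0L || best$dB != 0L)) {
      chain[i, `:=`(qend = qend + best$dA,
                    rstart = if (strand == "-") rstart - best$dA else rstart,
                    rend = if (strand == "+") rend + best$dA else rend)]
      chain[i + 1L, `:=`(qstart = qstart + best$dB,
                         rstart = if (strand == "+") rstart + best$dB else rstart,
                         rend = if (strand == "-") rend + best$dB else rend)]
    }
  }
  chain
}

# mismatches of a hit's query segment vs reference when its end/start is
# shifted by delta; NA if out of range
seg_mismatches <- function(contig_seq, reference, h, side, delta) {
  refseq <- reference[[h$chrom]]
  if (side == "end") {
    qs <- h$qstart; qe <- h$qend + delta
    if (h$strand == "+") { rs <- h$rstart; re <- h$rend + delta }
    else { rs <- h$rstart - delta; re <- h$rend }
  } else {
    qs <- h$qstart + delta; qe <- h$qend
    if (h$strand == "+") { rs <- h$rstart + delta; re <- h$rend }
    else { rs <- h$rstart; re <- h$rend + delta }
  }
  if (qs < 1L || qe > nchar(contig_seq) || rs < 1L || re > nchar(refseq) ||
      qe < qs || re < rs || (qe - qs) != (re - rs)) return(NA_integer_)
  q <- substr(contig_seq, qs, qe)
  r <- substr(refseq, rs, re)
  if (h$strand == "-") r <- revcomp(r)
  hamming(q, r)
}
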