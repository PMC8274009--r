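# ---------------------------------------------------------------------------
# Probabilistic breakpoint and single breakend calling: evidence scoring,
# two-pass maximal-clique clustering, unique evidence allocation, and the
# per-sample support breakdown.
# ---------------------------------------------------------------------------

#' Phred-scaled evidence quality
#'
#' score = min(mapq cap, -10*log10(empirical rate of the evidence
#' signature)); split reads are capped by both mapqs; discordant pairs use
#' the fragment-size tail probability when on-chromosome and in-range, the
#' discordant mapping rate otherwise; unmapped mates use the unmapped-mate
#' rate. Zero empirical rates are floored at one per observed read count.
#'
#' @param items evidence table
#' @param metrics library metrics for the items' sample
#' @return numeric phred score per item
#' @export
evidence_quality <- function(items, metrics) {
  n <- nrow(items)
  out <- numeric(n)
  phred <- function(rate) -10 * log10(rate)
  for (i in seq_len(n)) {
    it <- items[i]
    cap <- switch(it$kind,
      SPLIT_READ = min(it$mapq_local, it$mapq_remote, na.rm = TRUE),
      INDEL = it$mapq_local,
      DISCORDANT_PAIR = min(it$mapq_local, it$mapq_remote, na.rm = TRUE),
      it$mapq_local)
    rate <- switch(it$kind,
      SOFT_CLIP = cigar_tail_rate(metrics, "S", max(1L, nchar(it$seq))),
      SPLIT_READ = cigar_tail_rate(metrics, "S", max(1L, nchar(it$seq))),
      INDEL = min(cigar_tail_rate(metrics, "I", 5L) +
                    cigar_tail_rate(metrics, "D", 5L), 1),
      UNMAPPED_MATE = max(metrics$unmapped_mate_rate,
                          1 / max(metrics$n_mapped, 1L)),
      DISCORDANT_PAIR = {
        distal <- is.na(it$chrom2) || it$chrom2 != it$chrom ||
          it$dir1 == it$dir2
        if (distal) max(metrics$discordant_rate,
                        1 / max(metrics$n_mapped, 1L))
        else fragment_tail_prob(metrics, abs(it$end1 - it$start2))
      },
      1)
    out[i] <- max(0, min(cap, phred(rate)))
  }
  out
}

# ---------------------------------------------------------------------------
# Assembly contigs -> split alignment chains -> precise junctions
# ---------------------------------------------------------------------------

# breakend of hit `h` on its query-end (side="end") or query-start side
hit_breakend <- function(h, side) {
  if (side == "end") {
    if (h$strand == "+") list(chrom = h$chrom, pos = h$rend, dir = DIR_HEAD)
    else list(chrom = h$chrom, pos = h$rstart, dir = DIR_TAIL)
  } else {
    if (h$strand == "+") list(chrom = h$chrom, pos = h$rstart, dir = DIR_TAIL)
    else list(chrom = h$chrom, pos = h$rend, dir = DIR_HEAD)
  }
}

#' Realign contigs and extract their junctions
#'
#' Each contig is compound-realigned into a split alignment chain with
#' edit-distance-minimising split bounds; adjacent alignment pairs yield
#' precise breakpoint junctions (left-aligned over their exact homology).
#' Contigs whose breakend sequence has no unique alignment yield single
#' breakend junctions instead.
#'
#' @param contigs list of `svkit_contig`
#' @param reference named character reference
#' @param min_novel minimum unaligned novel bases for a single breakend
#' @return list(chains, bp = breakpoint junction table, be = breakend table)
#' @export
contig_junctions <- function(contigs, reference, min_novel = 20L) {
  chains <- list(); bp <- list(); be <- list()
  for (ct in contigs) {
    origin <- list(chrom = ct$chrom, start = ct$anchor_ref[1],
                   end = ct$anchor_ref[2])
    ch <- compound_realign(ct$seq, origin, reference)
    if (is.null(ch)) ch_n <- 0L else {
      ch <- adjust_split_bounds(ch, ct$seq, reference)
      ch_n <- nrow(ch)
    }
    if (ch_n >= 1L) chains[[ct$id]] <- ch
    if (ch_n >= 2L) {
      for (j in seq_len(ch_n - 1L)) {
        A <- ch[j]; B <- ch[j + 1L]
        b1 <- hit_breakend(A, "end"); b2 <- hit_breakend(B, "start")
        ins <- if (B$qstart > A$qend + 1L)
          substr(ct$seq, A$qend + 1L, B$qstart - 1L) else ""
        # canonical breakend order (junction is symmetric; flipping
        # reverse-complements the untemplated insert)
        if (b2$chrom < b1$chrom ||
            (b2$chrom == b1$chrom && b2$pos < b1$pos)) {
          tmp <- b1; b1 <- b2; b2 <- tmp
          if (nchar(ins)) ins <- revcomp(ins)
          tmpq <- A$mapq; A$mapq <- B$mapq; B$mapq <- tmpq
        }
        # a HEAD->TAIL junction joining adjacent reference positions with no
        # insert is the reference allele (a split alignment artefact of a
        # reference-supporting contig); such assemblies are ignored
        if (b1$chrom == b2$chrom && b1$dir == DIR_HEAD &&
            b2$dir == DIR_TAIL && b2$pos - b1$pos == 1L && !nchar(ins))
          next
        hom <- exact_homology(b1$chrom, b1$pos, b1$dir,
                              b2$chrom, b2$pos, b2$dir,
                              reference, insert_len = nchar(ins))
        bp[[length(bp) + 1L]] <- data.table(
          contig_id = ct$id, chrom1 = b1$chrom, pos1 = hom$pos1,
          dir1 = b1$dir, chrom2 = b2$chrom, pos2 = hom$pos2, dir2 = b2$dir,
          insert = ins, homlen = hom$homlen, homseq = hom$homseq,
          cipos1_lo = hom$cipos[1], cipos1_hi = hom$cipos[2],
          cipos2_lo = hom$cirpos[1], cipos2_hi = hom$cirpos[2],
          mapq1 = A$mapq, mapq2 = B$mapq, seg_index = j,
          n_segs = ch_n)
      }
    } else {
      # unaligned or single-hit contig: candidate single breakend
      novel <- ct$breakend_seq
      if (nchar(novel) >= min_novel) {
        al <- align_sequence(novel, reference)
        bealn <- if (nrow(al) == 0L) "" else
          paste(sprintf("%s:%d|%s|%d", head(al$chrom, 3L),
                        head(al$rstart, 3L), head(al$strand, 3L),
                        head(al$mapq, 3L)), collapse = ",")
        be[[length(be) + 1L]] <- data.table(
          contig_id = ct$id, chrom = ct$chrom, pos = ct$junction,
          dir = ct$dir, breakend_seq = novel, bealn = bealn)
      }
    }
  }
  list(chains = chains,
       bp = rbindlist(bp),
       be = rbindlist(be))
}

# canonical ordering of a junction's two breakends
canonical_bp <- function(dt) {
  flip <- dt$chrom2 < dt$chrom1 | (dt$chrom2 == dt$chrom1 & dt$pos2 < dt$pos1)
  if (!any(flip)) return(dt)
  f <- which(flip)
  swap <- function(a, b) {
    tmp <- dt[[a]][f]
    dt[f, (a) := dt[[b]][f]][f, (b) := tmp]
  }
  for (cols in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                    c("dir1", "dir2"), c("start1", "start2"),
                    c("end1", "end2"), c("cipos1_lo", "cipos2_lo"),
                    c("cipos1_hi", "cipos2_hi"), c("mapq1", "mapq2")))
    if (all(cols %in% names(dt))) swap(cols[1], cols[2])
  dt
}

#' Enumerate candidate variants as maximal cliques of compatible evidence
#'
#' Two items are compatible iff their local interval and direction overlap
#' and, for two-ended items, the remote interval and direction also overlap.
#' Returns one candidate per maximal clique with the intersection intervals.
#'
#' @param items table with eid, c1, s1, e1, d1 and optionally c2, s2, e2, d2
#' @return list(candidates = data.table, membership = list of eid vectors)
#' @export
enumerate_candidates <- function(items) {
  if (nrow(items) == 0L)
    return(list(candidates = data.table(), membership = list()))
  it <- copy(items)
  it[, vid := .I]
  two_ended <- "c2" %in% names(it) && any(!is.na(it$c2))
  pairs <- CJ(vid = it$vid, vid2 = it$vid)[vid < vid2]
  pairs <- merge(pairs, it[, .(vid, c1, d1, s1, e1, c2, d2, s2, e2)],
                 by = "vid")
  pairs <- merge(pairs, it[, .(vid2 = vid, c1b = c1, d1b = d1, s1b = s1,
                               e1b = e1, c2b = c2, d2b = d2, s2b = s2,
                               e2b = e2)], by = "vid2")
  pairs <- pairs[c1 == c1b & d1 == d1b & iv_overlaps(s1, e1, s1b, e1b)]
  if (two_ended)
    pairs <- pairs[(is.na(c2) & is.na(c2b)) |
                     (!is.na(c2) & !is.na(c2b) & c2 == c2b & d2 == d2b &
                        iv_overlaps(s2, e2, s2b, e2b))]
  g <- igraph::make_empty_graph(n = nrow(it), directed = FALSE)
  if (nrow(pairs))
    g <- igraph::add_edges(g, rbind(pairs$vid, pairs$vid2))
  cl <- igraph::max_cliques(g, min = 1L)
  cands <- rbindlist(lapply(seq_along(cl), function(ci) {
    mem <- it[as.integer(cl[[ci]])]
    out <- data.table(cand = ci, c1 = mem$c1[1], d1 = mem$d1[1],
                      s1 = max(mem$s1), e1 = min(mem$e1),
                      n_items = nrow(mem))
    if (two_ended) {
      out[, `:=`(c2 = mem$c2[1], d2 = mem$d2[1],
                 s2 = suppressWarnings(max(mem$s2)),
                 e2 = suppressWarnings(min(mem$e2)))]
    }
    out
  }))
  list(candidates = cands,
       membership = lapply(cl, function(v) it$eid[as.integer(v)]))
}

#' Uniquely allocate evidence to candidates
#'
#' Preference order per item: (1) a candidate supported by an assembly contig
#' containing that item's fragment, (2) the highest pre-allocation clique
#' score, (3) leftmost candidate position. Returns the allocation map and the
#' pre-allocation score (CQ) per candidate.
#'
#' @param cands candidate table from [enumerate_candidates()]
#' @param membership list of eid vectors per candidate
#' @param items evidence table with `qual` column
#' @param asm_frags named list: candidate index -> fragment ids contained in
#'   assemblies supporting that candidate
#' @return data.table(eid, cand)
#' @export
allocate_evidence <- function(cands, membership, items, asm_frags = NULL) {
  if (nrow(items) == 0L || length(membership) == 0L)
    return(data.table(eid = character(), cand = integer()))
  memdt <- rbindlist(lapply(seq_along(membership), function(ci)
    data.table(cand = ci, eid = membership[[ci]])))
  memdt <- merge(memdt, items[, .(eid, fragment_id, qual)], by = "eid")
  cq <- memdt[, .(cq = sum(qual)), by = cand]
  memdt <- merge(memdt, cq, by = "cand")
  memdt <- merge(memdt, cands[, .(cand, s1)], by = "cand")
  memdt[, asm := FALSE]
  if (!is.null(asm_frags)) {
    for (ci in as.integer(names(asm_frags)))
      memdt[cand == ci & fragment_id %in% asm_frags[[as.character(ci)]],
            asm := TRUE]
  }
  setorder(memdt, eid, -asm, -cq, s1, cand)
  alloc <- memdt[, .SD[1], by = eid][, .(eid, cand)]
  alloc
}
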