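# ---------------------------------------------------------------------------
# End-to-end somatic SV calling pipeline.
# ---------------------------------------------------------------------------

#' Calling parameters
#' @param k assembly kmer size
#' @param min_fragments minimum unique supporting fragments per call
#' @param min_event_size minimum intrachromosomal event size (bp);
#'   inversion-like breakpoints are exempt
#' @param min_mapq mapping quality below which reads are treated as unmapped
#' @param min_clip minimum soft/hard clip length considered (bp)
#' @param entropy_threshold minimum read sequence entropy (bits)
#' @param high_coverage_threshold evidence above this depth is ignored
#' @param cluster_slop interval slop when testing precise evidence
#'   compatibility (bp)
#' @export
call_params <- function(k = 25L, min_fragments = 2L, min_event_size = 10L,
                        min_mapq = 20L, min_clip = 5L,
                        entropy_threshold = 0.5,
                        high_coverage_threshold = 50000L,
                        cluster_slop = 15L) {
  list(k = as.integer(k), min_fragments = as.integer(min_fragments),
       min_event_size = as.integer(min_event_size),
       min_mapq = as.integer(min_mapq), min_clip = as.integer(min_clip),
       entropy_threshold = entropy_threshold,
       high_coverage_threshold = as.integer(high_coverage_threshold),
       cluster_slop = as.integer(cluster_slop))
}

#' Call structural variants from tumour/normal alignments
#'
#' Runs the full pipeline: library metrics, evidence extraction, soft-clip
#' realignment, positional de Bruijn breakend assembly, compound contig
#' realignment, two-pass maximal-clique calling with unique evidence
#' allocation, homology annotation and the per-sample support breakdown.
#'
#' @param tumour,normal SAM paths or read record tables (normal may be NULL
#'   for tumour-only calling)
#' @param reference FASTA path, `svkit_genome` or named character vector
#' @param params from [call_params()]
#' @return list(calls, contigs, chains, evidence, metrics)
#' @export
call_structural_variants <- function(tumour, normal = NULL, reference,
                                     params = call_params()) {
  ref <- load_reference(reference)
  rt <- as_read_table(tumour)
  mt <- estimate_library_metrics(rt)
  evl <- list(classify_reads(rt, mt, sample = "T",
                             min_clip = params$min_clip,
                             min_mapq = params$min_mapq,
                             entropy_threshold = params$entropy_threshold))
  reads_by_sample <- list(T = rt)
  mets <- list(T = mt)
  if (!is.null(normal)) {
    rn <- as_read_table(normal)
    mn <- estimate_library_metrics(rn)
    evl$N <- classify_reads(rn, mn, sample = "N",
                            min_clip = params$min_clip,
                            min_mapq = params$min_mapq,
                            entropy_threshold = params$entropy_threshold)
    reads_by_sample$N <- rn
    mets$N <- mn
  }
  ev <- rbindlist(evl, use.names = TRUE, fill = TRUE)
  ev <- exclude_high_coverage(ev, rbindlist(reads_by_sample, fill = TRUE),
                              params$high_coverage_threshold)
  ev <- realign_soft_clips(ev, ref, min_mapq = params$min_mapq)
  ev[, qual := 0]
  for (s in names(mets))
    if (nrow(ev[sample == s]))
      ev[sample == s, qual := evidence_quality(.SD, mets[[s]])]

  ev <- cluster_evidence(ev, gap = mets$T$read_length)
  contigs <- assemble_breakends(ev, mets$T, k = params$k)
  cj <- contig_junctions(contigs, ref)
  res <- build_calls(ev, contigs, cj, reads_by_sample, mets, ref, params)
  res$contigs <- contigs
  res$chains <- cj$chains
  res$junctions <- cj$bp
  res$evidence <- ev
  res$metrics <- mets
  res
}

#' Full somatic SV calling and filtering pipeline
#'
#' Runs [call_structural_variants()], derives assembly/SC/transitive phase
#' links, collapses transitive calls, annotates simple events, and applies
#' the somatic filter with optional panel of normals.
#'
#' @inheritParams call_structural_variants
#' @param pon optional panel of normals from [build_pon()]
#' @return list(calls (filtered), high, low, links, events, collapsed, plus
#'   the raw-calling outputs)
#' @export
somatic_sv_pipeline <- function(tumour, normal = NULL, reference,
                                params = call_params(), pon = NULL) {
  ref <- load_reference(reference)
  res <- call_structural_variants(tumour, normal, ref, params)
  calls <- res$calls
  if (nrow(calls) == 0L) {
    res$high <- calls; res$low <- calls; res$links <- empty_links()
    return(res)
  }
  window <- as.integer(1.5 * res$metrics$T$max_fragment)
  links <- rbind(assembly_links(res$chains, res$junctions, calls),
                 sc_trans_links(calls, window = window))
  tc <- transitive_collapse(calls)
  links <- rbind(links, tc$links)
  events <- annotate_events(calls, ref)
  eq <- events[kind == "EQUIVALENT"]
  all_links <- links
  if (nrow(eq))
    all_links <- rbind(links, eq[, .(link_id = paste0("eq_", .I),
                                     kind = "EQUIVALENT", id1, id2,
                                     provenance = "equivalence")])
  filtered <- somatic_filter(calls, links = all_links, pon = pon,
                             reference = ref, collapsed = tc$collapsed)
  sets <- emit_call_sets(filtered)
  res$calls <- filtered
  res$links <- links
  res$events <- events
  res$collapsed <- tc$collapsed
  res$high <- sets$high
  res$low <- sets$low
  res
}

# ---------------------------------------------------------------------------

# clique items for the breakpoint pass
bp_clique_items <- function(ev, cj, slop) {
  items <- list()
  raw <- ev[kind %in% c("SPLIT_READ", "INDEL") & !is.na(chrom2)]
  if (nrow(raw))
    items$raw <- data.table(
      eid = raw$eid, fragment_id = raw$fragment_id, sample = raw$sample,
      kind = raw$kind, qual = raw$qual,
      c1 = raw$chrom, s1 = raw$start1 - slop, e1 = raw$end1 + slop,
      d1 = raw$dir1, c2 = raw$chrom2, s2 = raw$start2 - slop,
      e2 = raw$end2 + slop, d2 = raw$dir2, precise = FALSE,
      contig_id = NA_character_, read_strand = raw$read_strand)
  dp <- ev[kind == "DISCORDANT_PAIR"]
  if (nrow(dp))
    items$dp <- data.table(
      eid = dp$eid, fragment_id = dp$fragment_id, sample = dp$sample,
      kind = dp$kind, qual = dp$qual,
      c1 = dp$chrom, s1 = dp$start1, e1 = dp$end1, d1 = dp$dir1,
      c2 = dp$chrom2, s2 = dp$start2, e2 = dp$end2, d2 = dp$dir2,
      precise = FALSE, contig_id = NA_character_,
      read_strand = dp$read_strand)
  if (nrow(cj$bp))
    items$asm <- data.table(
      eid = paste0("asm_", cj$bp$contig_id, "_", cj$bp$seg_index),
      fragment_id = NA_character_, sample = NA_character_,
      kind = "ASSEMBLY_BP", qual = 0,
      c1 = cj$bp$chrom1, s1 = cj$bp$pos1 + cj$bp$cipos1_lo - slop,
      e1 = cj$bp$pos1 + cj$bp$cipos1_hi + slop, d1 = cj$bp$dir1,
      c2 = cj$bp$chrom2, s2 = cj$bp$pos2 + cj$bp$cipos2_lo - slop,
      e2 = cj$bp$pos2 + cj$bp$cipos2_hi + slop, d2 = cj$bp$dir2,
      precise = TRUE, contig_id = cj$bp$contig_id,
      read_strand = NA_character_)
  out <- rbindlist(items, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) return(out)
  canonical_items(out)
}

# order each item's two breakends canonically (lower chrom/interval first)
canonical_items <- function(it) {
  flip <- !is.na(it$c2) &
    (it$c2 < it$c1 | (it$c2 == it$c1 & it$s2 < it$s1))
  if (any(flip)) {
    f <- which(flip)
    for (cols in list(c("c1", "c2"), c("s1", "s2"), c("e1", "e2"),
                      c("d1", "d2"))) {
      tmp <- it[[cols[1]]][f]
      it[f, (cols[1]) := it[[cols[2]]][f]][f, (cols[2]) := tmp]
    }
  }
  it
}

sv_class <- function(c1, c2, d1, d2, pos1, pos2, insert) {
  if (is.na(c2)) return("BND")
  if (c1 != c2) return("CTX")
  if (d1 == d2) return("INV")
  if (d1 == DIR_HEAD && d2 == DIR_TAIL) {
    if (pos2 - pos1 - 1L <= nchar(insert)) "INS" else "DEL"
  } else "DUP"
}

event_size <- function(svtype, pos1, pos2, insert) {
  switch(svtype,
         DEL = pos2 - pos1 - 1L,
         DUP = pos2 - pos1 + 1L,
         INV = pos2 - pos1,
         INS = nchar(insert),
         NA_integer_)
}

build_calls <- function(ev, contigs, cj, reads_by_sample, mets, ref, params) {
  slop <- params$cluster_slop
  contigs_by_id <- setNames(contigs, vapply(contigs, `[[`, "", "id"))
  items <- bp_clique_items(ev, cj, slop)
  samples <- names(reads_by_sample)

  bp_calls <- data.table()
  consumed <- character(0)
  if (nrow(items)) {
    enum <- enumerate_candidates(items)
    cands <- enum$candidates
    # assembly-contained fragments per candidate
    asm_frags <- list()
    for (ci in seq_along(enum$membership)) {
      cids <- items[eid %in% enum$membership[[ci]] & !is.na(contig_id),
                    contig_id]
      if (length(cids)) {
        fr <- unique(unlist(lapply(contigs_by_id[cids],
                                   function(ct) ct$support$fragment_id)))
        asm_frags[[as.character(ci)]] <- fr
      }
    }
    alloc <- allocate_evidence(cands, enum$membership, items, asm_frags)
    cq_pre <- merge(
      rbindlist(lapply(seq_along(enum$membership), function(ci)
        data.table(cand = ci, eid = enum$membership[[ci]]))),
      items[, .(eid, qual)], by = "eid")[, .(cq = sum(qual)), by = cand]
    bp_calls <- assemble_bp_calls(ev, items, cands, alloc, cq_pre,
                                  contigs_by_id, cj, reads_by_sample, mets,
                                  ref, params)
    if (nrow(bp_calls)) {
      consumed <- unique(unlist(strsplit(
        bp_calls[, paste(t_frags, n_frags, collapse = ",")], ",")))
      consumed <- consumed[nzchar(consumed)]
    }
  }
  be_calls <- assemble_be_calls(ev, cj, contigs_by_id, consumed, bp_calls,
                                reads_by_sample, mets, ref, params)
  calls <- rbindlist(list(bp_calls, be_calls), use.names = TRUE, fill = TRUE)
  if (nrow(calls)) {
    calls[, id := sprintf("svk%04d", .I)]
    setcolorder(calls, "id")
  }
  list(calls = calls)
}

# spanning fragments of a contig given the homology interval in contig cols
contig_spanning <- function(ct, homlen) {
  hom <- c(ct$junction_col, ct$junction_col + max(0L, homlen))
  ct$support[cs <= hom[1] - 1L & ce >= hom[2] + 1L]
}

# reference-supporting reads/pairs spanning the homology interval
ref_support <- function(reads, ch, jpos, homlen, exclude_frags) {
  p_lo <- jpos; p_hi <- jpos + max(0L, homlen)
  win <- reads[chrom == ch & mapped == TRUE &
                 pos <= p_hi + 1L & end >= p_lo - 1L]
  win <- win[!qname %in% exclude_frags]
  refr <- win[pos <= p_lo - 1L & end >= p_hi + 1L & !grepl("S", cigar)]
  nref <- length(unique(refr$qname))
  # pairs whose fragment spans but whose reads do not individually
  pr <- reads[chrom == ch & proper == TRUE & tlen > 0L &
                pos <= p_lo - 1L & (pos + tlen - 1L) >= p_hi + 1L]
  pr <- pr[!qname %in% c(exclude_frags, refr$qname)]
  pr <- pr[end < p_lo | pos > p_hi]
  list(ref = nref, refpair = length(unique(pr$qname)))
}

assemble_bp_calls <- function(ev, items, cands, alloc, cq_pre,
                              contigs_by_id, cj, reads_by_sample, mets, ref,
                              params) {
  samples <- names(reads_by_sample)
  calls <- list()
  for (ci in cands$cand) {
    mem <- items[eid %in% alloc[cand == ci, eid]]
    if (nrow(mem) == 0L) next
    asm <- mem[kind == "ASSEMBLY_BP"]
    precise <- nrow(asm) > 0L
    if (precise) {
      # junction from the contig with the most support
      jrows <- cj$bp[paste0("asm_", contig_id, "_", seg_index) %in% asm$eid]
      nsup <- vapply(jrows$contig_id, function(id)
        nrow(contigs_by_id[[id]]$support), 1L)
      j <- jrows[which.max(nsup)]
      pos1 <- j$pos1; pos2 <- j$pos2
      c1 <- j$chrom1; c2 <- j$chrom2; d1 <- j$dir1; d2 <- j$dir2
      insert <- j$insert; homlen <- j$homlen; homseq <- j$homseq
      cipos1 <- c(j$cipos1_lo, j$cipos1_hi)
      cipos2 <- c(j$cipos2_lo, j$cipos2_hi)
    } else {
      cr <- cands[cand == ci]
      if (!("c2" %in% names(cr)) || is.na(cr$c2)) next
      c1 <- cr$c1; c2 <- cr$c2; d1 <- cr$d1; d2 <- cr$d2
      s1 <- min(cr$s1, cr$e1); e1 <- max(cr$s1, cr$e1)
      s2 <- min(cr$s2, cr$e2); e2 <- max(cr$s2, cr$e2)
      pos1 <- s1; pos2 <- s2
      insert <- ""; homlen <- 0L; homseq <- ""
      cipos1 <- c(0L, e1 - s1); cipos2 <- c(0L, e2 - s2)
    }
    # supporting assemblies and their spanning fragments
    acids <- unique(asm$contig_id)
    span_fr <- list()
    asm_reads <- data.table()
    for (id in acids) {
      ct <- contigs_by_id[[id]]
      sp <- contig_spanning(ct, homlen)
      span_fr[[id]] <- sp
    }
    span <- rbindlist(span_fr)
    direct <- mem[kind != "ASSEMBLY_BP"]
    row <- list(type = "BP", chrom1 = c1, pos1 = as.integer(pos1), dir1 = d1,
                chrom2 = c2, pos2 = as.integer(pos2), dir2 = d2,
                insert = insert, imprecise = !precise,
                cipos1_lo = cipos1[1], cipos1_hi = cipos1[2],
                cipos2_lo = cipos2[1], cipos2_hi = cipos2[2],
                homlen = as.integer(homlen), homseq = homseq,
                beid = paste(acids, collapse = ","))
    svt <- sv_class(c1, c2, d1, d2, pos1, pos2, insert)
    row$svtype <- svt
    row$size <- event_size(svt, pos1, pos2, insert)
    # read pairs carry no positional information about events smaller than
    # the spread of the concordant fragment-size distribution; excluding
    # them stops concordant-tail pairs (classified discordant by the 99.5%
    # rule) from contaminating short-event support in either sample
    frag_spread <- max(vapply(mets, function(mm)
      mm$concordant_hi - mm$concordant_lo, 1L))
    short_event <- !is.na(row$size) && svt %in% c("DEL", "DUP", "INS") &&
      row$size < frag_spread
    if (precise) {
      ih <- inexact_homology(c1, pos1, d1, c2, pos2, d2, ref,
                             insert_seq = insert)
      row$ihompos_lo <- ih[1]; row$ihompos_hi <- ih[2]
    } else {
      row$ihompos_lo <- NA_integer_; row$ihompos_hi <- NA_integer_
    }
    qual_total <- 0
    sb_num <- 0L; sb_den <- 0L
    all_frags <- list()
    for (s in samples) {
      sp_s <- if (nrow(span)) span[sample == s] else span
      dir_s <- direct[sample == s]
      if (short_event) dir_s <- dir_s[kind != "DISCORDANT_PAIR"]
      fr_asm <- unique(sp_s$fragment_id)
      dir_only <- dir_s[!fragment_id %in% fr_asm]
      sup_ev <- copy(dir_s)
      # assembled member evidence quality (capped by contig alignment mapqs)
      asmq <- 0
      if (length(fr_asm)) {
        evs <- ev[fragment_id %in% fr_asm & sample == s &
                    kind %in% c("SOFT_CLIP", "SPLIT_READ", "UNMAPPED_MATE",
                                "DISCORDANT_PAIR")]
        asmq <- sum(pmin(evs$qual, 60))
      }
      kinds_sc <- c("SOFT_CLIP", "SPLIT_READ", "INDEL")
      assr <- if (nrow(sp_s)) sum(vapply(strsplit(sp_s$kinds, ","),
        function(kk) any(kk %in% kinds_sc), TRUE)) else 0L
      asrp <- if (nrow(sp_s)) sum(vapply(strsplit(sp_s$kinds, ","),
        function(kk) any(kk %in% c("UNMAPPED_MATE", "DISCORDANT_PAIR")), TRUE))
        else 0L
      srq <- dir_only[kind == "SPLIT_READ", sum(qual)]
      rpq <- dir_only[kind == "DISCORDANT_PAIR", sum(qual)]
      iq <- dir_only[kind == "INDEL", sum(qual)]
      vf_frags <- unique(c(fr_asm, dir_s$fragment_id))
      all_frags[[s]] <- vf_frags
      rs1 <- ref_support(reads_by_sample[[s]], c1, pos1, homlen, vf_frags)
      rs2 <- ref_support(reads_by_sample[[s]], c2, pos2, homlen, vf_frags)
      sbs <- dir_s[kind %in% c("SPLIT_READ"), read_strand]
      if (nrow(sp_s)) sbs <- c(sbs, unlist(strsplit(sp_s$strands, "")))
      sb_num <- sb_num + sum(sbs == "+"); sb_den <- sb_den + length(sbs)
      qual_s <- asmq + srq + rpq + iq
      qual_total <- qual_total + qual_s
      pre <- tolower(s)
      row[[paste0(pre, "_as")]] <- length(acids)
      row[[paste0(pre, "_assr")]] <- as.integer(assr)
      row[[paste0(pre, "_asrp")]] <- as.integer(asrp)
      row[[paste0(pre, "_sr")]] <- dir_s[kind == "SPLIT_READ", .N]
      row[[paste0(pre, "_rp")]] <- dir_s[kind == "DISCORDANT_PAIR", .N]
      row[[paste0(pre, "_ic")]] <- dir_s[kind == "INDEL", .N]
      row[[paste0(pre, "_asq")]] <- asmq
      row[[paste0(pre, "_srq")]] <- srq
      row[[paste0(pre, "_rpq")]] <- rpq
      row[[paste0(pre, "_iq")]] <- iq
      row[[paste0(pre, "_qual")]] <- qual_s
      row[[paste0(pre, "_vf")]] <- length(vf_frags)
      row[[paste0(pre, "_ref")]] <- rs1$ref
      row[[paste0(pre, "_refpair")]] <- rs1$refpair
      row[[paste0(pre, "_ref2")]] <- rs2$ref
      row[[paste0(pre, "_refpair2")]] <- rs2$refpair
      row[[paste0(pre, "_frags")]] <- paste(vf_frags, collapse = ",")
    }
    if (!"N" %in% samples) {
      for (f in c("as", "assr", "asrp", "sr", "rp", "ic", "vf", "ref",
                  "refpair", "ref2", "refpair2"))
        row[[paste0("n_", f)]] <- 0L
      for (f in c("asq", "srq", "rpq", "iq", "qual")) row[[paste0("n_", f)]] <- 0
      row$n_frags <- ""
    }
    row$qual <- qual_total
    row$cq <- cq_pre[cand == ci, cq]
    row$sb <- if (sb_den > 0L) sb_num / sb_den else 0.5
    # total unique fragment check
    nf <- length(unique(unlist(all_frags)))
    if (nf < params$min_fragments) next
    # minimum event size (inversion-like exempt)
    if (!is.na(row$size) && row$svtype %in% c("DEL", "DUP", "INS") &&
        max(row$size, nchar(insert)) < params$min_event_size) next
    # anchor extents (SC): contig anchor lengths per end
    row$anchor1 <- max(c(0L, vapply(acids, function(id) {
      ct <- contigs_by_id[[id]]
      if (ct$chrom == c1 && ct$dir == d1 &&
          abs(ct$junction - pos1) <= homlen + 20L)
        ct$anchor_ref[2] - ct$anchor_ref[1] + 1L else 0L
    }, 1L)))
    row$anchor2 <- max(c(0L, vapply(acids, function(id) {
      ct <- contigs_by_id[[id]]
      if (ct$chrom == c2 && ct$dir == d2 &&
          abs(ct$junction - pos2) <= homlen + 20L)
        ct$anchor_ref[2] - ct$anchor_ref[1] + 1L else 0L
    }, 1L)))
    calls[[length(calls) + 1L]] <- as.data.table(row)
  }
  out <- rbindlist(calls, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) return(out)
  dedupe_calls(out)
}

# collapse duplicate calls at the same canonical junction (keep highest QUAL)
dedupe_calls <- function(calls) {
  calls[, key := paste(chrom1, pos1, dir1, chrom2, pos2, dir2)]
  setorder(calls, key, -qual)
  out <- calls[, .SD[1], by = key][, key := NULL]
  # also collapse near-identical junctions within homology slop
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L) {
    setorder(out, chrom1, pos1)
    for (i in seq_len(nrow(out))[-1]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        same <- out$chrom1[i] == out$chrom1[j] &&
          out$chrom2[i] == out$chrom2[j] &&
          out$dir1[i] == out$dir1[j] && out$dir2[i] == out$dir2[j] &&
          abs(out$pos1[i] - out$pos1[j]) <= max(out$homlen[i], out$homlen[j], 5L) &&
          abs(out$pos2[i] - out$pos2[j]) <= max(out$homlen[i], out$homlen[j], 5L)
        if (same) {
          keep[if (out$qual[i] >= out$qual[j]) j else i] <- FALSE
          break
        }
      }
    }
  }
  out[keep]
}

assemble_be_calls <- function(ev, cj, contigs_by_id, consumed, bp_calls,
                              reads_by_sample, mets, ref, params) {
  slop <- params$cluster_slop
  samples <- names(reads_by_sample)
  items <- list()
  sc <- ev[kind == "SOFT_CLIP" & !fragment_id %in% consumed]
  if (nrow(sc))
    items$sc <- data.table(eid = sc$eid, fragment_id = sc$fragment_id,
                           sample = sc$sample, kind = sc$kind, qual = sc$qual,
                           c1 = sc$chrom, s1 = sc$start1 - slop,
                           e1 = sc$end1 + slop, d1 = sc$dir1,
                           contig_id = NA_character_,
                           read_strand = sc$read_strand)
  um <- ev[kind == "UNMAPPED_MATE" & !fragment_id %in% consumed]
  if (nrow(um))
    items$um <- data.table(eid = um$eid, fragment_id = um$fragment_id,
                           sample = um$sample, kind = um$kind, qual = um$qual,
                           c1 = um$chrom, s1 = um$start1, e1 = um$end1,
                           d1 = um$dir1, contig_id = NA_character_,
                           read_strand = um$read_strand)
  if (nrow(cj$be))
    items$asm <- data.table(eid = paste0("asmbe_", cj$be$contig_id),
                            fragment_id = NA_character_,
                            sample = NA_character_, kind = "ASSEMBLY_BE",
                            qual = 0, c1 = cj$be$chrom,
                            s1 = cj$be$pos - slop, e1 = cj$be$pos + slop,
                            d1 = cj$be$dir, contig_id = cj$be$contig_id,
                            read_strand = NA_character_)
  items <- rbindlist(items, use.names = TRUE, fill = TRUE)
  if (nrow(items) == 0L) return(data.table())
  items[, `:=`(c2 = NA_character_, s2 = NA_integer_, e2 = NA_integer_,
               d2 = NA_character_)]
  enum <- enumerate_candidates(items)
  cands <- enum$candidates
  asm_frags <- list()
  for (ci in seq_along(enum$membership)) {
    cids <- items[eid %in% enum$membership[[ci]] & !is.na(contig_id),
                  contig_id]
    if (length(cids))
      asm_frags[[as.character(ci)]] <- unique(unlist(lapply(
        contigs_by_id[cids], function(ct) ct$support$fragment_id)))
  }
  alloc <- allocate_evidence(cands, enum$membership, items, asm_frags)
  calls <- list()
  for (ci in cands$cand) {
    mem <- items[eid %in% alloc[cand == ci, eid]]
    if (nrow(mem) == 0L) next
    asm <- mem[kind == "ASSEMBLY_BE"]
    if (nrow(asm) == 0L) next   # single breakends require an assembly
    acids <- unique(asm$contig_id)
    bej <- cj$be[contig_id %in% acids]
    best <- bej[which.max(nchar(breakend_seq))]
    pos <- best$pos; c1 <- best$chrom; d1 <- best$dir
    # suppress if a breakpoint call already explains this breakend
    if (nrow(bp_calls)) {
      nearby <- bp_calls[(chrom1 == c1 & dir1 == d1 & abs(pos1 - pos) <= 10L) |
                         (chrom2 == c1 & dir2 == d1 & abs(pos2 - pos) <= 10L)]
      if (nrow(nearby)) next
    }
    direct <- mem[kind %in% c("SOFT_CLIP", "UNMAPPED_MATE")]
    span <- rbindlist(lapply(acids, function(id)
      contig_spanning(contigs_by_id[[id]], 0L)))
    row <- list(type = "BE", chrom1 = c1, pos1 = as.integer(pos), dir1 = d1,
                chrom2 = NA_character_, pos2 = NA_integer_,
                dir2 = NA_character_, insert = "", imprecise = FALSE,
                cipos1_lo = 0L, cipos1_hi = 0L, cipos2_lo = NA_integer_,
                cipos2_hi = NA_integer_, homlen = 0L, homseq = "",
                svtype = "BND", size = NA_integer_,
                breakend_seq = best$breakend_seq, bealn = best$bealn,
                beid = paste(acids, collapse = ","))
    qual_total <- 0; sb_num <- 0L; sb_den <- 0L
    for (s in samples) {
      sp_s <- if (nrow(span)) span[sample == s] else span
      dir_s <- direct[sample == s]
      fr_asm <- unique(sp_s$fragment_id)
      dir_only <- dir_s[!fragment_id %in% fr_asm]
      evs <- ev[fragment_id %in% fr_asm & sample == s &
                  kind %in% c("SOFT_CLIP", "UNMAPPED_MATE")]
      baq <- sum(pmin(evs$qual, 60))
      bscq <- dir_only[kind == "SOFT_CLIP", sum(qual)]
      bumq <- dir_only[kind == "UNMAPPED_MATE", sum(qual)]
      kinds_sc <- c("SOFT_CLIP", "SPLIT_READ")
      bassr <- if (nrow(sp_s)) sum(vapply(strsplit(sp_s$kinds, ","),
        function(kk) any(kk %in% kinds_sc), TRUE)) else 0L
      basrp <- if (nrow(sp_s)) sum(vapply(strsplit(sp_s$kinds, ","),
        function(kk) any(kk %in% c("UNMAPPED_MATE", "DISCORDANT_PAIR")),
        TRUE)) else 0L
      vf_frags <- unique(c(fr_asm, dir_s$fragment_id))
      rs <- ref_support(reads_by_sample[[s]], c1, pos, 0L, vf_frags)
      sbs <- dir_s[kind == "SOFT_CLIP", read_strand]
      if (nrow(sp_s)) sbs <- c(sbs, unlist(strsplit(sp_s$strands, "")))
      sb_num <- sb_num + sum(sbs == "+"); sb_den <- sb_den + length(sbs)
      qs <- baq + bscq + bumq
      qual_total <- qual_total + qs
      pre <- tolower(s)
      row[[paste0(pre, "_ba")]] <- length(acids)
      row[[paste0(pre, "_bassr")]] <- as.integer(bassr)
      row[[paste0(pre, "_basrp")]] <- as.integer(basrp)
      row[[paste0(pre, "_bsc")]] <- dir_s[kind == "SOFT_CLIP", .N]
      row[[paste0(pre, "_bum")]] <- dir_s[kind == "UNMAPPED_MATE", .N]
      row[[paste0(pre, "_baq")]] <- baq
      row[[paste0(pre, "_bscq")]] <- bscq
      row[[paste0(pre, "_bumq")]] <- bumq
      row[[paste0(pre, "_qual")]] <- qs
      row[[paste0(pre, "_bvf")]] <- length(vf_frags)
      row[[paste0(pre, "_vf")]] <- length(vf_frags)
      row[[paste0(pre, "_ref")]] <- rs$ref
      row[[paste0(pre, "_refpair")]] <- rs$refpair
      row[[paste0(pre, "_frags")]] <- paste(vf_frags, collapse = ",")
    }
    if (!"N" %in% samples) {
      for (f in c("ba", "bassr", "basrp", "bsc", "bum", "bvf", "vf", "ref",
                  "refpair"))
        row[[paste0("n_", f)]] <- 0L
      for (f in c("baq", "bscq", "bumq", "qual")) row[[paste0("n_", f)]] <- 0
      row$n_frags <- ""
    }
    row$qual <- qual_total
    row$cq <- qual_total
    row$sb <- if (sb_den > 0L) sb_num / sb_den else 0.5
    if ((row$t_bvf + row$n_bvf) < params$min_fragments) next
    row$anchor1 <- max(c(0L, vapply(acids, function(id) {
      ct <- contigs_by_id[[id]]
      ct$anchor_ref[2] - ct$anchor_ref[1] + 1L
    }, 1L)))
    row$anchor2 <- 0L
    calls[[length(calls) + 1L]] <- as.data.table(row)
  }
  out <- rbindlist(calls, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) return(out)
  # dedupe by position
  out[, key := paste(chrom1, pos1, dir1)]
  setorder(out, key, -qual)
  out <- out[, .SD[1], by = key][, key := NULL]
  out
}
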