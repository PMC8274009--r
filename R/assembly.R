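# ---------------------------------------------------------------------------
# Positional de Bruijn graph breakend assembly.
#
# All evidence for one breakend neighbourhood and direction is assembled in
# "assembly space": TAIL clusters are mirrored (coordinates negated,
# sequences reverse-complemented) so the anchor always lies left of the
# junction and novel sequence extends right. Kmers from clipped/split reads
# carry width-1 position intervals inferred from the anchoring alignment;
# kmers of unmapped/discordant mates may sit anywhere consistent with the
# fragment size distribution and are pinned to a concrete position when they
# share kmers with positioned sequence (leftmost placement on ties, which
# also truncates assembly at position-unresolvable repeat loops).
# ---------------------------------------------------------------------------

#' Group evidence into breakend assembly clusters
#'
#' Clusters are per (chrom, direction); members are merged when their local
#' breakend intervals lie within `gap` bp of each other.
#' @param evidence evidence table
#' @param gap merge distance (bp); defaults to the read length
#' @return evidence with a `cluster` column
#' @export
cluster_evidence <- function(evidence, gap = 100L) {
  ev <- copy(evidence)
  setorder(ev, chrom, dir1, start1, end1)
  ev[, cluster := {
    cl <- integer(.N)
    if (.N > 0L) {
      cl[1] <- 1L
      hi <- end1[1]
      for (i in seq_len(.N)[-1]) {
        if (start1[i] <= hi + gap) cl[i] <- cl[i - 1L]
        else cl[i] <- cl[i - 1L] + 1L
        hi <- max(hi, end1[i])
      }
    }
    cl
  }, by = .(chrom, dir1)]
  ev[, cluster := paste(chrom, dir1, cluster, sep = ":")]
  ev[]
}

# evidence rows -> assembly-space read table
assembly_reads <- function(ev, metrics) {
  dir <- ev$dir1[1]
  mirror <- dir == DIR_TAIL
  L <- metrics$read_length
  lo <- metrics$concordant_lo; hi <- metrics$concordant_hi
  rows <- list()
  pr <- ev[kind %in% c("SOFT_CLIP", "SPLIT_READ")]
  if (nrow(pr)) {
    span <- pr$anchor_end - pr$anchor_start + 1L
    cliplen <- nchar(pr$seq)
    otherclip <- nchar(pr$read_seq) - span - cliplen
    if (!mirror) {
      spos <- pr$anchor_start - otherclip
      aseq <- pr$read_seq
      aend <- pr$anchor_end
    } else {
      spos <- -pr$anchor_end - otherclip
      aseq <- revcomp(pr$read_seq)
      aend <- -pr$anchor_start
    }
    rows$pr <- data.table(fragment_id = pr$fragment_id, sample = pr$sample,
                          eid = pr$eid, kind = pr$kind, seq = aseq,
                          spos = as.integer(spos), lo = NA_integer_,
                          hi = NA_integer_, anchor_end = as.integer(aend),
                          read_strand = pr$read_strand)
  }
  wd <- ev[kind %in% c("UNMAPPED_MATE", "DISCORDANT_PAIR") & !is.na(seq) &
             nchar(seq) >= 20L]
  if (nrow(wd)) {
    # orient mate sequence into assembly space
    mseq <- wd$seq
    if ("mate_strand" %in% names(wd)) {
      dpr <- wd$kind == "DISCORDANT_PAIR"
      want_rc <- if (!mirror) wd$mate_strand == "+" else wd$mate_strand == "-"
      fix <- dpr & !is.na(wd$mate_strand) & want_rc
      if (any(fix)) mseq[fix] <- revcomp(mseq[fix])
    }
    if (mirror) {
      umr <- wd$kind == "UNMAPPED_MATE"
      if (any(umr)) mseq[umr] <- revcomp(mseq[umr])
    }
    Lm <- nchar(mseq)
    astart <- if (!mirror) wd$anchor_start else -wd$anchor_end
    rows$wd <- data.table(fragment_id = wd$fragment_id, sample = wd$sample,
                          eid = wd$eid, kind = wd$kind, seq = mseq,
                          spos = NA_integer_,
                          lo = as.integer(astart + lo - Lm),
                          hi = as.integer(astart + hi - Lm),
                          anchor_end = NA_integer_,
                          read_strand = wd$read_strand)
    # the anchored read of the pair also supports the reference side
    aseq <- if (!mirror) wd$read_seq else revcomp(wd$read_seq)
    rows$wa <- data.table(fragment_id = wd$fragment_id, sample = wd$sample,
                          eid = wd$eid, kind = wd$kind, seq = aseq,
                          spos = as.integer(if (!mirror) wd$anchor_start
                                            else -wd$anchor_end),
                          lo = NA_integer_, hi = NA_integer_,
                          anchor_end = as.integer(if (!mirror) wd$anchor_end
                                                  else -wd$anchor_start),
                          read_strand = wd$read_strand)
  }
  rbindlist(rows, use.names = TRUE, fill = TRUE)
}

kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build the positional de Bruijn graph for one cluster
#'
#' @param reads assembly-space read table from `assembly_reads`
#' @param k kmer size (default 25)
#' @return list(nodes = data.table(kmer, pos, weight), reads = placements)
#' @export
build_graph <- function(reads, k = 25L) {
  reads <- copy(reads)[nchar(seq) >= k]
  if (nrow(reads) == 0L)
    return(list(nodes = data.table(kmer = character(), pos = integer(),
                                   weight = integer()), reads = reads))
  reads[, rid := .I]
  prec <- reads[!is.na(spos)]
  nodes <- if (nrow(prec)) {
    km <- prec[, .(kmer = kmerize(seq, k),
                   pos = spos + seq_len(nchar(seq) - k + 1L) - 1L),
               by = rid]
    km[, .(weight = .N), by = .(kmer, pos)]
  } else data.table(kmer = character(), pos = integer(), weight = integer())
  # pin wide-interval reads by shared kmers (leftmost best placement)
  wide <- reads[is.na(spos)]
  pinned <- TRUE
  while (pinned && nrow(wide) > 0L && nrow(nodes) > 0L) {
    pinned <- FALSE
    for (i in seq_len(nrow(wide))) {
      r <- wide[i]
      if (!is.na(r$spos)) next
      km <- data.table(kmer = kmerize(r$seq, k),
                       j = seq_len(nchar(r$seq) - k + 1L) - 1L)
      hit <- merge(km, nodes, by = "kmer", allow.cartesian = TRUE)
      if (nrow(hit) == 0L) next
      hit[, placement := pos - j]
      hit <- hit[placement >= r$lo - 20L & placement <= r$hi + 20L]
      if (nrow(hit) == 0L) next
      votes <- hit[, .(v = .N), by = placement][order(-v, placement)]
      pl <- votes$placement[1]
      wide[i, spos := pl]
      reads[rid == r$rid, spos := pl]
      newk <- data.table(kmer = kmerize(r$seq, k),
                         pos = pl + seq_len(nchar(r$seq) - k + 1L) - 1L,
                         weight = 1L)
      nodes <- rbind(nodes, newk)[, .(weight = sum(weight)), by = .(kmer, pos)]
      pinned <- TRUE
    }
  }
  list(nodes = nodes, reads = reads)
}

#' Assemble the maximal-weight contig path from a positional graph
#'
#' Greedy bidirectional extension from the heaviest node (ties broken by
#' lexicographic kmer, then leftmost position); stops when no positionally
#' compatible successor exists or the length cap is reached.
#' @param graph from [build_graph()]
#' @param k kmer size used to build the graph
#' @param max_len contig length cap (1.5x maximum fragment size upstream)
#' @return list(seq, p0) or NULL; p0 = assembly-space position of base 1
#' @export
assemble_path <- function(graph, k = 25L, max_len = 1000L) {
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) return(NULL)
  setorder(nodes, -weight, kmer, pos)
  seed <- nodes[1]
  path_kmers <- seed$kmer
  path_pos <- seed$pos
  # index for successor lookup
  setkey(nodes, pos)
  cur <- seed
  while (length(path_kmers) + k - 1L < max_len) {
    nxt <- nodes[.(cur$pos + 1L)][!is.na(kmer)]
    nxt <- nxt[substr(kmer, 1L, k - 1L) == substr(cur$kmer, 2L, k)]
    if (nrow(nxt) == 0L) break
    setorder(nxt, -weight, kmer)
    cur <- nxt[1]
    path_kmers <- c(path_kmers, cur$kmer)
    path_pos <- c(path_pos, cur$pos)
  }
  cur <- seed
  while (length(path_kmers) + k - 1L < max_len) {
    prv <- nodes[.(cur$pos - 1L)][!is.na(kmer)]
    prv <- prv[substr(kmer, 2L, k) == substr(cur$kmer, 1L, k - 1L)]
    if (nrow(prv) == 0L) break
    cur <- prv[order(-weight, kmer)][1]
    path_kmers <- c(cur$kmer, path_kmers)
    path_pos <- c(cur$pos, path_pos)
  }
  o <- order(path_pos)
  path_kmers <- path_kmers[o]; path_pos <- path_pos[o]
  seq <- paste0(path_kmers[1],
                paste(substr(path_kmers[-1], k, k), collapse = ""))
  list(seq = seq, p0 = path_pos[1])
}

#' Assemble breakend contigs from classified evidence
#'
#' @param evidence evidence table (tumour + normal, clustered or not)
#' @param metrics library metrics
#' @param k kmer size (>= 11, < read length)
#' @param max_anchor anchoring reference sequence cap (bp)
#' @return list of `svkit_contig` objects
#' @export
assemble_breakends <- function(evidence, metrics, k = 25L, max_anchor = 300L) {
  stopifnot(k >= 11L, k < metrics$read_length)
  ev <- if ("cluster" %in% names(evidence)) evidence
        else cluster_evidence(evidence)
  max_len <- as.integer(1.5 * metrics$max_fragment)
  contigs <- list()
  cid <- 0L
  for (cl in unique(ev$cluster)) {
    cl_ev <- ev[cluster == cl]
    clips <- cl_ev[kind %in% c("SOFT_CLIP", "SPLIT_READ")]
    if (nrow(clips) == 0L) next
    # a cluster may span several junctions of the same direction (e.g. the
    # two ends of an inversion bridged by discordant-pair intervals):
    # subdivide by clip position and assemble one contig per junction group
    jc <- if (clips$dir1[1] == DIR_HEAD) clips$anchor_end else
      clips$anchor_start
    jp <- sort(unique(jc))
    jgrp <- cumsum(c(TRUE, diff(jp) > 20L))
    for (gidx in unique(jgrp)) {
      jset <- jp[jgrp == gidx]
      jlo <- min(jset); jhi <- max(jset)
      sub <- rbind(clips[jc >= jlo & jc <= jhi],
                   cl_ev[kind %in% c("UNMAPPED_MATE", "DISCORDANT_PAIR") &
                           start1 <= jhi + 50L & end1 >= jlo - 50L],
                   fill = TRUE)
      ctg <- assemble_one_contig(sub, metrics, k, max_anchor, max_len, cl)
      if (!is.null(ctg)) {
        cid <- cid + 1L
        ctg$id <- sprintf("asm%04d", cid)
        contigs[[cid]] <- ctg
      }
    }
  }
  contigs
}

assemble_one_contig <- function(sub, metrics, k, max_anchor, max_len, cl) {
  rd <- assembly_reads(sub, metrics)
  if (nrow(rd) == 0L) return(NULL)
  g <- build_graph(rd, k)
  path <- assemble_path(g, k, max_len = max_len + max_anchor)
  if (is.null(path)) return(NULL)
  dir <- sub$dir1[1]
  chrom <- sub$chrom[1]
  # junction = rightmost clip point attested by clipped/split alignments
  janch <- g$reads[!is.na(anchor_end) &
                     kind %in% c("SOFT_CLIP", "SPLIT_READ"), anchor_end]
  if (length(janch) == 0L) return(NULL)
  junc_a <- max(janch)
  clen <- nchar(path$seq)
  pend <- path$p0 + clen - 1L
  if (pend <= junc_a) return(NULL)   # no novel sequence assembled
  # trim anchor to max_anchor bases before the junction
  trim_from <- max(path$p0, junc_a - max_anchor + 1L)
  seq <- substr(path$seq, trim_from - path$p0 + 1L, clen)
  p0 <- trim_from
  clen <- nchar(seq)
  if (clen > max_len) return(NULL)   # over-long assembly discarded
  junction_col <- junc_a - p0 + 1L
  if (junction_col < 1L) return(NULL)
  # per-fragment support intervals in contig columns
  placed <- copy(g$reads[!is.na(spos)])
  placed[, rlen := nchar(seq)]
  placed[, `:=`(cs = pmax(1L, spos - p0 + 1L),
                ce = pmin(clen, spos + rlen - 1L - p0 + 1L))]
  support <- placed[ce >= cs,
                    .(cs = min(cs), ce = max(ce),
                      kinds = paste(sort(unique(kind)), collapse = ","),
                      strands = paste(read_strand, collapse = "")),
                    by = .(fragment_id, sample)]
  junction_ref <- if (dir == DIR_HEAD) junc_a else -junc_a
  anchor_ref <- if (dir == DIR_HEAD) c(p0, junc_a) else c(-junc_a, -p0)
  structure(list(
    id = "asm", chrom = chrom, dir = dir,
    junction = junction_ref, seq = seq, junction_col = junction_col,
    anchor_ref = as.integer(anchor_ref),
    breakend_seq = substr(seq, junction_col + 1L, clen),
    support = support, cluster = cl), class = "svkit_contig")
}

#' Does a fragment's assembly support span the breakpoint homology?
#'
#' True iff the fragment's support interval extends at least one base beyond
#' the homology interval on both sides (an empty homology interval is the
#' junction base itself).
#' @param contig a `svkit_contig`
#' @param fragment_id fragment to test
#' @param homology contig-column interval c(lo, hi), or the junction column
#'   repeated when there is no homology
#' @export
fragment_supports_breakpoint <- function(contig, fragment_id, homology) {
  fid <- fragment_id
  s <- contig$support[fragment_id == fid]
  if (nrow(s) == 0L) stop("fragment not in contig support map: ", fragment_id)
  any(s$cs <= homology[1] - 1L & s$ce >= homology[2] + 1L)
}
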