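# ---------------------------------------------------------------------------
# SV phasing: assembly-derived cis/trans links, transitive call collapsing,
# and phasability statistics.
#
# Traversal convention: landing on a breakend (chrom, pos, HEAD) from its
# junction, the anchored sequence extends leftward (coordinates <= pos), so
# the next junction encountered is a TAIL breakend at p2 <= pos with segment
# length pos - p2; symmetrically for TAIL landings.
# ---------------------------------------------------------------------------

# breakend table of breakpoint calls: one row per end
call_breakends <- function(calls) {
  bp <- calls[type == "BP"]
  if (nrow(bp) == 0L)
    return(data.table(id = character(), endno = integer(), chrom = character(),
                      pos = integer(), dir = character(), lo = integer(),
                      hi = integer()))
  rbind(
    bp[, .(id, endno = 1L, chrom = chrom1, pos = pos1, dir = dir1,
           lo = pos1 + cipos1_lo, hi = pos1 + cipos1_hi)],
    bp[, .(id, endno = 2L, chrom = chrom2, pos = pos2, dir = dir2,
           lo = pos2 + cipos2_lo, hi = pos2 + cipos2_hi)])
}

match_junction_to_call <- function(calls, chrom1p, pos1p, dir1p, chrom2p,
                                   pos2p, dir2p, slop = 10L) {
  calls[type == "BP" & chrom1 == chrom1p & chrom2 == chrom2p &
          dir1 == dir1p & dir2 == dir2p &
          abs(pos1 - pos1p) <= slop + homlen &
          abs(pos2 - pos2p) <= slop + homlen, id]
}

#' Assembly-based phase links
#'
#' A contig chain with n >= 3 non-overlapping alignments phases its n-1
#' junctions cis: each adjacent junction pair receives an ASSEMBLY_CIS link
#' sharing the contig identifier. A chain crossing one call's junction while
#' aligning contiguously across another nearby call's locus yields an
#' ASSEMBLY_TRANS link between the two calls.
#'
#' @param chains named list of split alignment chains (by contig id)
#' @param cj contig junction table (`bp` element of [contig_junctions()])
#' @param calls call table
#' @param min_ref_margin bases a single alignment must extend on both sides
#'   of another call's junction to attest the reference allele there
#' @return PhaseLink data.table(link_id, kind, id1, id2, provenance)
#' @export
assembly_links <- function(chains, cj, calls, min_ref_margin = 10L) {
  links <- list()
  lid <- 0L
  bp <- calls[type == "BP"]
  bends <- call_breakends(calls)
  for (cid in names(chains)) {
    ch <- chains[[cid]]
    jr <- cj[contig_id == cid][order(seg_index)]
    jids <- lapply(seq_len(nrow(jr)), function(j)
      match_junction_to_call(calls, jr$chrom1[j], jr$pos1[j], jr$dir1[j],
                             jr$chrom2[j], jr$pos2[j], jr$dir2[j]))
    if (nrow(ch) >= 3L && nrow(jr) >= 2L) {
      for (j in seq_len(nrow(jr) - 1L)) {
        a <- jids[[j]]; b <- jids[[j + 1L]]
        if (length(a) && length(b) && a[1] != b[1]) {
          lid <- lid + 1L
          links[[lid]] <- data.table(
            link_id = sprintf("%s_cis%d", cid, j), kind = "ASSEMBLY_CIS",
            id1 = a[1], id2 = b[1], provenance = cid)
        }
      }
    }
    # trans: a single alignment of this chain spans another call's breakend
    own <- unique(unlist(jids))
    if (length(own) == 0L || nrow(bends) == 0L) next
    for (hi in seq_len(nrow(ch))) {
      h <- ch[hi]
      sp <- bends[chrom == h$chrom &
                    pos - min_ref_margin >= h$rstart &
                    pos + min_ref_margin <= h$rend]
      for (oid in setdiff(unique(sp$id), own)) {
        lid <- lid + 1L
        links[[lid]] <- data.table(
          link_id = sprintf("%s_trans%d", cid, lid), kind = "ASSEMBLY_TRANS",
          id1 = own[1], id2 = oid, provenance = cid)
      }
    }
  }
  out <- rbindlist(links)
  if (nrow(out) == 0L)
    return(data.table(link_id = character(), kind = character(),
                      id1 = character(), id2 = character(),
                      provenance = character()))
  unique(out, by = c("kind", "id1", "id2"))
}

#' Soft-clip anchor trans links
#'
#' A call whose anchoring support extends at least `margin` bp past a nearby
#' call's junction is phased trans with it (the anchored reads attest the
#' reference allele across the other junction).
#' @param calls call table (anchor1/anchor2 extents required)
#' @param window neighbourhood radius (bp); 1.5x max fragment upstream
#' @param margin required anchor overshoot (bp, default 10)
#' @export
sc_trans_links <- function(calls, window = 600L, margin = 10L) {
  bends <- call_breakends(calls)
  links <- list()
  if (nrow(bends) == 0L) return(empty_links())
  anch <- rbind(
    calls[type == "BP", .(id, chrom = chrom1, pos = pos1, dir = dir1,
                          alen = anchor1)],
    calls[type == "BP", .(id, chrom = chrom2, pos = pos2, dir = dir2,
                          alen = anchor2)],
    calls[type == "BE", .(id, chrom = chrom1, pos = pos1, dir = dir1,
                          alen = anchor1)])
  for (i in seq_len(nrow(anch))) {
    a <- anch[i]
    if (a$alen <= 0L) next
    aiv <- if (a$dir == DIR_HEAD) c(a$pos - a$alen + 1L, a$pos)
           else c(a$pos, a$pos + a$alen - 1L)
    near <- bends[id != a$id & chrom == a$chrom &
                    abs(pos - a$pos) <= window]
    for (j in seq_len(nrow(near))) {
      b <- near[j]
      crossed <- if (a$dir == DIR_HEAD)
        b$pos >= aiv[1] + margin && b$pos <= a$pos
      else b$pos <= aiv[2] - margin && b$pos >= a$pos
      if (isTRUE(crossed)) {
        links[[length(links) + 1L]] <- data.table(
          link_id = sprintf("sctrans_%s_%s", a$id, b$id), kind = "SC_TRANS",
          id1 = a$id, id2 = b$id, provenance = "anchor")
      }
    }
  }
  out <- rbindlist(links)
  if (nrow(out) == 0L) return(empty_links())
  unique(out, by = c("id1", "id2"))
}

empty_links <- function() data.table(
  link_id = character(), kind = character(), id1 = character(),
  id2 = character(), provenance = character())

# enumerate traversal paths of precise breakpoints starting at a given call
# end; returns list of paths (vectors of call ids) with their end breakend
bp_paths <- function(bends, start_row, max_len = 1000L, max_segs = 4L,
                     min_seg = 20L, per_start_budget = 1000L) {
  paths <- list()
  n_explored <- 0L
  recurse <- function(cur_id, cur_endno, total, used, trail) {
    if (n_explored >= per_start_budget) return()
    # land on the OTHER end of cur_id, then walk to candidate next breakends
    land <- bends[id == cur_id & endno != cur_endno]
    if (nrow(land) == 0L) return()
    paths[[length(paths) + 1L]] <<- list(ids = trail,
                                         end = land)
    n_explored <<- n_explored + 1L
    if (length(trail) >= max_segs) return()
    if (land$dir == DIR_HEAD) {
      nxt <- bends[chrom == land$chrom & dir == DIR_TAIL & pos <= land$pos &
                     !id %in% used]
      nxt[, seg := land$pos - pos]
    } else {
      nxt <- bends[chrom == land$chrom & dir == DIR_HEAD & pos >= land$pos &
                     !id %in% used]
      nxt[, seg := pos - land$pos]
    }
    nxt <- nxt[seg >= min_seg & total + seg <= max_len][order(seg)]
    for (j in seq_len(nrow(nxt))) {
      recurse(nxt$id[j], nxt$endno[j], total + nxt$seg[j],
              c(used, nxt$id[j]), c(trail, nxt$id[j]))
    }
  }
  recurse(start_row$id, start_row$endno, 0L, start_row$id, start_row$id)
  paths
}

#' Collapse imprecise transitive calls onto precise breakpoint chains
#'
#' Breadth-limited search over the precise breakpoint graph: an imprecise
#' call whose two breakends overlap the start and end breakends of a valid
#' path of precise calls (total <= 1000 bp, <= 4 segments, each segment
#' >= 20 bp, non-self-intersecting) is marked collapsed and the path's
#' adjacent pairs receive TRANSITIVE links.
#'
#' @param calls call table
#' @param max_len,max_segs,min_seg,path_budget,per_start_budget path
#'   constraints and search budgets
#' @return list(links, collapsed = call ids)
#' @export
transitive_collapse <- function(calls, max_len = 1000L, max_segs = 4L,
                                min_seg = 20L, path_budget = 100000L,
                                per_start_budget = 1000L) {
  precise <- calls[type == "BP" & imprecise == FALSE]
  imprec <- calls[type == "BP" & imprecise == TRUE]
  links <- list(); collapsed <- character(0)
  if (nrow(precise) == 0L || nrow(imprec) == 0L)
    return(list(links = empty_links(), collapsed = collapsed))
  bends <- call_breakends(precise)
  setorder(bends, chrom, pos)
  total_paths <- 0L
  all_paths <- list()
  for (i in seq_len(nrow(bends))) {
    if (total_paths >= path_budget) {
      warning("transitive path budget exhausted; partial result")
      break
    }
    ps <- bp_paths(bends, bends[i], max_len, max_segs, min_seg,
                   min(per_start_budget, path_budget - total_paths))
    total_paths <- total_paths + length(ps)
    if (length(ps)) {
      for (p in ps) p$start <- bends[i]
      all_paths <- c(all_paths, lapply(ps, function(p) {
        p$start <- bends[i]; p
      }))
    }
  }
  for (ii in seq_len(nrow(imprec))) {
    v <- imprec[ii]
    e1 <- c(v$pos1 + v$cipos1_lo, v$pos1 + v$cipos1_hi)
    e2 <- c(v$pos2 + v$cipos2_lo, v$pos2 + v$cipos2_hi)
    for (p in all_paths) {
      if (length(p$ids) < 2L) next
      sb <- p$start; eb <- p$end
      ok <- (sb$chrom == v$chrom1 && sb$dir == v$dir1 &&
               sb$pos >= e1[1] - 50L && sb$pos <= e1[2] + 50L &&
               eb$chrom == v$chrom2 && eb$dir == v$dir2 &&
               eb$pos >= e2[1] - 50L && eb$pos <= e2[2] + 50L) ||
            (sb$chrom == v$chrom2 && sb$dir == v$dir2 &&
               sb$pos >= e2[1] - 50L && sb$pos <= e2[2] + 50L &&
               eb$chrom == v$chrom1 && eb$dir == v$dir1 &&
               eb$pos >= e1[1] - 50L && eb$pos <= e1[2] + 50L)
      if (ok) {
        collapsed <- union(collapsed, v$id)
        for (j in seq_len(length(p$ids) - 1L)) {
          links[[length(links) + 1L]] <- data.table(
            link_id = sprintf("trs_%s_%d", v$id, j), kind = "TRANSITIVE",
            id1 = p$ids[j], id2 = p$ids[j + 1L], provenance = v$id)
        }
        break
      }
    }
  }
  out <- rbindlist(links)
  if (nrow(out) == 0L) out <- empty_links()
  list(links = unique(out, by = c("kind", "id1", "id2", "provenance")),
       collapsed = collapsed)
}

#' Phasability of a call set
#'
#' For each break junction, the length of the DNA segment to the first
#' junction encountered in the facing orientation; the summary is the
#' fraction of junctions with a segment at most `max_phase_distance` bp. The
#' expected baseline under uniformly random junction placement is obtained
#' by simulation with the same junction count.
#'
#' @param calls call table (or a breakend table with chrom/pos/dir)
#' @param max_phase_distance bp threshold
#' @param genome_length total genome length for the random baseline
#' @param n_sim baseline simulation replicates
#' @param seed RNG seed for the baseline
#' @return list(distances, fraction, expected_fraction)
#' @export
phasability <- function(calls, max_phase_distance = 1000L,
                        genome_length = NULL, n_sim = 20L, seed = 1L) {
  bends <- if ("type" %in% names(calls)) call_breakends(calls) else calls
  d <- facing_distances(bends)
  frac <- if (length(d)) mean(d <= max_phase_distance, na.rm = TRUE) else NaN
  expected <- NA_real_
  if (!is.null(genome_length)) {
    nb <- nrow(bends)
    expected <- with_seed(seed, {
      mean(vapply(seq_len(n_sim), function(i) {
        pos <- sort(floor(runif(nb, 1, genome_length)))
        dir <- sample(c(DIR_HEAD, DIR_TAIL), nb, replace = TRUE)
        sim <- data.table(chrom = "sim", pos = as.integer(pos), dir = dir)
        dd <- facing_distances(sim)
        if (length(dd)) mean(dd <= max_phase_distance, na.rm = TRUE) else NaN
      }, 1))
    })
  }
  list(distances = d, fraction = frac, expected_fraction = expected)
}

# distance from each breakend to the first facing junction: a HEAD breakend
# faces leftward (anchored side), so it pairs with the nearest TAIL breakend
# at a lower position, and vice versa.
facing_distances <- function(bends) {
  out <- rep(NA_real_, nrow(bends))
  for (C in unique(bends$chrom)) {
    idx <- which(bends$chrom == C)
    b <- bends[idx]
    for (i in seq_along(idx)) {
      if (b$dir[i] == DIR_HEAD) {
        cand <- b[dir == DIR_TAIL & pos <= b$pos[i]]
        if (nrow(cand)) out[idx[i]] <- b$pos[i] - max(cand$pos)
      } else {
        cand <- b[dir == DIR_HEAD & pos >= b$pos[i]]
        if (nrow(cand)) out[idx[i]] <- min(cand$pos) - b$pos[i]
      }
    }
  }
  out[!is.na(out)]
}
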