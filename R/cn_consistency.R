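# ---------------------------------------------------------------------------
# Copy-number/SV consistency: FNR from unexplained copy-number transitions,
# VAF-consistency FDR, and centromere assignment scoring.
# ---------------------------------------------------------------------------

#' Copy-number transitions from a segment table
#' @param segments data.table(chrom, start, end, copy_number), non-overlapping
#' @return data.table(chrom, pos, delta, cn_left, cn_right); pos is the
#'   boundary (start of the right segment)
#' @export
cn_transitions <- function(segments) {
  seg <- as.data.table(segments)[order(chrom, start)]
  out <- seg[, {
    if (.N < 2L) NULL
    else .(pos = start[-1],
           delta = diff(copy_number),
           cn_left = copy_number[-.N], cn_right = copy_number[-1])
  }, by = chrom]
  out[delta != 0]
}

#' Match copy-number transitions with SV calls
#'
#' Each transition not excluded is assigned to exactly one class, with
#' breakpoint matches taking precedence over single-breakend matches;
#' FNR = unexplained / total non-excluded.
#' @param transitions from [cn_transitions()]
#' @param calls call table
#' @param margin matching margin in bp (0 for internally produced calls,
#'   100 kb for external call sets)
#' @param exclusions optional data.table(chrom, start, end) of excluded
#'   regions (e.g. centromeres/gaps); transitions within `exclusion_margin`
#'   of one are dropped from the denominator
#' @param exclusion_margin bp (default 100 kb)
#' @return list(classes = per-transition table, breakdown, fnr)
#' @export
match_transitions <- function(transitions, calls, margin = 0L,
                              exclusions = NULL,
                              exclusion_margin = 100000L) {
  tr <- copy(as.data.table(transitions))
  if (!is.null(exclusions) && nrow(exclusions)) {
    keep <- rep(TRUE, nrow(tr))
    for (i in seq_len(nrow(exclusions))) {
      ex <- exclusions[i]
      keep <- keep & !(tr$chrom == ex$chrom &
                         tr$pos >= ex$start - exclusion_margin &
                         tr$pos <= ex$end + exclusion_margin)
    }
    tr <- tr[keep]
  }
  if (nrow(tr) == 0L)
    return(list(classes = tr, breakdown = c(breakpoint = 0L, breakend = 0L,
                                            unexplained = 0L), fnr = NaN))
  bp <- calls[type == "BP"]
  be <- calls[type == "BE"]
  bpos <- rbind(
    if (nrow(bp)) bp[, .(chrom = chrom1, pos = pos1)] else NULL,
    if (nrow(bp)) bp[, .(chrom = chrom2, pos = pos2)] else NULL)
  epos <- if (nrow(be)) be[, .(chrom = chrom1, pos = pos1)] else
    data.table(chrom = character(), pos = integer())
  tr[, class := "unexplained"]
  for (i in seq_len(nrow(tr))) {
    hit_bp <- !is.null(bpos) && nrow(bpos) &&
      any(bpos$chrom == tr$chrom[i] & abs(bpos$pos - tr$pos[i]) <= margin)
    hit_be <- nrow(epos) > 0L &&
      any(epos$chrom == tr$chrom[i] & abs(epos$pos - tr$pos[i]) <= margin)
    tr[i, class := if (hit_bp) "breakpoint"
                   else if (hit_be) "breakend" else "unexplained"]
  }
  breakdown <- c(breakpoint = tr[class == "breakpoint", .N],
                 breakend = tr[class == "breakend", .N],
                 unexplained = tr[class == "unexplained", .N])
  list(classes = tr, breakdown = breakdown,
       fnr = breakdown[["unexplained"]] / nrow(tr))
}

#' VAF-consistency FDR estimate for isolated calls
#'
#' Only isolated calls (no other call within `isolation` bp) are assessed.
#' The VAF-inferred variant copy number is VAF x (flanking total copy
#' number) / purity; a call is flagged inconsistent (putative false
#' positive) iff the observed copy-number change at its position is below
#' `min_cn_change` while the inferred copy number is at least
#' `min_inferred_cn`.
#' @param calls call table with `vaf` column (or t_vf/t_ref/t_refpair)
#' @param segments copy-number segment table
#' @param purity tumour purity in (0, 1]
#' @param isolation bp (default 3000)
#' @param min_cn_change,min_inferred_cn the 0.1 / 0.25 consistency cutoffs
#' @return list(assessed = per-call table, fdr)
#' @export
vaf_consistency_fdr <- function(calls, segments, purity = 1.0,
                                isolation = 3000L, min_cn_change = 0.1,
                                min_inferred_cn = 0.25) {
  cl <- copy(as.data.table(calls))
  if (!"vaf" %in% names(cl))
    cl[, vaf := mapply(function(vf, rf, rp) {
      den <- vf + rf + rp
      if (den == 0) 0 else vf / den
    }, t_vf, t_ref, if ("t_refpair" %in% names(cl)) t_refpair else 0L)]
  seg <- as.data.table(segments)
  bends <- rbind(cl[, .(id, chrom = chrom1, pos = pos1)],
                 cl[type == "BP", .(id, chrom = chrom2, pos = pos2)])
  iso <- vapply(seq_len(nrow(cl)), function(i) {
    b <- bends[id == cl$id[i]]
    other <- bends[id != cl$id[i]]
    all(vapply(seq_len(nrow(b)), function(j)
      !any(other$chrom == b$chrom[j] & abs(other$pos - b$pos[j]) <= isolation),
      TRUE))
  }, TRUE)
  asd <- cl[iso]
  if (nrow(asd) == 0L) return(list(assessed = asd, fdr = NaN))
  obs_delta <- numeric(nrow(asd)); inferred <- numeric(nrow(asd))
  for (i in seq_len(nrow(asd))) {
    C <- asd$chrom1[i]; p <- asd$pos1[i]
    cns <- seg[chrom == C][order(start)]
    l <- cns[start <= p - 1L]
    l <- if (nrow(l)) l[.N] else NULL
    r <- cns[end >= p + 1L]
    r <- if (nrow(r)) r[1] else NULL
    obs_delta[i] <- if (!is.null(l) && !is.null(r))
      abs(r$copy_number - l$copy_number) else NA_real_
    tot <- mean(c(if (!is.null(l)) l$copy_number,
                  if (!is.null(r)) r$copy_number))
    inferred[i] <- asd$vaf[i] * tot / purity
  }
  asd[, `:=`(obs_cn_change = obs_delta, inferred_cn = inferred)]
  asd[, inconsistent := !is.na(obs_cn_change) &
        obs_cn_change < min_cn_change & inferred_cn >= min_inferred_cn]
  list(assessed = asd, fdr = mean(asd$inconsistent))
}

#' BLAT-style alignment score
#'
#' score = (1000 - ((9 - floor(Qsize/100)) * mismatch + Qcount + Tcount)) *
#' min(match/Qsize, 1)
#' @param qsize query length (bp)
#' @param match,mismatch matching/mismatching base counts
#' @param qcount,tcount gap-open counts in query/target
#' @export
blat_like_score <- function(qsize, match, mismatch = 0L, qcount = 0L,
                            tcount = 0L) {
  stopifnot(match + mismatch <= qsize, qsize > 0)
  (1000 - ((9 - floor(qsize / 100)) * mismatch + qcount + tcount)) *
    min(match / qsize, 1)
}

#' Assign a centromeric single breakend to its most likely centromere
#'
#' The chromosome with the best score is assigned iff that score is at
#' least `min_score` and exceeds the best score on any other chromosome by
#' at least `min_margin`.
#' @param candidates data.table(chrom, score) of per-centromere alignments
#'   (or chrom plus BlatScoreInput columns qsize/match/mismatch/qcount/
#'   tcount, scored internally)
#' @param min_score default 900
#' @param min_margin default 25
#' @return assigned chromosome name or NA_character_
#' @export
assign_centromere <- function(candidates, min_score = 900, min_margin = 25) {
  cd <- as.data.table(candidates)
  stopifnot(nrow(cd) >= 1L)
  if (!"score" %in% names(cd))
    cd[, score := mapply(blat_like_score, qsize, match, mismatch, qcount,
                         tcount)]
  best <- cd[, .(score = max(score)), by = chrom][order(-score)]
  if (best$score[1] < min_score) return(NA_character_)
  if (nrow(best) > 1L && best$score[1] - best$score[2] < min_margin)
    return(NA_character_)
  best$chrom[1]
}
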