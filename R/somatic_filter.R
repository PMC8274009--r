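# ---------------------------------------------------------------------------
# Somatic filtering: hard filters, the enumerated low-confidence rules,
# panel of normals, simple-event annotations, and the quality filter with
# link-based rescue.
# ---------------------------------------------------------------------------

SOMATIC_THRESHOLDS <- list(
  normal_support_frac = 0.03,
  short_event = 1000L,
  min_normal_coverage = 8L,
  min_tumour_af = 0.005,
  poly_gc_run = 16L,
  strand_bias = 0.95,
  max_homology = 50L,
  max_inexact_homology = 50L,
  del_ihom_min = 6L, del_ihom_range = c(100L, 800L),
  inv_hom_size = 40L, inv_hom_min = 6L,
  pseudo_del_margin = 5L,
  pseudo_del_edit = 0.5, pseudo_del_rc_edit = 0.2,
  pon_slop = 2L, pon_qual_bp = 75, pon_qual_be = 428,
  qual_bp = 350, qual_be = 1000,
  event_window = 35L, event_support_ratio = 3,
  equivalent_window = 5L, equivalent_edit = 0.1, equivalent_min_len = 20L)

# tumour VAF: supporting fragments over total fragments at the breakend
call_vaf <- function(call, sample = "t") {
  vf <- call[[paste0(sample, "_vf")]]
  den <- vf + call[[paste0(sample, "_ref")]] +
    if (call$type == "BP") call[[paste0(sample, "_refpair")]] else 0L
  if (den == 0L) 0 else vf / den
}

is_short_deldup <- function(call, th = SOMATIC_THRESHOLDS)
  call$type == "BP" & !is.na(call$size) & call$svtype %in% c("DEL", "DUP") &
  call$size < th$short_event

longest_run <- function(seq, base) {
  r <- rle(strsplit(seq, "")[[1]])
  mx <- r$lengths[r$values == base]
  if (length(mx)) max(mx) else 0L
}

#' Hard somatic filters
#'
#' A call is hard filtered when at least 3% of its supporting reads
#' originate from the matched normal, or when it is a deletion/duplication
#' under 1000 bp with any direct split read support in the normal.
#' @param call one-row call table
#' @param th threshold list
#' @return character vector of triggered hard-filter reasons (empty if none)
#' @export
hard_filter <- function(call, th = SOMATIC_THRESHOLDS) {
  reasons <- character(0)
  nsup <- call$n_vf
  tot <- call$t_vf + call$n_vf
  if (tot > 0L && nsup / tot >= th$normal_support_frac)
    reasons <- c(reasons, "normalSupport")
  if (isTRUE(is_short_deldup(call, th)) && call$n_sr > 0L)
    reasons <- c(reasons, "normalSplitRead")
  reasons
}

#' Low-confidence classification
#'
#' Applies the enumerated low-confidence rules; breakpoints inherit the
#' worse status of their two breakends (the per-end quantities are already
#' aggregated on the call row).
#' @param call one-row call table
#' @param reference named character reference (for the pseudo-deletion
#'   insert comparison); may be NULL to skip that rule
#' @param th threshold list
#' @return character vector of triggered low-confidence rule names
#' @export
classify_confidence <- function(call, reference = NULL,
                                th = SOMATIC_THRESHOLDS) {
  r <- character(0)
  short_dd <- isTRUE(is_short_deldup(call, th))
  if (call$imprecise) r <- c(r, "imprecise")
  ncov <- call$n_vf + call$n_ref +
    if (call$type == "BP") call$n_refpair else 0L
  if (ncov < th$min_normal_coverage) r <- c(r, "normalCoverage")
  if (call_vaf(call, "t") < th$min_tumour_af) r <- c(r, "lowAF")
  if (call$type == "BE" && (call$t_basrp + call$n_basrp) == 0L)
    r <- c(r, "noAssemblyRP")
  if (call$type == "BE" && nchar(call$breakend_seq %||% "") > 0L) {
    if (max(longest_run(call$breakend_seq, "C"),
            longest_run(call$breakend_seq, "G")) >= th$poly_gc_run)
      r <- c(r, "polyGC")
  }
  if (short_dd && max(call$sb, 1 - call$sb) >= th$strand_bias)
    r <- c(r, "strandBias")
  if (call$type == "BP" && call$homlen > th$max_homology)
    r <- c(r, "homologyLength")
  ihw <- if (call$type == "BP" && !is.na(call$ihompos_hi))
    call$ihompos_hi - call$ihompos_lo else 0L
  if (call$type == "BP" && !short_dd && ihw > th$max_inexact_homology)
    r <- c(r, "inexactHomology")
  if (short_dd && (call$t_sr + call$t_assr + call$n_sr + call$n_assr) == 0L)
    r <- c(r, "shortNoSplitRead")
  if (call$type == "BP" && !short_dd &&
      (call$t_rp + call$t_asrp + call$n_rp + call$n_asrp) == 0L)
    r <- c(r, "noDiscordantPair")
  if (short_dd && call$n_sr > 0L) r <- c(r, "normalSplitRead")
  if (call$type == "BP" && call$svtype == "DEL" && !is.na(call$size) &&
      call$size >= th$del_ihom_range[1] && call$size <= th$del_ihom_range[2] &&
      ihw >= th$del_ihom_min)
    r <- c(r, "shortDelInexactHomology")
  if (call$type == "BP" && call$svtype == "INV" && !is.na(call$size) &&
      call$size <= th$inv_hom_size && call$homlen >= th$inv_hom_min)
    r <- c(r, "shortInversionHomology")
  # pseudo-deletion: insert length within 5 bp of the deleted length,
  # unless the insert is clearly not the deleted sequence (or its reverse
  # complement retrotransposition-style copy)
  if (call$type == "BP" && call$svtype %in% c("DEL", "INS") &&
      !is.na(call$size) && call$chrom1 == call$chrom2) {
    dlen <- call$pos2 - call$pos1 - 1L
    ilen <- nchar(call$insert)
    if (dlen > 0L && dlen < th$short_event &&
        abs(ilen - dlen) <= th$pseudo_del_margin && !is.null(reference)) {
      delseq <- substr(reference[[call$chrom1]], call$pos1 + 1L,
                       call$pos2 - 1L)
      nb <- min(nchar(delseq), ilen)
      if (nb > 0L) {
        edr <- edit_dist(call$insert, delseq) / nb
        edrc <- edit_dist(call$insert, revcomp(delseq)) / nb
        exempt <- edr >= th$pseudo_del_edit && edrc < th$pseudo_del_rc_edit
        if (!exempt) r <- c(r, "pseudoDeletion")
      }
    }
  }
  r
}

#' Build a panel of normals from normal call sets
#'
#' Aggregates precise calls meeting the quality thresholds (75 for
#' breakpoints, 428 for single breakends); FILTER status is ignored.
#' @param normal_call_sets list of call tables
#' @param th threshold list
#' @return `svkit_pon` list with `bp` and `be` entry tables
#' @export
build_pon <- function(normal_call_sets, th = SOMATIC_THRESHOLDS) {
  bp <- list(); be <- list()
  for (cs in normal_call_sets) {
    if (nrow(cs) == 0L) next
    bp[[length(bp) + 1L]] <- cs[type == "BP" & imprecise == FALSE &
                                  qual >= th$pon_qual_bp,
                                .(chrom1, pos1, dir1, chrom2, pos2, dir2)]
    be[[length(be) + 1L]] <- cs[type == "BE" & imprecise == FALSE &
                                  qual >= th$pon_qual_be,
                                .(chrom1, pos1, dir1)]
  }
  bp <- if (length(bp)) rbindlist(bp) else
    data.table(chrom1 = character(), pos1 = integer(), dir1 = character(),
               chrom2 = character(), pos2 = integer(), dir2 = character())
  be <- if (length(be)) rbindlist(be) else
    data.table(chrom1 = character(), pos1 = integer(), dir1 = character())
  bp <- unique(bp)[, count := 1L]
  be <- unique(be)[, count := 1L]
  structure(list(bp = bp, be = be), class = "svkit_pon")
}

#' Panel-of-normals filter
#'
#' Filtered iff a PON entry of matching type and orientation lies within
#' `slop` bp (both breakends must match for breakpoints).
#' @param call one-row call table
#' @param pon from [build_pon()] (or read from BEDPE/BED)
#' @param slop matching distance (bp, default 2)
#' @export
pon_filter <- function(call, pon, slop = SOMATIC_THRESHOLDS$pon_slop) {
  if (is.null(pon)) return(FALSE)
  if (call$type == "BP") {
    hit <- pon$bp[chrom1 == call$chrom1 & chrom2 == call$chrom2 &
                    dir1 == call$dir1 & dir2 == call$dir2 &
                    abs(pos1 - call$pos1) <= slop &
                    abs(pos2 - call$pos2) <= slop]
    nrow(hit) > 0L
  } else {
    hit <- pon$be[chrom1 == call$chrom1 & dir1 == call$dir1 &
                    abs(pos1 - call$pos1) <= slop]
    nrow(hit) > 0L
  }
}

# breakend sequence used for the equivalence comparison
equivalence_seq <- function(call, reference, th = SOMATIC_THRESHOLDS) {
  if (call$type == "BE") return(call$breakend_seq %||% "")
  if (is.null(reference)) return("")
  len <- max(th$equivalent_min_len, call$anchor2 %||% 0L)
  flank_Y(reference, call$chrom2, call$pos2, call$dir2, len)
}

#' Simple-event annotations
#'
#' EQUIVALENT pairs share a breakend within 5 bp and a common breakend
#' sequence (per-base edit distance <= 0.1 over the shorter sequence).
#' Reciprocal-translocation, templated-insertion and simple-inversion
#' annotations apply to pairs with matching geometry within 35 bp whose
#' support differs by at most threefold; a pair receives at most one of the
#' three, tested in that order.
#' @param calls call table
#' @param reference named character reference (for equivalence sequences)
#' @param th threshold list
#' @return data.table(kind, id1, id2)
#' @export
annotate_events <- function(calls, reference = NULL,
                            th = SOMATIC_THRESHOLDS) {
  out <- list()
  n <- nrow(calls)
  if (n < 2L) return(data.table(kind = character(), id1 = character(),
                                id2 = character()))
  supp <- calls$t_vf + calls$n_vf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- calls[i]; b <- calls[j]
    # --- equivalence (independent of the simple-event kinds) -----------
    near <- a$chrom1 == b$chrom1 & abs(a$pos1 - b$pos1) <= th$equivalent_window
    if (isTRUE(near)) {
      sa <- equivalence_seq(a, reference, th)
      sb_ <- equivalence_seq(b, reference, th)
      nb <- min(nchar(sa), nchar(sb_))
      if (nb > 0L) {
        ed <- edit_dist(substr(sa, 1, nb), substr(sb_, 1, nb)) / nb
        if (ed <= th$equivalent_edit)
          out[[length(out) + 1L]] <- data.table(kind = "EQUIVALENT",
                                                id1 = a$id, id2 = b$id)
      }
    }
    # --- simple events (mutually exclusive, fixed precedence) ----------
    if (a$type != "BP" || b$type != "BP") next
    ratio_ok <- max(supp[i], supp[j]) <= th$event_support_ratio *
      max(1L, min(supp[i], supp[j]))
    if (!ratio_ok) next
    w <- th$event_window
    both_near <- a$chrom1 == b$chrom1 & a$chrom2 == b$chrom2 &
      abs(a$pos1 - b$pos1) <= w & abs(a$pos2 - b$pos2) <= w
    if (!isTRUE(both_near)) next
    opp1 <- a$dir1 != b$dir1; opp2 <- a$dir2 != b$dir2
    if (!(opp1 && opp2)) next
    inv_like <- function(x) x$dir1 == x$dir2
    kind <- if (a$chrom1 != a$chrom2 && b$chrom1 != b$chrom2)
      "RECIPROCAL_TRANSLOCATION"
    else if (!inv_like(a) && !inv_like(b)) "TEMPLATED_INSERTION"
    else if (inv_like(a) && inv_like(b)) "SIMPLE_INVERSION"
    else NULL
    if (!is.null(kind))
      out[[length(out) + 1L]] <- data.table(kind = kind, id1 = a$id,
                                            id2 = b$id)
  }
  if (length(out) == 0L)
    return(data.table(kind = character(), id1 = character(),
                      id2 = character()))
  rbindlist(out)
}

#' Quality filter with link-based rescue
#'
#' Breakpoints under QUAL 350 and single breakends under QUAL 1000 fail the
#' quality filter unless linked (assembly/transitive/SC, never equivalence)
#' to a passing call; rescue closes over the link graph to a fixed point.
#' @param calls call table
#' @param links PhaseLink table
#' @param statuses current character status vector ("PASS" etc. per call)
#' @param th threshold list
#' @return logical vector: TRUE where the call passes the quality filter
#' @export
quality_filter_with_rescue <- function(calls, links, statuses,
                                       th = SOMATIC_THRESHOLDS) {
  need <- ifelse(calls$type == "BP", th$qual_bp, th$qual_be)
  ok <- calls$qual >= need
  eligible <- statuses == "PASS"   # only otherwise-passing calls can rescue
  rescuing <- links[kind != "EQUIVALENT"]
  pass <- ok & eligible
  repeat {
    add <- rep(FALSE, nrow(calls))
    for (j in seq_len(nrow(rescuing))) {
      l <- rescuing[j]
      i1 <- match(l$id1, calls$id); i2 <- match(l$id2, calls$id)
      if (is.na(i1) || is.na(i2)) next
      if (pass[i1] && !pass[i2] && eligible[i2]) add[i2] <- TRUE
      if (pass[i2] && !pass[i1] && eligible[i1]) add[i1] <- TRUE
    }
    if (!any(add)) break
    pass <- pass | add
  }
  pass | !eligible & ok   # quality verdict; non-eligible calls keep raw ok
}

#' Apply the full somatic filter
#'
#' @param calls call table from [call_structural_variants()]
#' @param links PhaseLink table (rescue); may be empty
#' @param pon optional panel of normals
#' @param reference named character reference
#' @param collapsed ids of transitive-collapsed calls (removed from both
#'   output sets)
#' @param th threshold list
#' @return calls with `filter_status` ("PASS"/"LOW_CONFIDENCE"/
#'   "HARD_FILTERED") and `filter_reasons` columns
#' @export
somatic_filter <- function(calls, links = empty_links(), pon = NULL,
                           reference = NULL, collapsed = character(0),
                           th = SOMATIC_THRESHOLDS) {
  if (nrow(calls) == 0L) {
    calls[, `:=`(filter_status = character(), filter_reasons = character())]
    return(calls)
  }
  out <- copy(calls)
  status <- rep("PASS", nrow(out))
  reasons <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    cl <- out[i]
    hf <- hard_filter(cl, th)
    if (length(hf)) { status[i] <- "HARD_FILTERED"; reasons[[i]] <- hf; next }
    lc <- classify_confidence(cl, reference, th)
    if (pon_filter(cl, pon, th$pon_slop)) lc <- c(lc, "PON")
    if (cl$id %in% collapsed) lc <- c(lc, "transitive")
    if (length(lc)) { status[i] <- "LOW_CONFIDENCE"; reasons[[i]] <- lc }
  }
  qpass <- quality_filter_with_rescue(out, links, status, th)
  for (i in which(!qpass & status == "PASS")) {
    status[i] <- "LOW_CONFIDENCE"
    reasons[[i]] <- c(reasons[[i]], "lowQual")
  }
  out[, filter_status := status]
  out[, filter_reasons := vapply(reasons, function(r)
    paste(unique(r), collapse = ";"), character(1))]
  out
}

#' Emit the high- and low-confidence somatic call sets
#'
#' @param calls filtered calls (from [somatic_filter()])
#' @return list(high, low): high contains PASS calls only; low contains all
#'   calls except normal-support hard failures and short events with split
#'   read support in the normal
#' @export
emit_call_sets <- function(calls) {
  high <- calls[filter_status == "PASS"]
  low <- calls[!(filter_status == "HARD_FILTERED")]
  list(high = high, low = low)
}
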