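# ---------------------------------------------------------------------------
# Truth matching and benchmark classification.
# ---------------------------------------------------------------------------

#' Match calls against a truth set
#'
#' A call matches a truth junction when both breakends lie within `margin`
#' bp (orientation-aware); tandem duplications match insertion truths when
#' the size difference is within `dup_ins_margin`. Single-breakend calls
#' matching one truth side are MATCH_BREAKEND; breakpoint calls matching one
#' side only are ONE_SIDE_CORRECT. When several calls match one truth entry
#' all but the highest-QUAL call are ignored (not counted as FP). False
#' positive calls under `min_size` bp are dropped after matching.
#'
#' @param calls call table (high-confidence set, typically)
#' @param truth truth junction table (chrom1,pos1,dir1,chrom2,pos2,dir2,
#'   type, expected_class)
#' @param margin matching margin (bp, default 100)
#' @param dup_ins_margin DUP vs INS size margin (bp, default 25)
#' @param min_size FP size floor applied after matching (bp, default 50)
#' @return list(truth = per-truth classification, calls = per-call TP/FP,
#'   sensitivity, precision)
#' @export
match_calls <- function(calls, truth, margin = 100L, dup_ins_margin = 25L,
                        min_size = 50L) {
  truth <- copy(as.data.table(truth))[, tix := .I]
  truth[, class := "FALSE_NEGATIVE"]
  truth[, matched_by := NA_character_]
  calls <- copy(calls)
  if (nrow(calls)) setorder(calls, -qual)
  call_class <- rep(NA_character_, nrow(calls))
  names(call_class) <- calls$id
  ends_match <- function(c1, p1, d1, c2, p2, d2, t) {
    direct <- c1 == t$chrom1 & c2 == t$chrom2 & d1 == t$dir1 & d2 == t$dir2 &
      abs(p1 - t$pos1) <= margin & abs(p2 - t$pos2) <= margin
    flipped <- c1 == t$chrom2 & c2 == t$chrom1 & d1 == t$dir2 &
      d2 == t$dir1 & abs(p1 - t$pos2) <= margin & abs(p2 - t$pos1) <= margin
    direct | flipped
  }
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i]
    matched <- FALSE
    for (ti in truth$tix) {
      t <- truth[tix == ti]
      if (cl$type == "BP") {
        dupins <- isTRUE((cl$svtype == "DUP" && t$type == "INS") ||
                           (cl$svtype == "INS" && t$type == "DUP"))
        if (dupins) {
          # duplication <-> insertion cross-matching is gated on the size
          # difference in addition to the positional margin
          full <- !is.na(cl$size) && !is.na(t$size) &&
            cl$chrom1 == t$chrom1 &&
            abs(cl$pos1 - t$pos1) <= margin &&
            abs(cl$size - t$size) <= dup_ins_margin
        } else {
          full <- ends_match(cl$chrom1, cl$pos1, cl$dir1, cl$chrom2,
                             cl$pos2, cl$dir2, t)
        }
        one <- (cl$chrom1 == t$chrom1 & cl$dir1 == t$dir1 &
                  abs(cl$pos1 - t$pos1) <= margin) |
               (cl$chrom2 == t$chrom2 & cl$dir2 == t$dir2 &
                  abs(cl$pos2 - t$pos2) <= margin) |
               (cl$chrom1 == t$chrom2 & cl$dir1 == t$dir2 &
                  abs(cl$pos1 - t$pos2) <= margin) |
               (cl$chrom2 == t$chrom1 & cl$dir2 == t$dir1 &
                  abs(cl$pos2 - t$pos1) <= margin)
        if (isTRUE(full)) {
          if (t$class == "FALSE_NEGATIVE") {
            truth[tix == ti, `:=`(class = "MATCH_BREAKPOINT",
                                  matched_by = cl$id)]
            call_class[cl$id] <- "TP"
          } else call_class[cl$id] <- "IGNORED_DUPLICATE"
          matched <- TRUE; break
        } else if (isTRUE(one)) {
          if (t$class == "FALSE_NEGATIVE") {
            truth[tix == ti, `:=`(class = "ONE_SIDE_CORRECT",
                                  matched_by = cl$id)]
            call_class[cl$id] <- "TP"
          } else call_class[cl$id] <- "IGNORED_DUPLICATE"
          matched <- TRUE; break
        }
      } else {
        side <- (cl$chrom1 == t$chrom1 & cl$dir1 == t$dir1 &
                   abs(cl$pos1 - t$pos1) <= margin) |
                (cl$chrom1 == t$chrom2 & cl$dir1 == t$dir2 &
                   abs(cl$pos1 - t$pos2) <= margin)
        if (isTRUE(side)) {
          if (t$class %in% c("FALSE_NEGATIVE")) {
            truth[tix == ti, `:=`(class = "MATCH_BREAKEND",
                                  matched_by = cl$id)]
            call_class[cl$id] <- "TP"
          } else call_class[cl$id] <- "IGNORED_DUPLICATE"
          matched <- TRUE; break
        }
      }
    }
    if (!matched) call_class[cl$id] <- "FP"
  }
  # FP size floor applied after matching
  if (nrow(calls)) {
    small_fp <- call_class == "FP" & !is.na(calls$size) & calls$size < min_size
    call_class[small_fp] <- "IGNORED_SMALL"
  }
  n_tp <- sum(truth$class %in% c("MATCH_BREAKPOINT", "MATCH_BREAKEND",
                                 "ONE_SIDE_CORRECT"))
  n_fp <- sum(call_class == "FP", na.rm = TRUE)
  n_tp_calls <- sum(call_class == "TP", na.rm = TRUE)
  list(truth = truth,
       calls = data.table(id = calls$id, class = unname(call_class)),
       sensitivity = if (nrow(truth)) n_tp / nrow(truth) else NaN,
       precision = if (n_tp_calls + n_fp > 0L)
         n_tp_calls / (n_tp_calls + n_fp) else NaN)
}
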