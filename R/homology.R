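# ---------------------------------------------------------------------------
# Breakpoint microhomology: exact (CIPOS/HOMLEN/HOMSEQ) and inexact (IHOMPOS).
#
# A junction is the derivative concatenation X + insert + Y where
#   X ends at breakend 1 (chrom1, pos1, dir1) and
#   Y starts at breakend 2 (chrom2, pos2, dir2),
# both read in derivative-forward orientation.
# ---------------------------------------------------------------------------

# derivative-forward flank extractors ------------------------------------

# sequence of X approaching the junction (last `len` bases, forward)
flank_X <- function(reference, chrom, pos, dir, len) {
  s <- reference[[chrom]]
  if (dir == DIR_HEAD) substr(s, max(1L, pos - len + 1L), pos)
  else revcomp(substr(s, pos, min(nchar(s), pos + len - 1L)))
}
# continuation of X's chromosome beyond the junction (next `len` bases)
cont_X <- function(reference, chrom, pos, dir, len) {
  s <- reference[[chrom]]
  if (dir == DIR_HEAD) substr(s, pos + 1L, min(nchar(s), pos + len))
  else revcomp(substr(s, max(1L, pos - len), pos - 1L))
}
# sequence of Y leaving the junction (first `len` bases, forward)
flank_Y <- function(reference, chrom, pos, dir, len) {
  s <- reference[[chrom]]
  if (dir == DIR_TAIL) substr(s, pos, min(nchar(s), pos + len - 1L))
  else revcomp(substr(s, max(1L, pos - len + 1L), pos))
}
# bases preceding Y's start on Y's chromosome (reading toward the junction)
pre_Y <- function(reference, chrom, pos, dir, len) {
  s <- reference[[chrom]]
  if (dir == DIR_TAIL) substr(s, max(1L, pos - len), pos - 1L)
  else revcomp(substr(s, pos + 1L, min(nchar(s), pos + len)))
}

#' Exact breakpoint homology
#'
#' Enumerates all junction placements producing an identical alternate
#' sequence. The nominal call is left-aligned on breakend 1. Junctions with
#' non-template insert sequence have no exact homology by construction.
#'
#' @param chrom1,pos1,dir1,chrom2,pos2,dir2 the two breakends
#' @param reference named character reference
#' @param insert_len length of untemplated insert sequence at the junction
#' @param max_shift enumeration bound per side (bp)
#' @return list(pos1, pos2, homlen, homseq, cipos, cirpos); cipos/cirpos are
#'   length-2 offset intervals relative to the reported positions
#' @export
exact_homology <- function(chrom1, pos1, dir1, chrom2, pos2, dir2,
                           reference, insert_len = 0L, max_shift = 2000L) {
  if (!chrom1 %in% names(reference) || !chrom2 %in% names(reference))
    stop("breakend outside reference")
  same_move <- (dir1 == DIR_HEAD) == (dir2 == DIR_TAIL)
  if (insert_len > 0L) {
    return(list(pos1 = pos1, pos2 = pos2, homlen = 0L, homseq = "",
                cipos = c(0L, 0L),
                cirpos = c(0L, 0L)))
  }
  ext1 <- cont_X(reference, chrom1, pos1, dir1, max_shift)
  fY <- flank_Y(reference, chrom2, pos2, dir2, max_shift)
  r <- common_prefix_len(ext1, fY)
  lastX <- flank_X(reference, chrom1, pos1, dir1, max_shift)
  pY <- pre_Y(reference, chrom2, pos2, dir2, max_shift)
  # compare reversed tails
  l <- common_prefix_len(str_rev(lastX), str_rev(pY))
  H <- l + r
  # left-align on breakend 1
  s <- if (dir1 == DIR_HEAD) -l else r   # shift applied (along slide axis)
  # slide axis: +1 moves pos1 toward its novel side
  p1 <- pos1 + if (dir1 == DIR_HEAD) s else -s
  p2 <- pos2 + if (dir2 == DIR_TAIL) s else -s
  homseq <- if (H > 0L) {
    # homologous bases = the H bases of Y starting at the leftmost placement
    substr(flank_Y(reference, chrom2, p2, dir2, H), 1L, H)
  } else ""
  cipos <- c(0L, H)
  cirpos <- if (same_move) c(0L, H) else c(-H, 0L)
  list(pos1 = as.integer(p1), pos2 = as.integer(p2), homlen = as.integer(H),
       homseq = homseq, cipos = as.integer(cipos),
       cirpos = as.integer(cirpos))
}

str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ar <- charToRaw(substr(a, 1L, n)); br <- charToRaw(substr(b, 1L, n))
  d <- which(ar != br)
  if (length(d) == 0L) n else d[1] - 1L
}

#' Inexact breakpoint homology (IHOMPOS)
#'
#' Smith-Waterman (match 1, mismatch -4, gap open 6, gap extend 1) of the
#' breakpoint sequence against each breakend's reference context; sequences
#' are extended `flank` bp from the break with the reference extended a
#' further 10 bp. The homology length on each side is the distance the
#' alignment extends from the common sequence past the junction. Alignments
#' soft-clipped on the common-sequence side are treated as alignment errors
#' (contributing 0).
#'
#' @inheritParams exact_homology
#' @param insert_seq untemplated insert sequence at the junction ("" if none)
#' @param flank context length (bp)
#' @return integer ihompos = c(-left, right) interval around the junction
#' @export
inexact_homology <- function(chrom1, pos1, dir1, chrom2, pos2, dir2,
                             reference, insert_seq = "", flank = 300L) {
  right <- ihom_one_side(chrom1, pos1, dir1, chrom2, pos2, dir2,
                         reference, insert_seq, flank)
  # mirror the junction: X' = revcomp(Y), Y' = revcomp(X)
  left <- ihom_one_side(chrom2, pos2, dir2, chrom1, pos1, dir1,
                        reference, revcomp_str(insert_seq), flank)
  c(-left, right)
}

revcomp_str <- function(s) if (nchar(s) == 0L) "" else revcomp(s)

# extension of the SW alignment past the junction on X's side
ihom_one_side <- function(chrom1, pos1, dir1, chrom2, pos2, dir2,
                          reference, insert_seq, flank) {
  common <- flank_X(reference, chrom1, pos1, dir1, flank)
  bp_seq <- paste0(common, insert_seq,
                   flank_Y(reference, chrom2, pos2, dir2, flank))
  ref_ctx <- paste0(common, cont_X(reference, chrom1, pos1, dir1, flank + 10L))
  nc <- nchar(common)
  al <- Biostrings::pairwiseAlignment(bp_seq, ref_ctx, type = "local",
                                      substitutionMatrix = sw_submat(),
                                      gapOpening = SW_GAP_OPEN,
                                      gapExtension = SW_GAP_EXT)
  ps <- Biostrings::start(Biostrings::pattern(al))
  pe <- Biostrings::end(Biostrings::pattern(al))
  ss <- Biostrings::start(Biostrings::subject(al))
  se <- Biostrings::end(Biostrings::subject(al))
  # require the alignment to reach the junction from the common side
  if (pe < nc || ss > max(1L, nc %/% 2L)) return(0L)
  # homology is the contiguous extension past the junction: the reference
  # context is only 10 bp longer than the breakpoint sequence to tolerate
  # small indels, so the extension stops at the first gap longer than that
  # (a long gap means the alignment jumped the junction, not homology)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  subj_pos <- ss + cumsum(sa != "-") - 1L
  r <- rle(gap)
  cut <- se
  if (any(r$values & r$lengths > 10L)) {
    first <- cumsum(r$lengths)[which(r$values & r$lengths > 10L)[1]] -
      r$lengths[which(r$values & r$lengths > 10L)[1]]
    # subject coordinate just before the long gap begins
    cut <- if (first >= 1L) subj_pos[first] else ss - 1L
  }
  max(0L, min(se, cut) - nc)
}
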