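# ---------------------------------------------------------------------------
# VCF 4.2 breakend (BND) and single-breakend input/output with the full
# per-sample support-breakdown ledger.
#
# Bracket notation follows the VCF specification:
#   HEAD/TAIL partner -> t[p[ ; HEAD/HEAD -> t]p] ;
#   TAIL/TAIL -> [p[t ; TAIL/HEAD -> ]p]t ;
#   single breakends: HEAD -> t.  TAIL -> .t
# ---------------------------------------------------------------------------

VCF_INFO_FIELDS <- c(
  SVTYPE = "String", MATEID = "String", PARID = "String", EVENT = "String",
  CIPOS = "Integer2", CIRPOS = "Integer2", IHOMPOS = "Integer2",
  HOMLEN = "Integer", HOMSEQ = "String", IMPRECISE = "Flag",
  SVCLASS = "String", SVLEN = "Integer", INSSEQ = "String",
  BEID = "String", BEALN = "String", BESEQ = "String",
  CQ = "Float", SB = "Float", SC = "String", ANCHOR1 = "Integer",
  ANCHOR2 = "Integer", LINKED_BY = "String")

VCF_FORMAT_INT <- c("AS", "RAS", "CAS", "ASSR", "ASRP", "SR", "RP", "IC",
                    "BA", "BASSR", "BASRP", "BSC", "BUM", "BANRP", "BANSR",
                    "REF", "REFPAIR", "RF", "VF", "BVF")
VCF_FORMAT_FLOAT <- c("ASQ", "RASQ", "CASQ", "SRQ", "RPQ", "IQ", "BAQ",
                      "BSCQ", "BUMQ", "BANRPQ", "BANSRQ", "QUAL")

# call-table column backing a FORMAT key for sample prefix p ("t"/"n")
fmt_col <- function(p, key) paste0(p, "_", tolower(key))

vcf_header <- function(reference = NULL, sample_names = c("N", "T")) {
  h <- c("##fileformat=VCFv4.2",
         "##source=svkit")
  if (!is.null(reference))
    h <- c(h, vapply(names(reference), function(C)
      sprintf("##contig=<ID=%s,length=%d>", C, nchar(reference[[C]])),
      character(1)))
  for (k in names(VCF_INFO_FIELDS)) {
    ty <- VCF_INFO_FIELDS[[k]]
    num <- "1"
    if (ty == "Integer2") { ty <- "Integer"; num <- "2" }
    if (ty == "Flag") num <- "0"
    h <- c(h, sprintf(
      "##INFO=<ID=%s,Number=%s,Type=%s,Description=\"%s\">", k, num, ty, k))
  }
  for (k in VCF_FORMAT_INT)
    h <- c(h, sprintf(
      "##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"%s\">", k, k))
  for (k in VCF_FORMAT_FLOAT)
    h <- c(h, sprintf(
      "##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k))
  h <- c(h, "##FILTER=<ID=PASS,Description=\"High confidence somatic\">",
         "##FILTER=<ID=LOW_CONFIDENCE,Description=\"Low confidence\">",
         "##FILTER=<ID=HARD_FILTERED,Description=\"Hard filtered\">",
         paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_names), collapse = "\t"))
  h
}

bnd_alt <- function(refbase, insert, c2, p2, d1, d2) {
  partner <- sprintf("%s:%d", c2, p2)
  t <- paste0(refbase, insert)
  if (d1 == DIR_HEAD) {
    if (d2 == DIR_TAIL) paste0(t, "[", partner, "[")
    else paste0(t, "]", partner, "]")
  } else {
    t <- paste0(insert, refbase)
    if (d2 == DIR_TAIL) paste0("[", partner, "[", t)
    else paste0("]", partner, "]", t)
  }
}

num_fmt <- function(x) {
  if (is.na(x)) return(".")
  if (is.integer(x)) return(as.character(x))
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

#' Write calls as a breakend VCF
#'
#' Breakpoints emit reciprocal mate-pair records with PARID/MATEID; single
#' breakends use dot notation carrying the assembled breakend sequence.
#' Records are ordered by (chrom, pos, id).
#' @param calls call table
#' @param path output file
#' @param reference named character reference (REF bases and contig header)
#' @param links optional PhaseLink table serialized into LINKED_BY
#' @param sample_names VCF sample column names, normal first
#' @return path, invisibly
#' @export
write_vcf <- function(calls, path, reference = NULL, links = NULL,
                      sample_names = c("N", "T")) {
  recs <- list()
  refbase <- function(C, p) {
    if (is.null(reference) || !C %in% names(reference)) return("N")
    b <- substr(reference[[C]], p, p)
    if (nchar(b)) b else "N"
  }
  linkstr <- function(id) {
    if (is.null(links) || nrow(links) == 0L) return(NA_character_)
    ll <- links[id1 == id | id2 == id, link_id]
    if (length(ll)) paste(ll, collapse = ",") else NA_character_
  }
  fmt_block <- function(row, p) {
    vals <- c(vapply(VCF_FORMAT_INT, function(k) {
      v <- row[[fmt_col(p, k)]]
      if (is.null(v) || is.na(v)) "0" else as.character(as.integer(v))
    }, character(1)),
    vapply(VCF_FORMAT_FLOAT, function(k) {
      v <- row[[fmt_col(p, k)]]
      if (is.null(v) || is.na(v)) "0" else num_fmt(as.numeric(v))
    }, character(1)))
    paste(vals, collapse = ":")
  }
  fmt_keys <- paste(c(VCF_FORMAT_INT, VCF_FORMAT_FLOAT), collapse = ":")
  for (i in seq_len(nrow(calls))) {
    row <- as.list(calls[i])
    filt <- row$filter_status %||% "PASS"
    if (is.null(filt) || is.na(filt)) filt <- "PASS"
    common_info <- c(
      sprintf("SVTYPE=BND"),
      if (!is.na(row$svtype)) sprintf("SVCLASS=%s", row$svtype),
      if (!is.null(row$size) && !is.na(row$size)) sprintf("SVLEN=%d", row$size),
      if (isTRUE(row$imprecise)) "IMPRECISE",
      sprintf("HOMLEN=%d", row$homlen %||% 0L),
      if (!is.null(row$homseq) && nzchar(row$homseq))
        sprintf("HOMSEQ=%s", row$homseq),
      if (!is.null(row$insert) && nzchar(row$insert))
        sprintf("INSSEQ=%s", row$insert),
      if (!is.null(row$beid) && !is.na(row$beid) && nzchar(row$beid))
        sprintf("BEID=%s", row$beid),
      sprintf("CQ=%s", num_fmt(row$cq %||% row$qual)),
      sprintf("SB=%s", num_fmt(row$sb %||% 0.5)),
      sprintf("ANCHOR1=%d", row$anchor1 %||% 0L),
      sprintf("ANCHOR2=%d", row$anchor2 %||% 0L))
    if (!is.null(row$ihompos_lo) && !is.na(row$ihompos_lo))
      common_info <- c(common_info,
                       sprintf("IHOMPOS=%d,%d", row$ihompos_lo,
                               row$ihompos_hi))
    lb <- linkstr(row$id)
    if (!is.na(lb)) common_info <- c(common_info, sprintf("LINKED_BY=%s", lb))
    smp <- paste(fmt_block(row, "n"), fmt_block(row, "t"), sep = "\t")
    if (row$type == "BP") {
      id1 <- paste0(row$id, "o"); id2 <- paste0(row$id, "h")
      info1 <- c(common_info,
                 sprintf("PARID=%s", id2), sprintf("MATEID=%s", id2),
                 sprintf("EVENT=%s", row$id),
                 sprintf("CIPOS=%d,%d", row$cipos1_lo, row$cipos1_hi),
                 sprintf("CIRPOS=%d,%d", row$cipos2_lo, row$cipos2_hi))
      info2 <- c(common_info,
                 sprintf("PARID=%s", id1), sprintf("MATEID=%s", id1),
                 sprintf("EVENT=%s", row$id),
                 sprintf("CIPOS=%d,%d", row$cipos2_lo, row$cipos2_hi),
                 sprintf("CIRPOS=%d,%d", row$cipos1_lo, row$cipos1_hi))
      rb1 <- refbase(row$chrom1, row$pos1)
      rb2 <- refbase(row$chrom2, row$pos2)
      # the canonical insert reads breakend1 -> breakend2 in derivative
      # orientation; each record stores it in its own reference-forward
      # orientation (reverse complement on TAIL-side records)
      rc_ins <- if (nzchar(row$insert)) revcomp(row$insert) else ""
      ins1 <- if (row$dir1 == DIR_HEAD) row$insert else rc_ins
      ins2 <- if (row$dir2 == DIR_HEAD) rc_ins else row$insert
      recs[[length(recs) + 1L]] <- data.table(
        chrom = row$chrom1, pos = row$pos1, id = id1, ref = rb1,
        alt = bnd_alt(rb1, ins1, row$chrom2, row$pos2, row$dir1,
                      row$dir2),
        qual = row$qual, filt = filt,
        info = paste(info1, collapse = ";"), smp = smp)
      recs[[length(recs) + 1L]] <- data.table(
        chrom = row$chrom2, pos = row$pos2, id = id2, ref = rb2,
        alt = bnd_alt(rb2, ins2, row$chrom1, row$pos1, row$dir2, row$dir1),
        qual = row$qual, filt = filt,
        info = paste(info2, collapse = ";"), smp = smp)
    } else {
      rb <- refbase(row$chrom1, row$pos1)
      bes <- row$breakend_seq %||% ""
      if (is.na(bes)) bes <- ""
      alt <- if (row$dir1 == DIR_HEAD) paste0(rb, bes, ".")
             else paste0(".", bes, rb)
      info <- c(common_info,
                sprintf("CIPOS=%d,%d", row$cipos1_lo, row$cipos1_hi),
                if (nzchar(bes)) sprintf("BESEQ=%s", bes),
                if (!is.null(row$bealn) && !is.na(row$bealn) &&
                    nzchar(row$bealn)) sprintf("BEALN=%s", row$bealn))
      recs[[length(recs) + 1L]] <- data.table(
        chrom = row$chrom1, pos = row$pos1, id = row$id, ref = rb,
        alt = alt, qual = row$qual, filt = filt,
        info = paste(info, collapse = ";"), smp = smp)
    }
  }
  hdr <- vcf_header(reference, sample_names)
  if (length(recs) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  rd <- rbindlist(recs)[order(chrom, pos, id)]
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   rd$chrom, rd$pos, rd$id, rd$ref, rd$alt,
                   vapply(rd$qual, num_fmt, character(1)), rd$filt, rd$info,
                   fmt_keys, rd$smp)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

parse_info <- function(s) {
  kv <- strsplit(s, ";")[[1]]
  out <- list()
  for (x in kv) {
    if (grepl("=", x)) {
      k <- sub("=.*$", "", x)
      out[[k]] <- sub("^[^=]+=", "", x)
    } else out[[x]] <- TRUE
  }
  out
}

parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^(.*)([][])([^:]+):([0-9]+)([][])(.*)$",
                               alt))[[1]]
  if (length(m) == 0L) return(NULL)
  before <- m[2]; br <- m[3]; c2 <- m[4]; p2 <- as.integer(m[5]); after <- m[7]
  if (nchar(before) > 0L) {
    d1 <- DIR_HEAD
    ins <- substr(before, 2L, nchar(before))
  } else {
    d1 <- DIR_TAIL
    ins <- substr(after, 1L, nchar(after) - 1L)
  }
  d2 <- if (br == "[") DIR_TAIL else DIR_HEAD
  list(d1 = d1, d2 = d2, c2 = c2, p2 = p2, ins = ins)
}

#' Read a breakend VCF back into a call table
#'
#' Mate records are re-paired via PARID/MATEID; an orphaned mate produces a
#' warning and is kept as a single breakend flagged in `filter_reasons`.
#' @param path VCF file
#' @return call table in the same shape [write_vcf()] consumes
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  hline <- lines[startsWith(lines, "#CHROM")]
  sample_names <- strsplit(hline, "\t")[[1]][-(1:9)]
  if (length(body) == 0L) return(data.table())
  f <- tstrsplit(body, "\t")
  rec <- data.table(chrom = f[[1]], pos = as.integer(f[[2]]), vid = f[[3]],
                    ref = f[[4]], alt = f[[5]], qual = as.numeric(f[[6]]),
                    filt = f[[7]], info = f[[8]], fmt = f[[9]])
  nsmp <- length(sample_names)
  for (i in seq_len(nsmp)) set(rec, j = paste0("S", i), value = f[[9L + i]])
  set(rec, j = "infod", value = list(lapply(rec$info, parse_info)))
  getI <- function(ii, k, def = NA_character_) {
    v <- ii[[k]]; if (is.null(v)) def else v
  }
  # sample column mapping: first sample = normal (n_), second = tumour (t_)
  pref <- c("n", "t")[seq_len(nsmp)]
  parse_fmt <- function(fmt, val) {
    keys <- strsplit(fmt, ":")[[1]]
    vals <- strsplit(val, ":")[[1]]
    setNames(vals, keys)
  }
  rows <- list()
  done <- character(0)
  for (i in seq_len(nrow(rec))) {
    r <- rec[i]
    if (r$vid %in% done) next
    ii <- r$infod[[1]]
    pid <- getI(ii, "PARID")
    row <- list()
    if (!is.na(pid)) {
      # parse each pair from its canonical ("o"-suffixed) record
      if (grepl("h$", r$vid) && sub("h$", "o", r$vid) == pid &&
          any(rec$vid == pid)) next
      j <- which(rec$vid == pid)
      if (length(j) == 0L) {
        warning("orphan mate record: ", r$vid)
        ab <- parse_bnd_alt(r$alt)
        row <- list(type = "BE", chrom1 = r$chrom, pos1 = r$pos,
                    dir1 = ab$d1, chrom2 = NA_character_, pos2 = NA_integer_,
                    dir2 = NA_character_, insert = ab$ins,
                    breakend_seq = "", bealn = "",
                    orphan = TRUE)
      } else {
        j <- j[1]
        mate <- rec[j]
        ab <- parse_bnd_alt(r$alt)
        done <- c(done, mate$vid)
        row <- list(type = "BP", chrom1 = r$chrom, pos1 = r$pos, dir1 = ab$d1,
                    chrom2 = ab$c2, pos2 = ab$p2, dir2 = ab$d2,
                    insert = if (ab$d1 == DIR_HEAD) ab$ins else
                      if (nzchar(ab$ins)) revcomp(ab$ins) else "",
                    breakend_seq = "", bealn = "", orphan = FALSE)
        cirpos <- as.integer(strsplit(getI(ii, "CIRPOS", "0,0"), ",")[[1]])
        row$cipos2_lo <- cirpos[1]; row$cipos2_hi <- cirpos[2]
      }
    } else {
      # single breakend dot notation
      head <- grepl("\\.$", r$alt)
      bes <- getI(ii, "BESEQ", "")
      row <- list(type = "BE", chrom1 = r$chrom, pos1 = r$pos,
                  dir1 = if (head) DIR_HEAD else DIR_TAIL,
                  chrom2 = NA_character_, pos2 = NA_integer_,
                  dir2 = NA_character_, insert = "",
                  breakend_seq = bes,
                  bealn = getI(ii, "BEALN", ""), orphan = FALSE)
      row$cipos2_lo <- NA_integer_; row$cipos2_hi <- NA_integer_
    }
    cipos <- as.integer(strsplit(getI(ii, "CIPOS", "0,0"), ",")[[1]])
    row$cipos1_lo <- cipos[1]; row$cipos1_hi <- cipos[2]
    ihp <- getI(ii, "IHOMPOS")
    if (!is.na(ihp)) {
      ih <- as.integer(strsplit(ihp, ",")[[1]])
      row$ihompos_lo <- ih[1]; row$ihompos_hi <- ih[2]
    } else { row$ihompos_lo <- NA_integer_; row$ihompos_hi <- NA_integer_ }
    row$imprecise <- isTRUE(ii$IMPRECISE)
    row$homlen <- as.integer(getI(ii, "HOMLEN", "0"))
    row$homseq <- getI(ii, "HOMSEQ", "")
    row$svtype <- getI(ii, "SVCLASS", NA_character_)
    row$size <- as.integer(getI(ii, "SVLEN", NA_character_))
    row$beid <- getI(ii, "BEID", "")
    row$cq <- as.numeric(getI(ii, "CQ", NA_character_))
    row$sb <- as.numeric(getI(ii, "SB", NA_character_))
    row$anchor1 <- as.integer(getI(ii, "ANCHOR1", "0"))
    row$anchor2 <- as.integer(getI(ii, "ANCHOR2", "0"))
    row$linked_by <- getI(ii, "LINKED_BY", NA_character_)
    row$qual <- r$qual
    row$filter_status <- r$filt
    row$id <- sub("[oh]$", "", r$vid)
    for (si in seq_len(nsmp)) {
      fv <- parse_fmt(r$fmt, r[[paste0("S", si)]])
      p <- pref[si]
      for (k in VCF_FORMAT_INT)
        row[[fmt_col(p, k)]] <- if (k %in% names(fv))
          suppressWarnings(as.integer(fv[[k]])) else 0L
      for (k in VCF_FORMAT_FLOAT)
        row[[fmt_col(p, k)]] <- if (k %in% names(fv))
          suppressWarnings(as.numeric(fv[[k]])) else 0
    }
    rows[[length(rows) + 1L]] <- as.data.table(row)
  }
  out <- rbindlist(rows, use.names = TRUE, fill = TRUE)
  setcolorder(out, c("id", "type"))
  out[]
}

#' Export breakpoints as BEDPE
#' @param calls call table
#' @param path output file
#' @export
write_bedpe <- function(calls, path) {
  bp <- calls[type == "BP"]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   bp$chrom1, bp$pos1 - 1L, bp$pos1, bp$chrom2,
                   bp$pos2 - 1L, bp$pos2, bp$id,
                   vapply(bp$qual, num_fmt, character(1)),
                   ifelse(bp$dir1 == DIR_HEAD, "+", "-"),
                   ifelse(bp$dir2 == DIR_HEAD, "+", "-"))
  writeLines(lines, path)
  invisible(path)
}
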