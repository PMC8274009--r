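#' Read a SAM/BAM file into a read-record table
#'
#' Uses Rsamtools for parsing (SAM input is converted to BAM in a temporary
#' directory). Secondary, supplementary and duplicate records are dropped.
#'
#' @param path SAM or BAM file
#' @return data.table with one row per primary record: qname, flag, chrom,
#'   pos, mapq, cigar, mchrom, mpos, tlen, seq, strand, mate_mapq,
#'   mate_mapped, proper, mapped, end
#' @export
read_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq"),
    tag = c("MQ", "SA"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  mq <- x$tag$MQ
  if (is.null(mq)) mq <- rep(NA_integer_, n)
  sa <- x$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, n)
  dt <- data.table(
    qname = x$qname, flag = x$flag,
    chrom = as.character(x$rname), pos = x$pos, mapq = x$mapq,
    cigar = x$cigar, mchrom = as.character(x$mrnm), mpos = x$mpos,
    tlen = x$isize, seq = as.character(x$seq),
    mate_mapq = mq, sa_tag = sa)
  dt[, `:=`(
    mapped = bitwAnd(flag, 4L) == 0L,
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    proper = bitwAnd(flag, 2L) > 0L,
    first = bitwAnd(flag, 64L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L)]
  dt <- dt[!duplicate & !secondary]
  dt[, end := ifelse(mapped, pos + cigar_ref_span_vec(cigar) - 1L, pos)]
  dt[]
}

# accept either a path or an in-memory simulator table
as_read_table <- function(x) {
  if (is.character(x)) return(read_sam(x))
  dt <- copy(as.data.table(x))
  if (!"mapped" %in% names(dt)) dt[, mapped := bitwAnd(flag, 4L) == 0L]
  if (!"first" %in% names(dt)) dt[, first := bitwAnd(flag, 64L) > 0L]
  if (!"strand" %in% names(dt))
    dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  if (!"proper" %in% names(dt)) dt[, proper := bitwAnd(flag, 2L) > 0L]
  if (!"mate_mapped" %in% names(dt)) dt[, mate_mapped := bitwAnd(flag, 8L) == 0L]
  if (!"end" %in% names(dt))
    dt[, end := ifelse(mapped, pos + cigar_ref_span_vec(cigar) - 1L, pos)]
  if (!"sa_tag" %in% names(dt)) dt[, sa_tag := NA_character_]
  if (!"duplicate" %in% names(dt)) dt[, duplicate := FALSE]
  if (!"secondary" %in% names(dt)) dt[, secondary := FALSE]
  dt[]
}

#' Load a reference genome from FASTA or a svkit_genome
#' @param x FASTA path, `svkit_genome`, or named character vector
#' @return named character vector of chromosome sequences
#' @export
load_reference <- function(x) {
  if (inherits(x, "svkit_genome")) return(vapply(x$seqs, identity, character(1)))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}
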