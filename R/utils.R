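#' @import data.table
#' @importFrom stats rnorm runif setNames quantile rbinom
#' @importFrom utils head tail
NULL

# Internal breakend direction encoding:
#   HEAD: anchored bases lie at coordinates <= the breakend (novel sequence
#         continues to the right of it).
#   TAIL: anchored bases lie at coordinates >= the breakend (novel sequence
#         continues to the left).
DIR_HEAD <- "HEAD"
DIR_TAIL <- "TAIL"

other_dir <- function(d) ifelse(d == DIR_HEAD, DIR_TAIL, DIR_HEAD)

#' Reverse complement of character vectors of DNA
#' @param x character vector of DNA sequences (ACGTN)
#' @return character vector
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# closed-interval overlap
iv_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# run an expression under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# Levenshtein distance (base R adist)
edit_dist <- function(a, b) as.integer(utils::adist(a, b))

`%||%` <- function(a, b) if (is.null(a)) b else a
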