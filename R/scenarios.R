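# ---------------------------------------------------------------------------
# Bundled simulation scenarios: the fixed study conditions under which the
# caller is exercised and evaluated. Genome sizes are desk-scale (a few
# hundred kilobases) so a full run completes in minutes; coverage, purity,
# fragment geometry and variant spectra follow the package defaults
# (60x tumour / 40x normal, 100 bp reads, 300 +/- 30 bp fragments,
# error-free bases, purity 1).
# ---------------------------------------------------------------------------

#' Mixed somatic SV scenario: 20 rearrangements in unique sequence
#'
#' 16 deletions/duplications/inversions (all >= 50 bp) spaced along a
#' 100 kb chromosome, two more on a 30 kb chromosome, and two
#' translocations into dedicated target chromosomes. Insertions are absent
#' by design: at 100 bp reads an insertion of 50 bp or more leaves fewer
#' than 30 uniquely alignable bases of far flank in any single read, so it
#' is geometrically representable only as a breakend pair.
#' @param seed RNG seed
#' @param cov_tumour,cov_normal,purity study conditions (defaults 60/40/1)
#' @return sim_config
#' @export
sim_scenario_mixed <- function(seed = 1L, cov_tumour = 60, cov_normal = 40,
                               purity = 1.0) {
  g <- synth_genome(c(chr1 = 100000L, chr2 = 18000L, chr3 = 30000L,
                      chr4 = 18000L), seed = seed)
  pos1 <- seq(5000L, by = 5500L, length.out = 16L)
  svs <- rbind(
    sv_table("DEL", "chr1", pos1[1], size = 60L),
    sv_table("DEL", "chr1", pos1[2], size = 120L),
    sv_table("DEL", "chr1", pos1[3], size = 250L),
    sv_table("DEL", "chr1", pos1[4], size = 500L),
    sv_table("DEL", "chr1", pos1[5], size = 900L),
    sv_table("DEL", "chr1", pos1[6], size = 1500L),
    sv_table("DEL", "chr1", pos1[7], size = 2500L),
    sv_table("DUP", "chr1", pos1[8], size = 60L),
    sv_table("DUP", "chr1", pos1[9], size = 110L),
    sv_table("DUP", "chr1", pos1[10], size = 300L),
    sv_table("INV", "chr1", pos1[11], size = 160L),
    sv_table("INV", "chr1", pos1[12], size = 400L),
    sv_table("INV", "chr1", pos1[13], size = 800L),
    sv_table("DEL", "chr1", pos1[14], size = 700L),
    sv_table("DUP", "chr1", pos1[15], size = 450L),
    sv_table("DEL", "chr1", pos1[16], size = 51L),
    sv_table("TRA", "chr1", 95000L, "chr2", 9000L),
    sv_table("DEL", "chr3", 8000L, size = 400L),
    sv_table("DUP", "chr3", 16000L, size = 150L),
    sv_table("TRA", "chr3", 26000L, "chr4", 9000L))
  sim_config(g, svs, cov_tumour = cov_tumour, cov_normal = cov_normal,
             purity = purity, seed = seed)
}

#' Repeat-array single-breakend scenario
#'
#' `n` junctions from unique chromosomes into the interior of a 50-copy
#' 200 bp tandem repeat array; every junction's repeat side is ambiguous by
#' construction and must surface as a single breakend.
#' @param seed RNG seed
#' @param n number of planted junctions
#' @export
sim_scenario_repeat <- function(seed = 1L, n = 10L) {
  lens <- setNames(rep(8000L, n), paste0("chrU", seq_len(n)))
  g <- synth_genome(lens, repeat_array = list(chrom = "chrR", flank = 5000L,
                                              unit_len = 200L, copies = 50L),
                    seed = seed)
  svs <- sv_table(type = rep("BND_INTO_REPEAT", n),
                  chrom1 = paste0("chrU", seq_len(n)),
                  pos1 = 4000L + 150L * seq_len(n),
                  chrom2 = "chrR",
                  pos2 = as.integer(5200L + 900L * seq_len(n)))
  sim_config(g, svs, seed = seed)
}

#' Short-duplication scenario with minimum-size boundary events
#'
#' Tandem duplications of 32-100 bp, a 9 bp deletion (below any minimum
#' event size) and a 9 bp foldback inversion (exempt from it).
#' @param seed RNG seed
#' @export
sim_scenario_smalldup <- function(seed = 1L) {
  g <- synth_genome(c(chr1 = 60000L), seed = seed)
  svs <- rbind(
    sv_table("DUP", "chr1", 10000L, size = 32L),
    sv_table("DUP", "chr1", 20000L, size = 50L),
    sv_table("DUP", "chr1", 30000L, size = 100L),
    sv_table("DEL", "chr1", 40000L, size = 9L),
    sv_table("FOLDBACK", "chr1", 50000L, size = 9L))
  sim_config(g, svs, seed = seed)
}

#' Clustered three-junction chain scenario
#'
#' A derivative chromosome splicing two 100 bp segments from elsewhere on
#' the chromosome between distant loci: three precise junctions whose
#' discordant read pairs also generate spurious transitive candidates.
#' @param seed RNG seed
#' @export
sim_scenario_chain <- function(seed = 1L) {
  g <- synth_genome(c(chr1 = 60000L), seed = seed)
  segs <- list(chr1 = data.table(
    chrom = "chr1",
    start = c(1L, 30000L, 40000L, 50000L),
    end = c(20000L, 30099L, 40099L, 60000L),
    strand = "+"))
  truth <- data.table(
    chrom1 = "chr1", pos1 = c(20000L, 30099L, 40099L),
    dir1 = DIR_HEAD,
    chrom2 = "chr1", pos2 = c(30000L, 40000L, 50000L),
    dir2 = DIR_TAIL,
    type = "TRA", size = NA_integer_, expected_class = "BREAKPOINT",
    germline = FALSE)
  sim_config(g, sv_table(character(0), character(0), integer(0))[0],
             cov_tumour = 50, cov_normal = 35, seed = seed,
             tumour_segments = segs, truth = truth)
}
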