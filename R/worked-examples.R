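#' Curated wheat indel loci (wild emmer vs bread wheat)
#'
#' The eleven characterized large-scale rearrangement loci on wheat
#' chromosomes 3B and 5B, with their published breakpoint coordinates on
#' both assemblies (1-based closed), the printed locus lengths, and the
#' rearrangement type. Shipped as a plain-text table under
#' \code{inst/extdata/wheat_indel_loci.tsv}; locus lengths satisfy
#' \code{length == end - start + 1} on both genomes, the coordinate
#' convention used throughout the package.
#'
#' @return data.frame with columns \code{locus_id}, \code{chrom},
#'   \code{emmer_start}, \code{emmer_end}, \code{emmer_length},
#'   \code{bw_start}, \code{bw_end}, \code{bw_length}, \code{type}.
#' @export
wheat_indel_loci <- function() {
  path <- system.file("extdata", "wheat_indel_loci.tsv", package = "teindel")
  if (path == "")
    path <- file.path("inst", "extdata", "wheat_indel_loci.tsv")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Worked junction examples from the wheat indel loci
#'
#' Junction contexts for the six microhomology/SD-MMEJ loci (5B_3, 5B_4,
#' 3B_2, 3B_3, 3B_4, 3B_5). The published panels for these junctions are
#' figure images; these contexts are synthetic reconstructions that embed
#' the described motif layout exactly -- the 'A' and 'GCGT' microhomologies
#' bordering the 5B_3/5B_4 deletions, the 'AAATTTG' template 22 bp upstream
#' of the 3B_2 5' breakpoint, the 'G'-bounded 14-bp templated insertion
#' 'TCTAGCACAACTCC' with its 'TCT' direct repeat 20 bp downstream of the
#' 3B_4 3' breakpoint, the 'GATC' motif 29 bp downstream of the 3B_5 3'
#' breakpoint, and the 'GT'/'CCCC' arrangement at 3B_3 -- inside fixed
#' random filler. Deleted segments are shortened placeholders (the
#' megabase-scale lengths live in \code{\link{wheat_indel_loci}}).
#'
#' For each locus: \code{left} ends at the 5' breakpoint, \code{deleted} is
#' the (placeholder) deleted segment, \code{right} starts at the 3'
#' breakpoint, \code{net} is the net insertion observed at the derived
#' junction. The donor locus is \code{left + deleted + right}; the derived
#' junction is \code{left + net + right}.
#'
#' @return named list of loci, each a list with \code{left},
#'   \code{deleted}, \code{right}, \code{net}.
#' @export
worked_junction_examples <- function() {
  list(
    `5B_3` = list(
      left = "CGTAGCCTCAGTAACCGGCGAGATCGCGCTGGGCCTACCGCTCCAACAGGACTGAGCTAAAACGGCCTGC",
      deleted = "ACACTTTCGCATCCATACACCTCGTAAGCGCAAATGCGCGGTCAGTACTTTTAGTTAAGGG",
      right = "AGGTGCGCAACGACATGCTGCGTCTGGTACAATCGAAAACATTGCGGATAAGAACAGTTGCAATGCGGATC",
      net = ""),
    `5B_4` = list(
      left = "GAGAAGGCACTTCATCTAAGCCGCTTTGAGGTGTGCACCGTTATCTCCGTATAAGAACTAGGGGATTTAG",
      deleted = "GCGTACAAGACTCACGTAGGAGGATGAACCGGTTACAGCTCGTTGTGAATCCGGCCAGGTGTTC",
      right = "GCGTGGACCGGGCAACGCTCTGATAATTTTCAGAATTTGACCTGCCCGTTGAATGGAGAAGCTGCGATAC",
      net = ""),
    `3B_2` = list(
      left = "GTCGGTGGGATCCCGGGGATCACGATAAGACTTCACTCTAAAATTTGCTCGCGGGTTGGGTCGCCTTCGA",
      deleted = "TCAAAGCTGGCTGTTTTGCATTTCCGAGACGCCGACCTCGTCGTAAAAACCTGTGTACAC",
      right = "TTGAGTCTACTAGTCAGGGAGCACCTACGTCTGAGGACTGCTGGGGTAAACCGTTTACGTTCCGAGCCG",
      net = "AAT"),
    `3B_3` = list(
      left = "TGCTAAGCTCCGCCGCCCTGCAATGGCCGGAAATTATAATCTATGACACTGTGTCCCCAGAGGT",
      deleted = "GGCATCCGTGTATGGTATCACACTATGCCCTTGCCTAACATGGACTGTCCAATCAATCAG",
      right = "CCCCGATCTTCGAGGGCAAATTTGGATCGGACTTTTCAATCCCGGGGCCTTCAGCCCGGGATTT",
      net = ""),
    `3B_4` = list(
      left = "TACAAACCCACCCCCCCGCTCGCCCTGAATAACTGCCTACGTAGCTGTGTGGTTGCCCGAG",
      deleted = "TCGTGAACGGGACGCAGTGTCGCAACGTGCGAGGGTAACTTGGTCTCCTCTGCTTTCTAG",
      right = "GTCTTTACTATTTAATTTCCATCTAGCACAACTCCGTCGAGTTGGCAAAGGGAATCGGGATACTTATGGGTCACACGC",
      net = "TCTAGCACAACTCC"),
    `3B_5` = list(
      left = "GCCGTCCGCTGGCCAGTTAGTGCGCGTCACATATGCCGGTGCCAATGTATAACCAACACCGA",
      deleted = "GTAAGATAAGCAGTACTTTACAAGCGACCCAGAGACGGTGCCGACTCGCCTGGTCATACC",
      right = "TCAAACTAGCACTGTTAACGTGTACAACGGGGATCATCATGCAACTGATAATCTCGGAAGGTACCAACTT",
      net = "")
  )
}

#' Donor locus and deletion interval of a worked example
#'
#' Convenience accessor assembling \code{left + deleted + right} with the
#' deletion interval in donor coordinates.
#'
#' @param example one element of \code{\link{worked_junction_examples}}.
#' @return list(\code{donor}, \code{deletion}, \code{derived_junction}).
#' @export
worked_example_donor <- function(example) {
  donor <- paste0(example$left, example$deleted, example$right)
  list(donor = donor,
       deletion = c(nchar(example$left) + 1L,
                    nchar(example$left) + nchar(example$deleted)),
       derived_junction = paste0(example$left, example$net, example$right))
}
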