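#' Genome build: ordered autosome coordinate frame
#'
#' A genome build is the coordinate frame for all fraction-of-chromosome
#' arithmetic: an ordered set of chromosome names with their lengths in bp.
#' The default build contains exactly the 22 human autosomes (GRCh38
#' lengths); scoring sums over all 22 autosomes, so sex chromosomes are
#' intentionally absent.
#'
#' @param chromosome character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` with columns `chromosome` and `length`, of class
#'   `genome_build`.
#' @examples
#' b <- genome_build(c("chr1", "chr2"), c(1e6, 2e6))
#' @export
genome_build <- function(chromosome, length) {
  chromosome <- as.character(chromosome)
  length <- as.numeric(length)
  if (length(chromosome) != length(length))
    stop("chromosome and length must have equal length")
  if (anyDuplicated(chromosome))
    stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(
    data.frame(chromosome = chromosome, length = length,
               stringsAsFactors = FALSE),
    class = c("genome_build", "data.frame")
  )
}

# GRCh38 primary-assembly autosome lengths
.grch38_autosomes <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468
)

#' Default genome build (GRCh38 autosomes)
#'
#' @param style chromosome naming style: `"chr"` (UCSC, `chr1`...`chr22`) or
#'   `"plain"` (`1`...`22`). Input readers normalise either style, so this
#'   only affects the names carried by the build.
#' @return A [genome_build] of the 22 human autosomes.
#' @export
default_build <- function(style = c("chr", "plain")) {
  style <- match.arg(style)
  nm <- names(.grch38_autosomes)
  if (style == "plain") nm <- sub("^chr", "", nm)
  genome_build(nm, unname(.grch38_autosomes))
}

# Map heterogeneous chromosome labels ("1", "chr1", " Chr1 ") onto the
# build's names. Returns a character vector aligned with `x`; NA where the
# label has no counterpart in the build.
normalize_chromosome <- function(x, build) {
  x <- trimws(as.character(x))
  key <- tolower(sub("^chr", "", x))
  bkey <- tolower(sub("^chr", "", build$chromosome))
  build$chromosome[match(key, bkey)]
}
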