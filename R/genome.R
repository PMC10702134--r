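# GRCh37 chromosome scaffold used by the simulator and the pericentromeric
# windowing. Lengths are the standard assembly lengths; centromere positions
# are approximate midpoints (sufficient for arm assignment).

CHROMOSOMES <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

CHROM_LENGTH <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
)

CHROM_CENTROMERE <- c(
  "1" = 125000000, "2" = 93300000, "3" = 91000000, "4" = 50400000,
  "5" = 48400000, "6" = 61000000, "7" = 59900000, "8" = 45600000,
  "9" = 49000000, "10" = 40200000, "11" = 53700000, "12" = 35800000,
  "13" = 17900000, "14" = 17600000, "15" = 19000000, "16" = 36600000,
  "17" = 24000000, "18" = 17200000, "19" = 26500000, "20" = 27500000,
  "21" = 13200000, "22" = 14700000, "X" = 60600000, "Y" = 12500000
)

#' Validate a chromosome label
#' @param chrom character vector of chromosome labels
#' @return the labels, normalised to character
#' @keywords internal
check_chromosome <- function(chrom) {
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), CHROMOSOMES)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  chrom
}

#' Construct a SNP panel definition
#'
#' A panel is the set of array SNP positions against which all samples are
#' genotyped: one row per SNP with its identifier, chromosome and 1-based
#' GRCh37 position. Alleles are the Illumina A/B abstraction and are implicit.
#'
#' @param snp_id character vector of unique SNP identifiers
#' @param chromosome chromosome labels (1-22, X, Y)
#' @param position 1-based base-pair positions
#' @return a `data.frame` of class `snp_panel`, ordered by chromosome then
#'   position
#' @export
snp_panel <- function(snp_id, chromosome, position) {
  chromosome <- check_chromosome(chromosome)
  position <- as.integer(position)
  if (any(position < 1L)) stop("SNP positions must be >= 1")
  if (anyDuplicated(snp_id)) stop("snp_id must be unique within a panel")
  chr_ord <- match(chromosome, CHROMOSOMES)
  o <- order(chr_ord, position)
  out <- data.frame(snp_id = as.character(snp_id)[o],
                    chromosome = chromosome[o],
                    position = position[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "SNPs on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  invisible(x)
}
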