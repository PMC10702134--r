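#' One genotyped sample on a SNP panel
#'
#' Holds one SNP-array sample: the GenomeStudio-style AB genotype call plus
#' B-allele frequency (BAF) and log R ratio (LRR) per panel SNP. Genotypes are
#' one of `AA`, `AB`, `BB`, `NC`; BAF/LRR may be missing (`NA`), including for
#' called SNPs, and `NC` SNPs may still carry BAF/LRR.
#'
#' @param sample_id sample identifier
#' @param role one of "father", "mother", "embryo"
#' @param records data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `gtype`, `baf`, `lrr`; one row per panel SNP
#' @return object of class `sample_array`
#' @export
sample_array <- function(sample_id, role, records) {
  role <- match.arg(role, c("father", "mother", "embryo"))
  need <- c("snp_id", "chromosome", "position", "gtype", "baf", "lrr")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$snp_id))
    stop("duplicate snp_id in records for sample ", sample_id)
  bad <- !(records$gtype %in% c("AA", "AB", "BB", "NC"))
  if (any(bad)) stop("invalid genotype value(s): ",
                     paste(unique(records$gtype[bad]), collapse = ", "))
  if (any(!is.na(records$baf) & (records$baf < 0 | records$baf > 1)))
    stop("BAF values must lie in [0, 1]")
  chr_ord <- match(as.character(records$chromosome), CHROMOSOMES)
  records <- records[order(chr_ord, records$position), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(sample_id = sample_id, role = role, records = records),
            class = "sample_array")
}

#' @export
print.sample_array <- function(x, ...) {
  cat(sprintf("<sample_array> %s (%s): %d SNPs, call rate %.3f\n",
              x$sample_id, x$role, nrow(x$records), compute_call_rate(x)))
  invisible(x)
}

#' Genotype call rate of a sample
#'
#' The fraction of panel SNPs with a non-missing (non-`NC`) genotype call —
#' the whole-genome-amplification quality metric used for the QC gate in the
#' discordance workflow.
#'
#' @param sample a [sample_array()]
#' @return fraction in `[0, 1]`
#' @export
compute_call_rate <- function(sample) {
  n <- nrow(sample$records)
  if (n == 0L) stop("sample has no records")
  sum(sample$records$gtype != "NC") / n
}

#' Genotypes of a sample at given SNPs
#' @keywords internal
gtype_at <- function(sample, snp_ids) {
  sample$records$gtype[match(snp_ids, sample$records$snp_id)]
}

#' @keywords internal
baf_at <- function(sample, snp_ids) {
  sample$records$baf[match(snp_ids, sample$records$snp_id)]
}
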