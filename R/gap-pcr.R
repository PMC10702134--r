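# Interpretation of fluorescent Gap-PCR peak data. The SEA assay uses three
# primers: the flanking pair amplifies a 178-bp product only from the deleted
# allele (the intervening sequence is gone), while an internal primer pair
# yields a 280-bp product only from the intact allele. Dyes: 280 bp = FAM,
# 178 bp = HEX.

PCR_PRODUCTS <- data.frame(
  allele = c("normal", "deletion"),
  size_bp = c(280L, 178L),
  dye = c("FAM", "HEX"),
  stringsAsFactors = FALSE)

# Primer sequences of the assay, carried as metadata constants only.
SEA_PRIMERS <- c(
  S1 = "gtgttctcagtattggagggaa",
  S2 = "gacacgcttccaatacgctta",
  S3 = "ctactgcagccttgaactcc")

#' Call a SEA genotype from Gap-PCR peaks
#'
#' A peak within `size_tolerance` of 280 bp above the height threshold
#' asserts a normal allele; one near 178 bp asserts a deletion allele. Both
#' present: CARRIER (--/aa); only 280: NORMAL (aa/aa); only 178: AFFECTED
#' (--/--); neither: FAIL. The default height threshold is relative: 10% of
#' the tallest peak in the lane. A dye inconsistent with the product size
#' raises a warning (not an error); peak files may omit dye.
#'
#' @param peaks data.frame with `size_bp`, `height` and optionally `dye`
#'   (one sample's lane)
#' @param min_height absolute height threshold, or NULL for the relative
#'   default
#' @param size_tolerance matching window in bp around each product size
#' @param rel_height relative threshold (fraction of the tallest peak) used
#'   when `min_height` is NULL
#' @return character scalar in `NORMAL`, `CARRIER`, `AFFECTED`, `FAIL`, with
#'   attribute `evidence` (the matched peaks)
#' @export
call_pcr_genotype <- function(peaks, min_height = NULL, size_tolerance = 3,
                              rel_height = 0.10) {
  if (size_tolerance <= 0 || (!is.null(min_height) && min_height <= 0))
    stop("thresholds must be positive")
  if (abs(280 - 178) <= 2 * size_tolerance)
    stop("size tolerance windows for the two products overlap")
  if (nrow(peaks) == 0L)
    return(structure("FAIL", evidence = peaks))
  thr <- if (is.null(min_height)) rel_height * max(peaks$height) else min_height
  ok <- peaks$height >= thr
  near <- function(target) ok & abs(peaks$size_bp - target) <= size_tolerance
  is_norm <- near(280); is_del <- near(178)
  if (!is.null(peaks$dye)) {
    mism <- (is_norm & !is.na(peaks$dye) & peaks$dye != "FAM") |
      (is_del & !is.na(peaks$dye) & peaks$dye != "HEX")
    if (any(mism)) warning("peak dye inconsistent with product size")
  }
  value <- if (any(is_norm) && any(is_del)) "CARRIER"
  else if (any(is_norm)) "NORMAL"
  else if (any(is_del)) "AFFECTED"
  else "FAIL"
  structure(value, evidence = peaks[is_norm | is_del, , drop = FALSE])
}

#' Compare first and retest Gap-PCR calls for allele-dropout evidence
#'
#' A homozygous first call that becomes CARRIER on retest indicates allele
#' dropout in the first reaction: a first NORMAL call means the mutant
#' (deletion) allele dropped, a first AFFECTED call means the normal allele
#' dropped. Identical homozygous calls are reported as `still_single_peak`
#' (the resolution engine decides what that means); other identical calls are
#' `consistent`.
#'
#' @param first,retest genotype calls from [call_pcr_genotype()]
#' @return list with `verdict` ("consistent", "ado_suspected",
#'   "still_single_peak") and `dropped` ("mutant", "normal" or NA)
#' @export
compare_pcr_runs <- function(first, retest) {
  first <- as.character(first); retest <- as.character(retest)
  if (first == "FAIL" || retest == "FAIL")
    stop("cannot compare runs with a FAIL call")
  if (first == retest) {
    verdict <- if (first %in% c("NORMAL", "AFFECTED")) "still_single_peak"
    else "consistent"
    return(list(verdict = verdict, dropped = NA_character_))
  }
  if (retest == "CARRIER" && first == "NORMAL")
    return(list(verdict = "ado_suspected", dropped = "mutant"))
  if (retest == "CARRIER" && first == "AFFECTED")
    return(list(verdict = "ado_suspected", dropped = "normal"))
  # remaining disagreements (e.g. NORMAL then AFFECTED) are unexplained
  list(verdict = "inconsistent", dropped = NA_character_)
}

#' Genotype display string for a PCR-level call
#' @param call "NORMAL", "CARRIER" or "AFFECTED"
#' @return e.g. `"--/aa"` for CARRIER
#' @export
genotype_string <- function(call) {
  unname(SEA_GENOTYPES[as.character(call)])
}
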