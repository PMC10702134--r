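# End-to-end analysis of one family: Gap-PCR calls, reference selection,
# phasing, per-embryo haplotype calls, genome-wide aneuploidy screen, and
# the discordance-resolution workflow.

#' Analyse a whole family
#'
#' Runs the complete comprehensive-PGT workflow: per-embryo Gap-PCR
#' genotypes from peak data; genome-wide aneuploidy screening; selection of
#' a phasing reference (a homozygous affected embryo preferentially, then a
#' homozygous normal one, then the carrier-pair fallback); parental phasing;
#' per-embryo haplotype genotypes; and the PCR-vs-haplotype discordance
#' resolution with retest/rebiopsy providers. Returns finalized reports, the
#' cohort summary and a transfer prioritisation.
#'
#' @param father,mother parental [sample_array()]s
#' @param embryos named list of embryo [sample_array()]s
#' @param peaks data.frame of Gap-PCR peaks covering all embryos (`sample`
#'   column), or a named list of per-embryo peak data.frames
#' @param config a [family_config()]
#' @param retest_provider NULL or `function(embryo_id)` returning a PCR call
#' @param rebiopsy_provider NULL or `function(embryo_id)` returning a list
#'   with `pcr`, `call_rate`, optionally `haplotype`
#' @param qc_threshold call-rate QC gate
#' @param cnv cnv options from [cnv_options()]
#' @param min_informative,majority,min_block haplotype-calling thresholds
#'   (see [call_embryo_haplotype()])
#' @return list of class `pgt_family_analysis`: `reports`, `summary`,
#'   `transfer`, `phase`, `informative`, `screens`, `pcr`, `reference`
#' @export
analyze_family <- function(father, mother, embryos, peaks,
                           config = family_config(),
                           retest_provider = NULL, rebiopsy_provider = NULL,
                           qc_threshold = 0.90, cnv = cnv_options(),
                           min_informative = 3, majority = 0.8,
                           min_block = 3) {
  if (is.data.frame(peaks))
    peaks <- split(peaks, peaks$sample)
  ids <- names(embryos)
  pcr <- lapply(ids, function(id) {
    pk <- peaks[[id]]
    if (is.null(pk) || !nrow(pk)) "FAIL" else call_pcr_genotype(pk)
  })
  names(pcr) <- ids
  call_rates <- vapply(embryos, compute_call_rate, numeric(1))

  informative <- find_informative_snps(father, mother, config)
  screens <- lapply(embryos, function(e)
    genome_screen(e, father, mother, cnv, config = config))

  chr16_cn <- vapply(screens, function(s) {
    cc <- s$calls[[config$locus$chrom]]
    if (is.null(cc) || is.na(cc$copy_number)) NA_integer_ else cc$copy_number
  }, integer(1))

  # reference selection: homozygous PCR genotype, chr16 disomic, good QC
  pcr_chr <- vapply(pcr, as.character, character(1))
  ok_ref <- !is.na(chr16_cn) & chr16_cn == 2L & call_rates >= qc_threshold
  ref_candidates <- c(ids[pcr_chr == "AFFECTED" & ok_ref],
                      ids[pcr_chr == "NORMAL" & ok_ref])
  phase <- NULL; reference <- NULL
  for (ref_id in ref_candidates) {
    cand <- tryCatch(
      phase_from_reference(embryos[[ref_id]], pcr_chr[[ref_id]],
                           informative),
      error = function(e) NULL)
    if (!is.null(cand)) {
      phase <- cand
      reference <- list(kind = tolower(pcr_chr[[ref_id]]), ids = ref_id)
      break
    }
  }
  if (is.null(phase)) {
    carriers <- ids[pcr_chr == "CARRIER" & ok_ref]
    if (length(carriers) >= 2) {
      pairs <- utils::combn(carriers[seq_len(min(4, length(carriers)))], 2)
      for (k in seq_len(ncol(pairs))) {
        cand <- phase_from_carrier_pair(embryos[[pairs[1, k]]],
                                        embryos[[pairs[2, k]]], informative,
                                        config = config,
                                        father = father, mother = mother,
                                        min_informative = min_informative)
        if (!is.null(cand$father)) {
          phase <- cand
          reference <- list(kind = "carrier_pair", ids = pairs[, k])
          break
        }
      }
    }
  }
  if (is.null(phase))
    stop("no usable phasing reference: need a homozygous embryo or a ",
         "consistent carrier pair")

  haplo <- lapply(ids, function(id) {
    pc <- call_embryo_haplotype(embryos[[id]], phase$father, informative,
                                config, min_informative, majority, min_block)
    mc <- call_embryo_haplotype(embryos[[id]], phase$mother, informative,
                                config, min_informative, majority, min_block)
    haplotype_genotype(pc, mc)
  })
  names(haplo) <- ids

  # annotate chr16 monosomies with the retained haplotype's risk status
  for (id in ids) {
    cc <- screens[[id]]$calls[[config$locus$chrom]]
    if (!is.null(cc) && !is.na(cc$copy_number) && cc$copy_number == 1L &&
        !is.na(cc$retained_parent)) {
      hc <- call_embryo_haplotype(embryos[[id]], phase[[cc$retained_parent]],
                                  informative, config, min_informative,
                                  majority, min_block, hemizygous = TRUE)
      screens[[id]]$calls[[config$locus$chrom]]$retained_risk <-
        switch(hc$locus_side_verdict, RISK = TRUE, NONRISK = FALSE, NA)
    }
  }

  reports <- lapply(ids, function(id) {
    finalize_embryo(
      id, pcr_chr[[id]], haplo[[id]], screens[[id]], call_rates[[id]],
      retest = if (!is.null(retest_provider)) function() retest_provider(id),
      rebiopsy = if (!is.null(rebiopsy_provider))
        function() rebiopsy_provider(id),
      qc_threshold = qc_threshold, config = config)
  })
  names(reports) <- ids

  structure(list(reports = reports, summary = cohort_summary(reports),
                 transfer = transfer_priority(reports, informative),
                 phase = phase, informative = informative,
                 screens = screens, pcr = pcr, reference = reference),
            class = "pgt_family_analysis")
}

#' @export
print.pgt_family_analysis <- function(x, ...) {
  cat("PGT family analysis —", length(x$reports), "embryos, reference:",
      x$reference$kind, "\n")
  for (r in x$reports)
    cat(sprintf("  %s: PCR %s | haplotype %s | final %s (%s)\n",
                r$embryo_id, r$pcr_genotype, r$haplotype_genotype,
                r$final_genotype, r$cause))
  print(x$summary)
  invisible(x)
}
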