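# Loaders for the published-case fixtures shipped with the package: the
# 25-family informative-SNP count table and the 10 discordant embryos with
# their resolution evidence.

#' Published informative-SNP counts (25 families)
#'
#' Per-family counts of maternal and paternal informative SNPs in the
#' upstream 5' flank, the HBA1+HBA2 genes and the downstream 3' flank, as a
#' long data.frame ready for [informative_snp_stats()].
#'
#' @return data.frame with columns `family`, `parent`, `flank`, `n`
#' @export
published_informative_counts <- function() {
  path <- system.file("extdata", "table4_informative_snp_counts.tsv",
                      package = "alphapgt", mustWork = TRUE)
  wide <- read.delim(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("maternal", "paternal"), function(p) {
    do.call(rbind, lapply(c("upstream_5p", "in_gene", "downstream_3p"),
                          function(fl) data.frame(
      family = as.character(wide$family),
      parent = c(maternal = "mother", paternal = "father")[[p]],
      flank = fl, n = wide[[paste(p, fl, sep = "_")]],
      stringsAsFactors = FALSE)))
  }))
  rownames(long) <- NULL
  long
}

#' Published discordant embryo cases
#'
#' The ten embryos whose Gap-PCR and haplotype results disagreed, encoded
#' with the evidence the resolution workflow consumes (first-pass calls,
#' chromosome-16 CNV review, call rate, retest/rebiopsy outcomes) plus the
#' published final genotype and cause for cross-checking.
#'
#' @return list of case lists
#' @export
published_discordant_cases <- function() {
  path <- system.file("extdata", "table3_discordant_cases.yaml",
                      package = "alphapgt", mustWork = TRUE)
  yaml::read_yaml(path)$cases
}

# Minimal haplotype_call stub carrying a locus verdict.
stub_haplotype_call <- function(parent, verdict) {
  n <- if (verdict %in% c("RISK", "NONRISK")) 10L else 0L
  new_haplotype_call("case", parent, verdict,
                     support = if (verdict == "RISK") n else 0L,
                     conflict = if (verdict == "NONRISK") n else 0L,
                     skipped = 0L, per_flank = NULL,
                     breakpoint_interval = NULL, locus_side_verdict = verdict)
}

#' Run the resolution workflow on one published case
#'
#' Reconstructs the evidence objects (haplotype genotype with per-parent
#' locus verdicts, chromosome-16 CNV call, retest/rebiopsy providers) from a
#' case fixture and routes it through [finalize_embryo()].
#'
#' @param case one element of [published_discordant_cases()]
#' @return an `embryo_report`
#' @export
resolve_published_case <- function(case) {
  hc <- case$haplotype
  haplo <- haplotype_genotype(stub_haplotype_call("father", hc$paternal),
                              stub_haplotype_call("mother", hc$maternal))
  # keep the printed wording and genotype even where the combined call is
  # confounded (the stubs reproduce the per-parent locus evidence)
  haplo$genotype <- hc$genotype
  haplo$annotation <- hc$annotation
  cv <- case$chr16_cnv
  cnv <- new_cnv_call("16", as.integer(cv$copy_number),
                      origin_parent = cv$origin %||% cv$lost %||% NA_character_,
                      stage = cv$stage %||% NA_character_,
                      retained_parent = cv$retained %||% NA_character_,
                      retained_risk = cv$retained_risk %||% NA)
  screen <- structure(list(calls = setNames(list(cnv), "16"),
                           euploid = cnv$copy_number == 2L, status = "ok"),
                      class = "genome_screen")
  finalize_embryo(case$id, case$pcr, haplo, screen, case$call_rate,
                  retest = case$retest,
                  rebiopsy = case$rebiopsy)
}
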