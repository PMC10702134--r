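# The workflow engine: compare the Gap-PCR genotype with the haplotype
# genotype, resolve discordances through chromosome-16 CNV evidence, PCR
# retest and embryo rebiopsy, apply the call-rate QC gate, and produce final
# per-embryo reports, cohort summaries and a transfer prioritisation.

#' Compare PCR and haplotype genotype calls
#'
#' @param pcr Gap-PCR call ("NORMAL"/"CARRIER"/"AFFECTED"/"FAIL")
#' @param haplo a `haplo_genotype` (or its genotype string)
#' @return list with `concordant` (logical) and `reason`
#' @export
compare_calls <- function(pcr, haplo) {
  hg <- if (inherits(haplo, "haplo_genotype")) haplo$genotype
  else as.character(haplo)
  pcr <- as.character(pcr)
  if (hg == "UNDETERMINED")
    return(list(concordant = FALSE, reason = "haplotype unavailable"))
  if (pcr == "FAIL")
    return(list(concordant = FALSE, reason = "PCR unavailable"))
  if (pcr == hg) list(concordant = TRUE, reason = "match")
  else list(concordant = FALSE,
            reason = sprintf("PCR %s vs haplotype %s", pcr, hg))
}

# Final three-allele genotype string of a chromosome-16 trisomy.
# The origin parent (a carrier) contributes one risk and one non-risk
# haplotype after an MI error, or a double dose of a single haplotype after
# an MII error; the other parent contributes one haplotype whose risk status
# comes from its haplotype call. The deletion-allele count consistent with
# the observed PCR alleles resolves the MII ambiguity.
trisomy_genotype_string <- function(stage, other_parent_risk, pcr) {
  other <- as.integer(isTRUE(other_parent_risk))
  candidates <- if (is.na(stage)) 0:2 + other
  else if (stage == "MII") c(0L, 2L) + other
  else 1L + other
  feasible <- switch(as.character(pcr),
                     NORMAL = 0L, AFFECTED = 3L, CARRIER = 1:2,
                     0:3)
  r <- intersect(candidates, feasible)
  if (length(r) != 1L) return(NA_character_)
  paste(c(rep(ALLELE_DEL, r), rep(ALLELE_NORM, 3L - r)), collapse = "/")
}

#' Resolve a PCR/haplotype discordance
#'
#' Decision tree, in order: (1) chromosome-16 trisomy explains the
#' discordance (the extra homolog confuses the haplotype; final genotype is
#' the three-allele string); (2) chromosome-16 monosomy (final genotype is
#' the single retained allele); (3) a call rate below the QC threshold
#' triggers a rebiopsy — if the rebiopsy concurs with the original PCR the
#' first array data are discarded as poor-quality WGA; (4) otherwise the PCR
#' is retested — a retest that flips to match the haplotype establishes
#' allele dropout in the first reaction; (5) a persistent conflict after
#' retest goes to rebiopsy and, failing that, stays unresolved (excluded
#' from transfer).
#'
#' @param pcr first-pass Gap-PCR call
#' @param haplo a `haplo_genotype`
#' @param chr16_cnv `cnv_call` for the locus chromosome
#' @param call_rate the sample's genotype call rate
#' @param retest NULL, a PCR call, or a zero-argument function returning one
#' @param rebiopsy NULL, or a list / zero-argument function returning a list
#'   with `pcr`, `call_rate` and optionally `haplotype` (genotype string)
#' @param qc_threshold call-rate QC gate
#' @return list with `final_genotype`, `cause`, `retest`, `rebiopsy`
#' @export
resolve_discordance <- function(pcr, haplo, chr16_cnv, call_rate,
                                retest = NULL, rebiopsy = NULL,
                                qc_threshold = 0.90) {
  pcr <- as.character(pcr)
  provide <- function(p) if (is.function(p)) p() else p
  hg <- if (inherits(haplo, "haplo_genotype")) haplo else
    list(genotype = as.character(haplo), risk_from = c(father = NA, mother = NA))

  if (!is.null(chr16_cnv) && !is.na(chr16_cnv$copy_number) &&
      chr16_cnv$copy_number == 3L) {
    origin <- chr16_cnv$origin_parent
    other <- if (identical(origin, "father")) "mother" else "father"
    other_risk <- hg$risk_from[[other]]
    if (is.na(other_risk) && !is.null(hg[[c(father = "paternal",
                                            mother = "maternal")[[other]]]])) {
      # the overall haplotype genotype may be undetermined (the trisomic
      # chromosome confuses the origin parent's call) while the other
      # parent's call is still clean
      oc <- hg[[c(father = "paternal", mother = "maternal")[[other]]]]
      other_risk <- switch(oc$locus_side_verdict %||% oc$verdict,
                           RISK = TRUE, NONRISK = FALSE, NA)
    }
    final <- trisomy_genotype_string(chr16_cnv$stage, other_risk, pcr)
    if (is.na(final)) final <- "undetermined"
    return(list(final_genotype = final,
                cause = "TRISOMY16_BPH", retest = NULL, rebiopsy = NULL))
  }
  if (!is.null(chr16_cnv) && !is.na(chr16_cnv$copy_number) &&
      chr16_cnv$copy_number == 1L) {
    final <- if (isTRUE(chr16_cnv$retained_risk)) ALLELE_DEL
    else if (isFALSE(chr16_cnv$retained_risk)) ALLELE_NORM
    else "undetermined"
    return(list(final_genotype = final, cause = "MONOSOMY16",
                retest = NULL, rebiopsy = NULL))
  }
  if (call_rate < qc_threshold) {
    rb <- provide(rebiopsy)
    if (is.null(rb))
      return(list(final_genotype = "undetermined", cause = "UNRESOLVED",
                  retest = NULL, rebiopsy = "pending"))
    if (pcr != "FAIL" && identical(as.character(rb$pcr), pcr))
      return(list(final_genotype = genotype_string(pcr),
                  cause = "POOR_WGA_QUALITY", retest = NULL, rebiopsy = rb))
    return(list(final_genotype = "undetermined", cause = "UNRESOLVED",
                retest = NULL, rebiopsy = rb))
  }
  rt <- provide(retest)
  if (is.null(rt))
    return(list(final_genotype = "undetermined", cause = "UNRESOLVED",
                retest = "pending", rebiopsy = NULL))
  rt <- as.character(rt)
  if (pcr == "FAIL" && rt != "FAIL" && rt == hg$genotype) {
    # the first reaction failed entirely; the repeat succeeded and agrees
    # with the haplotype, so the conflict was amplification quality
    return(list(final_genotype = genotype_string(rt),
                cause = "POOR_WGA_QUALITY", retest = rt, rebiopsy = NULL))
  }
  if (rt != "FAIL" && pcr != "FAIL" && rt != pcr && rt == hg$genotype) {
    dir <- compare_pcr_runs(pcr, rt)
    cause <- if (identical(dir$dropped, "mutant")) "ADO_MUTANT_ALLELE"
    else if (identical(dir$dropped, "normal")) "ADO_NORMAL_ALLELE"
    else "UNRESOLVED"
    final <- if (cause == "UNRESOLVED") "undetermined"
    else genotype_string(hg$genotype)
    return(list(final_genotype = final, cause = cause, retest = rt,
                rebiopsy = NULL))
  }
  rb <- provide(rebiopsy)
  if (!is.null(rb) && pcr != "FAIL" && identical(as.character(rb$pcr), pcr) &&
      (is.null(rb$haplotype) || identical(rb$haplotype, genotype_string(pcr)) ||
         identical(rb$haplotype, pcr)))
    return(list(final_genotype = genotype_string(pcr),
                cause = "POOR_WGA_QUALITY", retest = rt, rebiopsy = rb))
  list(final_genotype = "undetermined", cause = "UNRESOLVED", retest = rt,
       rebiopsy = rb %||% "pending")
}

#' Assemble the final report for one embryo
#'
#' Concordant embryos take the shared genotype (cause CONCORDANT);
#' discordant ones are routed through [resolve_discordance()]. The euploid
#' flag comes from the genome screen.
#'
#' @param embryo_id embryo identifier
#' @param pcr first-pass Gap-PCR call
#' @param haplo a `haplo_genotype`
#' @param screen a `genome_screen` (or NULL)
#' @param call_rate genotype call rate of the sample
#' @param retest,rebiopsy providers passed to [resolve_discordance()]
#' @param qc_threshold call-rate QC gate
#' @param config a [family_config()]
#' @return object of class `embryo_report`
#' @export
finalize_embryo <- function(embryo_id, pcr, haplo, screen, call_rate,
                            retest = NULL, rebiopsy = NULL,
                            qc_threshold = 0.90, config = family_config()) {
  chr16_cnv <- if (!is.null(screen)) screen$calls[[config$locus$chrom]]
  cmp <- compare_calls(pcr, haplo)
  if (cmp$concordant) {
    res <- list(final_genotype = genotype_string(pcr), cause = "CONCORDANT",
                retest = NULL, rebiopsy = NULL)
  } else {
    res <- resolve_discordance(pcr, haplo, chr16_cnv, call_rate, retest,
                               rebiopsy, qc_threshold)
  }
  structure(list(
    embryo_id = embryo_id, pcr_genotype = as.character(pcr),
    haplotype_genotype = if (inherits(haplo, "haplo_genotype")) haplo$genotype
    else as.character(haplo),
    haplotype_annotation = if (inherits(haplo, "haplo_genotype"))
      haplo$annotation else NA_character_,
    chr16_cnv = chr16_cnv, call_rate = call_rate,
    concordant = cmp$concordant, retest = res$retest,
    rebiopsy = res$rebiopsy, final_genotype = res$final_genotype,
    cause = res$cause,
    euploid = if (!is.null(screen)) screen$euploid else NA,
    screen_status = if (!is.null(screen)) screen$status else "missing"
  ), class = "embryo_report")
}

#' Construct an embryo report directly from its fields
#'
#' Low-level constructor used for encoding published cases and for cohort
#' arithmetic on pre-resolved reports.
#'
#' @param embryo_id identifier
#' @param pcr_genotype,haplotype_genotype,final_genotype genotype fields
#' @param cause one of the cause categories
#' @param concordant logical
#' @param euploid logical (NA when screening failed)
#' @param call_rate call rate
#' @param screen_status "ok"/"failed"/"missing"
#' @return object of class `embryo_report`
#' @export
embryo_report <- function(embryo_id, pcr_genotype, haplotype_genotype,
                          final_genotype, cause, concordant,
                          euploid = NA, call_rate = NA_real_,
                          screen_status = "ok") {
  cause <- match.arg(cause, CAUSE_LEVELS)
  structure(list(embryo_id = embryo_id, pcr_genotype = pcr_genotype,
                 haplotype_genotype = haplotype_genotype,
                 haplotype_annotation = NA_character_, chr16_cnv = NULL,
                 call_rate = call_rate, concordant = concordant,
                 retest = NULL, rebiopsy = NULL,
                 final_genotype = final_genotype, cause = cause,
                 euploid = euploid, screen_status = screen_status),
            class = "embryo_report")
}

#' @export
print.embryo_report <- function(x, ...) {
  cat(sprintf("<embryo_report> %s: final %s (%s)%s\n", x$embryo_id,
              x$final_genotype, x$cause,
              if (isTRUE(x$euploid)) ", euploid" else ""))
  invisible(x)
}

# Percentage printed the way the cohort tables print them: one decimal for
# ordinary rates, two decimals for small rates (below 2%).
printed_pct <- function(num, den) {
  if (!den) return(NA_real_)
  p <- 100 * num / den
  round(p, if (p < 2) 2 else 1)
}

#' Cohort summary statistics
#'
#' Laboratory metrics over a set of finalized embryo reports: consistency
#' rate of the two methods, Gap-PCR allele-dropout rate, genotype
#' distributions, and the euploid rate over successfully screened embryos.
#' Percentages are rounded to one decimal (two below 1%).
#'
#' @param reports list of `embryo_report` objects
#' @return object of class `pgt_cohort_summary`
#' @export
cohort_summary <- function(reports) {
  if (!length(reports)) stop("at least one report is required")
  g <- function(f, what) vapply(reports, function(r) r[[what]], f)
  n <- length(reports)
  concord <- g(logical(1), "concordant")
  cause <- g(character(1), "cause")
  pcr <- g(character(1), "pcr_genotype")
  hap <- g(character(1), "haplotype_genotype")
  screened <- g(character(1), "screen_status") == "ok"
  eu <- g(logical(1), "euploid")
  n_ado <- sum(cause %in% c("ADO_MUTANT_ALLELE", "ADO_NORMAL_ALLELE"))
  dist <- function(x) table(factor(x, levels = c("NORMAL", "CARRIER",
                                                 "AFFECTED", "FAIL",
                                                 "UNDETERMINED")))
  structure(list(
    n_embryos = n,
    n_concordant = sum(concord),
    consistency_rate = printed_pct(sum(concord), n),
    n_ado = n_ado,
    ado_rate = printed_pct(n_ado, n),
    cause_counts = table(factor(cause, levels = CAUSE_LEVELS)),
    pcr_distribution = dist(pcr),
    haplotype_distribution = dist(hap),
    n_screened = sum(screened),
    n_euploid = sum(eu & screened, na.rm = TRUE),
    euploid_rate = printed_pct(sum(eu & screened, na.rm = TRUE),
                               sum(screened))
  ), class = "pgt_cohort_summary")
}

#' @export
print.pgt_cohort_summary <- function(x, ...) {
  cat("PGT cohort summary\n")
  cat(sprintf("  embryos: %d\n", x$n_embryos))
  cat(sprintf("  consistency: %.1f%% (%d/%d)\n", x$consistency_rate,
              x$n_concordant, x$n_embryos))
  cat(sprintf("  Gap-PCR ADO: %.2f%% (%d/%d)\n", x$ado_rate, x$n_ado,
              x$n_embryos))
  cat(sprintf("  euploid: %.1f%% (%d/%d screened)\n", x$euploid_rate,
              x$n_euploid, x$n_screened))
  invisible(x)
}

#' Rank embryos for transfer
#'
#' Excludes affected, unresolved/undetermined and non-euploid embryos.
#' Normal homozygous embryos rank before carriers; when the family has no
#' upstream-5' informative SNPs for one of the parents (elevated
#' misdiagnosis risk from undetected recombination), carriers are
#' additionally flagged and only-normal transfer is recommended. Ties break
#' by higher call rate, then embryo id.
#'
#' @param reports list of `embryo_report` objects
#' @param informative optional informative-SNP table for the family (used to
#'   detect missing upstream-5' coverage)
#' @return data.frame: `rank`, `embryo_id`, `final_genotype`, `call_rate`,
#'   `flag`; excluded embryos are absent
#' @export
transfer_priority <- function(reports, informative = NULL) {
  upstream_missing <- FALSE
  if (!is.null(informative)) {
    up <- informative[informative$flank == "upstream_5p", , drop = FALSE]
    upstream_missing <- !all(c("father", "mother") %in% up$informative_for)
  }
  df <- do.call(rbind, lapply(reports, function(r) data.frame(
    embryo_id = r$embryo_id, final_genotype = r$final_genotype,
    cause = r$cause, euploid = isTRUE(r$euploid),
    call_rate = if (is.null(r$call_rate) || is.na(r$call_rate)) 0
    else r$call_rate,
    stringsAsFactors = FALSE)))
  class_of <- function(fg) {
    if (identical(fg, SEA_GENOTYPES[["NORMAL"]])) "NORMAL"
    else if (identical(fg, SEA_GENOTYPES[["CARRIER"]])) "CARRIER"
    else if (identical(fg, SEA_GENOTYPES[["AFFECTED"]])) "AFFECTED"
    else "OTHER"
  }
  df$class <- vapply(df$final_genotype, class_of, character(1))
  keep <- df$euploid & df$class %in% c("NORMAL", "CARRIER") &
    df$cause != "UNRESOLVED"
  df <- df[keep, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(rank = integer(), embryo_id = character(),
                      final_genotype = character(), call_rate = numeric(),
                      flag = character(), stringsAsFactors = FALSE))
  df$flag <- ifelse(df$class == "CARRIER" & upstream_missing,
                    "elevated misdiagnosis risk", "")
  o <- order(df$class != "NORMAL", -df$call_rate, df$embryo_id)
  df <- df[o, , drop = FALSE]
  data.frame(rank = seq_len(nrow(df)), embryo_id = df$embryo_id,
             final_genotype = df$final_genotype, call_rate = df$call_rate,
             flag = df$flag, stringsAsFactors = FALSE, row.names = NULL)
}
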