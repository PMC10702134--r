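# Chromosome-level copy-number calling from BAF/LRR, with parental origin and
# meiosis I/II staging of trisomies via BPH/SPH allele-dosage patterns at
# parent-informative SNPs.

#' Copy-number calling options
#'
#' Ideal-scale defaults: the simulator renders LRR as log2(CN/2), so a
#' trisomy sits at +0.585 and a monosomy at -1.0; the gain/loss thresholds
#' bisect those bands conservatively. BAF band membership uses a fixed
#' tolerance around the ideal bands {0, 1/3, 1/2, 2/3, 1}.
#'
#' @param lrr_gain median-LRR threshold above which a gain is considered
#' @param lrr_loss median-LRR threshold below which a loss is considered
#' @param baf_tol band tolerance around ideal BAF bands
#' @param min_snps_per_chrom minimum usable SNPs to call a chromosome
#' @param third_band_min minimum fraction of het-context SNPs in the 1/3 or
#'   2/3 bands required for a trisomy call
#' @param mid_band_max maximum fraction of het-context SNPs in the 1/2 band
#'   compatible with CN 1 or 3
#' @param max_stage_snps of the usable staging SNPs, how many nearest the
#'   centromere are voted on (crossovers erode the BPH signal further out)
#' @return list of options
#' @export
cnv_options <- function(lrr_gain = 0.3, lrr_loss = -0.5, baf_tol = 0.08,
                        min_snps_per_chrom = 20, third_band_min = 0.15,
                        mid_band_max = 0.10, max_stage_snps = 10) {
  list(lrr_gain = lrr_gain, lrr_loss = lrr_loss, baf_tol = baf_tol,
       min_snps_per_chrom = min_snps_per_chrom,
       third_band_min = third_band_min, mid_band_max = mid_band_max,
       max_stage_snps = max_stage_snps)
}

# Records of one chromosome for a sample.
chrom_records <- function(sample, chromosome) {
  r <- sample$records
  r[r$chromosome == chromosome, , drop = FALSE]
}

# Fraction of values within tol of each ideal band.
baf_band_profile <- function(baf, tol) {
  baf <- baf[!is.na(baf)]
  bands <- c(`0` = 0, `1/3` = 1 / 3, `1/2` = 1 / 2, `2/3` = 2 / 3, `1` = 1)
  if (!length(baf)) return(setNames(rep(NA_real_, 5), names(bands)))
  vapply(bands, function(b) mean(abs(baf - b) <= tol), numeric(1))
}

#' Call the copy number of one chromosome
#'
#' Trisomy: median LRR above the gain threshold, heterozygous-context BAF
#' mass concentrated at 1/3 and 2/3 with an empty mid (1/2) band. Monosomy:
#' median LRR below the loss threshold and an empty mid band. Anything else
#' is two copies (intermediate patterns get a "non-integer pattern" note
#' rather than a mosaic call). Heterozygous context = SNPs where at least
#' one parent is AB.
#'
#' @param embryo embryo [sample_array()]
#' @param father,mother parental [sample_array()]s
#' @param chromosome chromosome label
#' @param options from [cnv_options()]
#' @return object of class `cnv_call`: `chromosome`, `copy_number` (1/2/3 or
#'   NA), `origin_parent`, `stage`, `note`, `evidence`
#' @export
call_chromosome_cnv <- function(embryo, father, mother, chromosome,
                                options = cnv_options()) {
  er <- chrom_records(embryo, chromosome)
  usable <- er$gtype != "NC" | !is.na(er$baf) | !is.na(er$lrr)
  if (sum(usable) < options$min_snps_per_chrom)
    return(new_cnv_call(chromosome, NA_integer_, note = "too few SNPs"))
  med_lrr <- median(er$lrr, na.rm = TRUE)
  f_gt <- gtype_at(father, er$snp_id); m_gt <- gtype_at(mother, er$snp_id)
  het_ctx <- (f_gt == "AB" | m_gt == "AB") & !is.na(er$baf)
  prof <- baf_band_profile(er$baf[het_ctx], options$baf_tol)
  mid <- prof[["1/2"]]; third <- prof[["1/3"]] + prof[["2/3"]]
  cn <- 2L; note <- NA_character_
  if (!is.na(med_lrr) && !is.na(mid)) {
    if (med_lrr > options$lrr_gain && mid <= options$mid_band_max &&
        third >= options$third_band_min) cn <- 3L
    else if (med_lrr < options$lrr_loss && mid <= options$mid_band_max) cn <- 1L
    else if (med_lrr > options$lrr_gain || med_lrr < options$lrr_loss)
      note <- "non-integer pattern"
  }
  new_cnv_call(chromosome, cn, note = note,
               evidence = list(median_lrr = med_lrr, baf_bands = prof,
                               n_snps = sum(usable),
                               n_het_context = sum(het_ctx)))
}

new_cnv_call <- function(chromosome, copy_number, origin_parent = NA_character_,
                         stage = NA_character_, note = NA_character_,
                         evidence = NULL, origin_score = NA_real_,
                         retained_parent = NA_character_,
                         retained_risk = NA) {
  structure(list(chromosome = chromosome, copy_number = copy_number,
                 origin_parent = origin_parent, stage = stage, note = note,
                 evidence = evidence, origin_score = origin_score,
                 retained_parent = retained_parent,
                 retained_risk = retained_risk),
            class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat("<cnv_call>", format_iscn_like(x))
  if (!is.na(x$stage)) cat(" [", x$stage, "]", sep = "")
  if (!is.na(x$note)) cat(" (", x$note, ")", sep = "")
  cat("\n")
  invisible(x)
}

# Band membership index with tolerance; NA when off-band.
nearest_band <- function(baf, tol) {
  bands <- c(0, 1 / 3, 1 / 2, 2 / 3, 1)
  idx <- vapply(baf, function(b) {
    if (is.na(b)) return(NA_integer_)
    d <- abs(bands - b)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, integer(1))
  bands[idx]
}

# Expected BAF band probability tables at SNPs where the candidate origin
# parent is AB and the other parent homozygous (hom allele X), and at SNPs
# where the origin candidate is homozygous (Y) and the other parent AB.
# Bands keyed by numeric value; eps-smoothed into a likelihood.
origin_band_probs <- function(origin_is_het, hom_allele, stage) {
  if (origin_is_het) {
    if (stage == "MI") {
      # origin contributes A and B; hom parent one X
      if (hom_allele == "A") c(`0.333` = 1) else c(`0.667` = 1)
    } else {
      # origin contributes AA or BB, equal probability
      if (hom_allele == "A") c(`0.000` = 0.5, `0.667` = 0.5)
      else c(`0.333` = 0.5, `1.000` = 0.5)
    }
  } else {
    # origin contributes YY; the het parent transmits A or B equally
    if (hom_allele == "A") c(`0.000` = 0.5, `0.333` = 0.5)
    else c(`0.667` = 0.5, `1.000` = 0.5)
  }
}

band_loglik <- function(obs_bands, probs, eps = 0.02) {
  all_bands <- c(0, 1 / 3, 1 / 2, 2 / 3, 1)
  p <- setNames(rep(eps, 5), sprintf("%.3f", all_bands))
  for (nm in names(probs)) p[[nm]] <- p[[nm]] + probs[[nm]]
  p <- p / sum(p)
  sum(log(p[sprintf("%.3f", obs_bands)]))
}

#' Parental origin of a trisomy
#'
#' At SNPs where exactly one parent is heterozygous, the BAF band pattern of
#' a trisomic chromosome depends on which parent contributed the double dose.
#' Both origin hypotheses are scored by a band likelihood (marginalised over
#' MI/MII); the winner and a posterior-style score are returned.
#'
#' @param embryo embryo [sample_array()]
#' @param father,mother parental [sample_array()]s
#' @param chromosome chromosome with an established copy number of 3
#' @param options from [cnv_options()]
#' @return list with `origin` ("father"/"mother"/"unknown") and `score`
#'   (posterior probability of the winning hypothesis)
#' @export
trisomy_parental_origin <- function(embryo, father, mother, chromosome,
                                    options = cnv_options()) {
  er <- chrom_records(embryo, chromosome)
  f_gt <- gtype_at(father, er$snp_id); m_gt <- gtype_at(mother, er$snp_id)
  one_het <- (f_gt == "AB") != (m_gt == "AB")
  informative <- one_het & (f_gt %in% c("AA", "AB", "BB")) &
    (m_gt %in% c("AA", "AB", "BB")) & !is.na(er$baf)
  if (sum(informative, na.rm = TRUE) < 3)
    return(list(origin = "unknown", score = NA_real_))
  i <- which(informative)
  band <- nearest_band(er$baf[i], options$baf_tol)
  keep <- !is.na(band)
  i <- i[keep]; band <- band[keep]
  if (length(i) < 3) return(list(origin = "unknown", score = NA_real_))
  het_parent <- ifelse(f_gt[i] == "AB", "father", "mother")
  hom_gt <- ifelse(f_gt[i] == "AB", m_gt[i], f_gt[i])
  hom_allele <- substr(hom_gt, 1, 1)
  ll <- function(origin, stage) {
    sum(vapply(seq_along(i), function(k) {
      band_loglik(band[k],
                  origin_band_probs(het_parent[k] == origin, hom_allele[k],
                                    stage))
    }, numeric(1)))
  }
  lf <- max(ll("father", "MI"), ll("father", "MII"))
  lm <- max(ll("mother", "MI"), ll("mother", "MII"))
  post <- 1 / (1 + exp(min(lf, lm) - max(lf, lm)))
  if (abs(lf - lm) < log(10))  # less than 10:1 evidence
    return(list(origin = "unknown", score = post))
  list(origin = if (lf > lm) "father" else "mother", score = post)
}

#' Meiotic stage (MI/MII) of a trisomy
#'
#' Within the pericentromeric window, at SNPs where the origin parent is AB
#' and the other parent homozygous, a BAF band containing both origin-parent
#' alleles (single + double dose, band 1/3 or 2/3 depending on the shared
#' allele) indicates both parental homologs (BPH), hence a meiosis-I error;
#' bands reflecting a duplicated single homolog (SPH) indicate meiosis II.
#' BPH only extends from the centromere to the first crossover on either
#' transmitted homolog, so only the `max_stage_snps` usable SNPs closest to
#' the centromere are voted on.
#'
#' @param embryo embryo [sample_array()]
#' @param father,mother parental [sample_array()]s
#' @param chromosome trisomic chromosome
#' @param origin_parent "father" or "mother"
#' @param options from [cnv_options()]
#' @return "MI", "MII" or "unknown"
#' @export
meiotic_stage <- function(embryo, father, mother, chromosome, origin_parent,
                          options = cnv_options()) {
  er <- chrom_records(embryo, chromosome)
  f_gt <- gtype_at(father, er$snp_id); m_gt <- gtype_at(mother, er$snp_id)
  og <- if (origin_parent == "father") f_gt else m_gt
  other <- if (origin_parent == "father") m_gt else f_gt
  sel <- og == "AB" & other %in% c("AA", "BB") & !is.na(er$baf)
  sel[is.na(sel)] <- FALSE
  if (!sum(sel)) return("unknown")
  # keep only the usable SNPs nearest the centromere: further out the BPH
  # signal is increasingly disrupted by crossovers
  cen <- CHROM_CENTROMERE[[chromosome]]
  keep <- which(sel)[order(abs(er$position[sel] - cen))]
  keep <- keep[seq_len(min(length(keep), options$max_stage_snps))]
  sel <- seq_len(nrow(er)) %in% keep
  band <- nearest_band(er$baf[sel], options$baf_tol)
  hom_allele <- substr(other[sel], 1, 1)
  bph_band <- ifelse(hom_allele == "A", 1 / 3, 2 / 3)
  sph_lo <- ifelse(hom_allele == "A", 0, 1 / 3)
  sph_hi <- ifelse(hom_allele == "A", 2 / 3, 1)
  ok <- !is.na(band)
  n_mi <- sum(ok & abs(band - bph_band) < 1e-9)
  n_mii <- sum(ok & (abs(band - sph_lo) < 1e-9 | abs(band - sph_hi) < 1e-9))
  if (n_mi + n_mii < 3) return("unknown")
  frac_mi <- n_mi / (n_mi + n_mii)
  if (frac_mi >= 0.7) "MI" else if (frac_mi <= 0.3) "MII" else "unknown"
}

#' Which parent's homolog a monosomic chromosome retains
#'
#' At SNPs informative for a parent, observing that parent's private allele
#' in the hemizygous embryo proves its homolog is present; the lost parent
#' shows (almost) no private-allele evidence.
#'
#' @param embryo embryo [sample_array()]
#' @param father,mother parental [sample_array()]s
#' @param chromosome chromosome with an established copy number of 1
#' @param min_frac private-allele fraction required for the retained parent
#' @param max_frac maximum private-allele fraction tolerated for the lost one
#' @return list with `retained`, `lost` ("father"/"mother"/"unknown") and
#'   the two evidence fractions
#' @export
monosomy_retained_parent <- function(embryo, father, mother, chromosome,
                                     min_frac = 0.2, max_frac = 0.05) {
  er <- chrom_records(embryo, chromosome)
  f_gt <- gtype_at(father, er$snp_id); m_gt <- gtype_at(mother, er$snp_id)
  e_gt <- er$gtype
  private_frac <- function(het, hom) {
    sel <- which(het == "AB" & hom %in% c("AA", "BB") & e_gt != "NC")
    if (!length(sel)) return(NA_real_)
    hom_allele <- substr(hom[sel], 1, 1)
    private <- ifelse(hom_allele == "A", "BB", "AA")
    mean(e_gt[sel] == private)
  }
  ev_f <- private_frac(f_gt, m_gt)  # father's private allele seen
  ev_m <- private_frac(m_gt, f_gt)
  if (is.na(ev_f) || is.na(ev_m))
    return(list(retained = "unknown", lost = "unknown",
                father_evidence = ev_f, mother_evidence = ev_m))
  res <- if (ev_f >= min_frac && ev_m <= max_frac)
    c("father", "mother")
  else if (ev_m >= min_frac && ev_f <= max_frac)
    c("mother", "father")
  else c("unknown", "unknown")
  list(retained = res[1], lost = res[2],
       father_evidence = ev_f, mother_evidence = ev_m)
}

#' ISCN-like display string for a chromosome CNV call
#'
#' Examples: `"arr(16)×3 mat"` for a maternal-origin trisomy 16,
#' `"arr(16)×1 mat"` for a monosomy whose maternal homolog was lost (the
#' parent tag marks the affected homolog: extra for a gain, lost for a
#' loss), `"arr(16)×2"` for a disomic chromosome.
#'
#' @param call a `cnv_call`
#' @return character scalar
#' @export
format_iscn_like <- function(call) {
  if (is.na(call$copy_number)) return(sprintf("arr(%s)×?", call$chromosome))
  tag <- if (call$copy_number == 3L && !is.na(call$origin_parent))
    c(father = " pat", mother = " mat")[[call$origin_parent]]
  else if (call$copy_number == 1L && !is.na(call$origin_parent))
    c(father = " pat", mother = " mat")[[call$origin_parent]]
  else ""
  sprintf("arr(%s)×%d%s", call$chromosome, call$copy_number, tag)
}

#' Genome-wide aneuploidy screen
#'
#' Calls every autosome's copy number; trisomies are annotated with parental
#' origin and meiotic stage, monosomies with the lost/retained parent. The
#' embryo is euploid when every autosome is called at two copies. Sex
#' chromosomes present on the panel are reported but excluded from the
#' euploid verdict. A chromosome that cannot be analysed marks the whole
#' screen as failed.
#'
#' @param embryo embryo [sample_array()]
#' @param father,mother parental [sample_array()]s
#' @param options from [cnv_options()]
#' @param phase optional list of `parental_phase` objects (`father`,
#'   `mother`); when given, a monosomy of the locus chromosome is annotated
#'   with the retained haplotype's risk status
#' @param config a [family_config()] (locus chromosome for risk annotation)
#' @param informative informative-SNP table (needed with `phase`)
#' @return object of class `genome_screen`: `calls` (named list of
#'   `cnv_call`), `euploid`, `status` ("ok"/"failed")
#' @export
genome_screen <- function(embryo, father, mother, options = cnv_options(),
                          phase = NULL, config = family_config(),
                          informative = NULL) {
  chroms <- intersect(CHROMOSOMES, unique(embryo$records$chromosome))
  calls <- list()
  failed <- FALSE
  for (c_ in chroms) {
    call <- call_chromosome_cnv(embryo, father, mother, c_, options)
    if (is.na(call$copy_number)) failed <- failed || c_ %in% AUTOSOMES
    else if (call$copy_number == 3L) {
      or <- trisomy_parental_origin(embryo, father, mother, c_, options)
      call$origin_parent <- if (or$origin == "unknown") NA_character_ else or$origin
      call$origin_score <- or$score
      if (!is.na(call$origin_parent))
        call$stage <- meiotic_stage(embryo, father, mother, c_,
                                    call$origin_parent, options)
    } else if (call$copy_number == 1L) {
      mr <- monosomy_retained_parent(embryo, father, mother, c_)
      call$retained_parent <- if (mr$retained == "unknown") NA_character_ else mr$retained
      call$origin_parent <- if (mr$lost == "unknown") NA_character_ else mr$lost
      if (c_ == config$locus$chrom && !is.na(call$retained_parent) &&
          !is.null(phase) && !is.null(informative)) {
        hc <- call_embryo_haplotype(embryo, phase[[call$retained_parent]],
                                    informative, config, hemizygous = TRUE)
        call$retained_risk <- switch(hc$locus_side_verdict,
                                     RISK = TRUE, NONRISK = FALSE, NA)
      }
    }
    calls[[c_]] <- call
  }
  auto <- calls[intersect(names(calls), AUTOSOMES)]
  euploid <- !failed && all(vapply(auto, function(x)
    !is.na(x$copy_number) && x$copy_number == 2L, logical(1)))
  structure(list(calls = calls, euploid = euploid,
                 status = if (failed) "failed" else "ok"),
            class = "genome_screen")
}

#' @export
print.genome_screen <- function(x, ...) {
  ab <- Filter(function(c_) is.na(c_$copy_number) || c_$copy_number != 2L,
               x$calls)
  cat(sprintf("<genome_screen> %s, %s\n",
              if (x$euploid) "euploid" else "aneuploid/failed", x$status))
  for (c_ in ab) cat("  ", format_iscn_like(c_), "\n")
  invisible(x)
}
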