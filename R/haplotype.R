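# Informative-SNP selection, parental phasing from reference embryos (or a
# carrier-embryo pair), and per-embryo haplotype calling with recombination
# detection.

#' Find informative SNPs in the flanked locus region
#'
#' An informative SNP has a heterozygous (AB) call in exactly one parent and
#' a homozygous (AA/BB) call in the other; a no-call in either parent
#' excludes the SNP. Each SNP is tagged with the flank it falls in
#' (upstream 5' / in-gene / downstream 3').
#'
#' @param father,mother parental [sample_array()]s
#' @param config a [family_config()]; defines the locus, flank and chromosome
#' @param region optional `region_partition` (default: from `config`)
#' @return data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `informative_for`, `het_parent_gt`, `hom_parent_allele`, `flank`
#' @export
find_informative_snps <- function(father, mother, config = family_config(),
                                  region = NULL) {
  part <- region %||% partition_region(config)
  fr <- father$records; mr <- mother$records
  if (!identical(fr$snp_id, mr$snp_id))
    stop("parents are not genotyped on the same panel")
  on_chrom <- fr$chromosome == part$chrom
  fl <- rep(NA_character_, nrow(fr))
  fl[on_chrom] <- flank_of(fr$position[on_chrom], part)
  in_region <- !is.na(fl)
  f_het <- fr$gtype == "AB"; m_het <- mr$gtype == "AB"
  f_hom <- fr$gtype %in% c("AA", "BB"); m_hom <- mr$gtype %in% c("AA", "BB")
  pat <- in_region & f_het & m_hom
  mat <- in_region & m_het & f_hom
  idx <- which(pat | mat)
  if (!length(idx))
    return(data.frame(snp_id = character(), chromosome = character(),
                      position = integer(), informative_for = character(),
                      het_parent_gt = character(),
                      hom_parent_allele = character(), flank = character(),
                      stringsAsFactors = FALSE))
  hom_gt <- ifelse(pat[idx], mr$gtype[idx], fr$gtype[idx])
  data.frame(snp_id = fr$snp_id[idx], chromosome = fr$chromosome[idx],
             position = fr$position[idx],
             informative_for = ifelse(pat[idx], "father", "mother"),
             het_parent_gt = "AB",
             hom_parent_allele = substr(hom_gt, 1, 1),
             flank = fl[idx], stringsAsFactors = FALSE)
}

#' Summarise informative-SNP counts across families
#'
#' Produces the per-parent, per-flank count table with arithmetic means and
#' sample standard deviations (n-1 denominator; NA for a single family).
#'
#' @param families either a list of informative-SNP data.frames (as from
#'   [find_informative_snps()]) or a long data.frame with columns `family`,
#'   `parent`, `flank`, `n`
#' @return list with `counts` (long data.frame, one row per family x parent x
#'   flank) and `stats` (per parent x flank: `n_families`, `mean`, `sd`)
#' @export
informative_snp_stats <- function(families) {
  flanks <- c("upstream_5p", "in_gene", "downstream_3p")
  parents <- c("mother", "father")
  if (is.data.frame(families)) {
    counts <- families
    need <- c("family", "parent", "flank", "n")
    if (length(setdiff(need, names(counts))))
      stop("counts data.frame needs columns family, parent, flank, n")
  } else {
    if (!length(families)) stop("at least one family is required")
    if (is.null(names(families)))
      names(families) <- sprintf("family%02d", seq_along(families))
    counts <- do.call(rbind, lapply(names(families), function(fam) {
      inf <- families[[fam]]
      grid <- expand.grid(parent = parents, flank = flanks,
                          stringsAsFactors = FALSE)
      grid$family <- fam
      grid$n <- mapply(function(p, fl)
        sum(inf$informative_for == p & inf$flank == fl),
        grid$parent, grid$flank)
      grid[, c("family", "parent", "flank", "n")]
    }))
  }
  grid <- expand.grid(parent = parents, flank = flanks,
                      stringsAsFactors = FALSE)
  stats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- counts$n[counts$parent == grid$parent[i] &
                    counts$flank == grid$flank[i]]
    data.frame(parent = grid$parent[i], flank = grid$flank[i],
               n_families = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2) sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- rownames(stats) <- NULL
  list(counts = counts, stats = stats)
}

#' Phase parental risk haplotypes from a homozygous reference embryo
#'
#' A sibling embryo with a homozygous Gap-PCR genotype (affected --/-- or
#' normal aa/aa) is used as the phasing reference, assumed recombination-free.
#' At each SNP informative for parent P, Mendelian subtraction of the other
#' parent's homozygous allele from the reference genotype yields P's
#' transmitted allele; an affected reference puts that allele on P's risk
#' haplotype, a normal reference on the non-risk haplotype (risk = the other
#' allele of the AB pair). Reference no-calls are skipped; a Mendelian
#' inconsistency rate above `mendel_tol` aborts with a
#' contamination/aneuploidy warning.
#'
#' @param reference reference embryo [sample_array()]
#' @param reference_pcr its Gap-PCR call: "AFFECTED" or "NORMAL"
#' @param informative data.frame from [find_informative_snps()]
#' @param mendel_tol tolerated fraction of Mendelian-inconsistent SNPs
#' @return list of two `parental_phase` objects (`father`, `mother`), each
#'   with `risk_allele` (named A/B vector over that parent's informative
#'   SNPs), `source`, `reference_kind`, `n_used`, `n_conflict`
#' @export
phase_from_reference <- function(reference, reference_pcr, informative,
                                 mendel_tol = 0.10) {
  reference_pcr <- as.character(reference_pcr)
  if (!reference_pcr %in% c("AFFECTED", "NORMAL"))
    stop("reference embryo must have a homozygous Gap-PCR genotype")
  gt <- gtype_at(reference, informative$snp_id)
  trans <- transmitted_allele(gt, informative$hom_parent_allele)
  usable <- !is.na(trans)
  n_called <- sum(gt != "NC", na.rm = TRUE)
  n_conf <- sum(gt != "NC" & is.na(trans), na.rm = TRUE)
  if (n_called > 0 && n_conf / n_called > mendel_tol)
    stop(sprintf(paste("reference embryo is Mendelian-inconsistent at %.1f%%",
                       "of informative SNPs: suspect contamination or",
                       "aneuploidy"), 100 * n_conf / n_called))
  mk <- function(parent) {
    sel <- informative$informative_for == parent & usable
    trans_p <- trans[sel]
    risk <- if (reference_pcr == "AFFECTED") trans_p
    else ifelse(trans_p == "A", "B", "A")
    structure(list(parent = parent,
                   risk_allele = setNames(risk, informative$snp_id[sel]),
                   source = reference$sample_id,
                   reference_kind = tolower(reference_pcr),
                   n_used = sum(sel), n_conflict = n_conf),
              class = "parental_phase")
  }
  list(father = mk("father"), mother = mk("mother"))
}

#' @export
print.parental_phase <- function(x, ...) {
  cat(sprintf("<parental_phase> %s: %d SNPs phased (%s reference: %s)\n",
              x$parent, length(x$risk_allele), x$reference_kind, x$source))
  invisible(x)
}

# The het parent's transmitted allele by Mendelian subtraction of the hom
# parent's allele X from the embryo genotype. NA = unusable (NC) or
# Mendelian-inconsistent.
transmitted_allele <- function(gt, hom_allele) {
  gt[is.na(gt)] <- "NC"
  out <- rep(NA_character_, length(gt))
  other <- ifelse(hom_allele == "A", "B", "A")
  out[gt == "AB"] <- other[gt == "AB"]
  hom_same <- gt == paste0(hom_allele, hom_allele)
  out[hom_same] <- hom_allele[hom_same]
  # embryo homozygous for the non-shared allele contradicts the hom parent
  out
}

#' Phase parental haplotypes from a pair of carrier embryos
#'
#' Fallback when no homozygous reference embryo exists. The two embryos are
#' both Gap-PCR carriers; each carries one parental risk haplotype and the
#' other parent's non-risk haplotype. Flanking informative SNPs alone leave
#' a two-fold ambiguity (the true assignment and its full flip are equally
#' consistent), so when the parent arrays and family configuration are
#' supplied the deletion interval itself is used to break it: inside the
#' deletion each carrier parent is hemizygous (the array shows only the
#' retained non-risk allele) and a carrier embryo shows only the retained
#' parent's transmitted allele, so in-gene SNPs where the two parents'
#' retained alleles differ reveal which parent transmitted the deletion.
#' The assignments of which parent's risk each embryo carries (restricted by
#' any deletion-origin evidence) are then checked for cross-embryo phase
#' consistency (mismatch fraction <= `mismatch_tol`). A unique survivor
#' yields the phase; zero or several survivors yield NOCALL.
#'
#' @param embryo1,embryo2 carrier-embryo [sample_array()]s
#' @param informative data.frame from [find_informative_snps()]
#' @param config a [family_config()] (deletion interval); optional, but
#'   required together with `father`/`mother` for deletion-origin evidence
#' @param father,mother parental [sample_array()]s; optional
#' @param min_informative minimum usable SNPs per parent per embryo
#' @param mismatch_tol tolerated disagreement fraction between the two
#'   embryos' implied phases
#' @param min_call_rate QC gate on each embryo's call rate
#' @return on success a list as from [phase_from_reference()]; otherwise a
#'   list with `verdict = "NOCALL"` and `reason`
#' @export
phase_from_carrier_pair <- function(embryo1, embryo2, informative,
                                    config = NULL,
                                    father = NULL, mother = NULL,
                                    min_informative = 3,
                                    mismatch_tol = 0.05,
                                    min_call_rate = 0.90) {
  for (e in list(embryo1, embryo2))
    if (compute_call_rate(e) < min_call_rate)
      return(list(verdict = "NOCALL",
                  reason = sprintf("embryo %s call rate below QC",
                                   e$sample_id)))
  origin1 <- origin2 <- NA_character_
  if (!is.null(config) && !is.null(father) && !is.null(mother)) {
    origin1 <- deletion_origin(embryo1, father, mother, config)
    origin2 <- deletion_origin(embryo2, father, mother, config)
  }
  implied <- function(embryo, risk_parent) {
    # risk_parent carries risk in this embryo; the other parent contributes
    # its non-risk haplotype
    lapply(c("father", "mother"), function(p) {
      sel <- informative$informative_for == p
      gt <- gtype_at(embryo, informative$snp_id[sel])
      trans <- transmitted_allele(gt, informative$hom_parent_allele[sel])
      risk <- if (p == risk_parent) trans
      else ifelse(trans == "A", "B", "A")
      setNames(risk, informative$snp_id[sel])
    })
  }
  assignments <- expand.grid(
    e1 = if (is.na(origin1)) c("father", "mother") else origin1,
    e2 = if (is.na(origin2)) c("father", "mother") else origin2,
    stringsAsFactors = FALSE)
  survivors <- list()
  for (k in seq_len(nrow(assignments))) {
    ph1 <- implied(embryo1, assignments$e1[k])
    ph2 <- implied(embryo2, assignments$e2[k])
    stats <- mapply(function(a, b) {
      both <- !is.na(a) & !is.na(b)
      c(n = sum(both), mismatch = sum(a[both] != b[both]))
    }, ph1, ph2)
    n_shared <- sum(stats["n", ])
    if (any(stats["n", ] < min_informative)) next
    if (sum(stats["mismatch", ]) / n_shared > mismatch_tol) next
    merged <- lapply(seq_along(ph1), function(j) {
      a <- ph1[[j]]; b <- ph2[[j]]
      a[is.na(a)] <- b[is.na(a)]
      a[!is.na(a)]
    })
    survivors[[length(survivors) + 1L]] <- list(assign = assignments[k, ],
                                                phases = merged)
  }
  if (length(survivors) == 0L)
    return(list(verdict = "NOCALL", reason = "no consistent assignment"))
  if (length(survivors) > 1L)
    return(list(verdict = "NOCALL",
                reason = "ambiguous: several consistent assignments"))
  ph <- survivors[[1]]$phases
  mk <- function(j, parent) structure(
    list(parent = parent, risk_allele = ph[[j]],
         source = paste(embryo1$sample_id, embryo2$sample_id, sep = "+"),
         reference_kind = "carrier_pair",
         n_used = length(ph[[j]]), n_conflict = 0L),
    class = "parental_phase")
  list(father = mk(1, "father"), mother = mk(2, "mother"))
}

# Which parent transmitted the deletion to a carrier embryo, read off the
# deletion interval itself: both carrier parents are hemizygous there (the
# array shows the retained non-risk allele as a homozygous call) and the
# embryo shows only the retained parent's transmitted allele. SNPs where the
# two parents' retained alleles differ vote for the matching (retained)
# parent; the deletion came from the other one. Returns "father", "mother"
# or NA when the evidence is absent or indecisive.
deletion_origin <- function(embryo, father, mother, config,
                            min_votes = 2L, majority = 0.8) {
  sel <- father$records$chromosome == config$locus$chrom &
    father$records$position >= config$deletion$start &
    father$records$position <= config$deletion$end
  ids <- father$records$snp_id[sel]
  if (!length(ids)) return(NA_character_)
  fg <- gtype_at(father, ids); mg <- gtype_at(mother, ids)
  eg <- gtype_at(embryo, ids)
  hom <- c(AA = "A", BB = "B")
  fa <- hom[fg]; ma <- hom[mg]; ea <- hom[eg]
  use <- !is.na(fa) & !is.na(ma) & !is.na(ea) & fa != ma
  if (!any(use)) return(NA_character_)
  # embryo matching the father's retained allele means the father's copy was
  # retained, i.e. the deletion is maternal
  votes_mother <- sum(ea[use] == fa[use])
  votes_father <- sum(ea[use] == ma[use])
  n <- votes_mother + votes_father
  if (n < min_votes) return(NA_character_)
  if (votes_father / n >= majority) return("father")
  if (votes_mother / n >= majority) return("mother")
  NA_character_
}

#' Call which parental haplotype an embryo inherited
#'
#' At each usable informative SNP for the phased parent, the embryo allele
#' attributable to that parent (Mendelian subtraction of the other parent's
#' homozygous allele; or the observed single allele in hemizygous mode) is
#' compared with the phased risk allele. Runs of agreeing SNPs along the
#' chromosome of at least `min_block` SNPs form anchor blocks; anchor blocks
#' of both kinds indicate recombination (the verdict is RECOMBINANT and the
#' breakpoint interval is the gap between the adjacent opposing anchors).
#' Otherwise a majority vote over all usable SNPs gives RISK or NONRISK;
#' insufficient SNPs or an indecisive vote give NOCALL.
#'
#' @param embryo embryo [sample_array()]
#' @param phase a `parental_phase`
#' @param informative data.frame from [find_informative_snps()]
#' @param config a [family_config()] (locus interval, for the
#'   recombination-across-locus guard)
#' @param min_informative minimum usable SNPs for a verdict
#' @param majority vote fraction required for RISK/NONRISK
#' @param min_block minimum consecutive SNPs forming a recombination anchor
#' @param hemizygous TRUE when the embryo has a single copy of the
#'   chromosome (monosomy): attribution skips Mendelian subtraction
#' @return object of class `haplotype_call`: `verdict` (RISK / NONRISK /
#'   RECOMBINANT / NOCALL), `support`, `conflict`, `skipped`, `per_flank`,
#'   `breakpoint_interval`, `locus_side_verdict`
#' @export
call_embryo_haplotype <- function(embryo, phase, informative,
                                  config = family_config(),
                                  min_informative = 3, majority = 0.8,
                                  min_block = 3, hemizygous = FALSE) {
  if (!length(phase$risk_allele)) {
    return(new_haplotype_call(embryo$sample_id, phase$parent, "NOCALL",
                              0L, 0L, 0L, NULL, NULL, "NOCALL"))
  }
  inf <- informative[informative$informative_for == phase$parent &
                       informative$snp_id %in% names(phase$risk_allele), ,
                     drop = FALSE]
  inf <- inf[order(inf$position), , drop = FALSE]
  gt <- gtype_at(embryo, inf$snp_id)
  gt[is.na(gt)] <- "NC"
  attributed <- if (hemizygous) {
    out <- rep(NA_character_, length(gt))
    out[gt %in% c("AA", "BB")] <- substr(gt[gt %in% c("AA", "BB")], 1, 1)
    out
  } else transmitted_allele(gt, inf$hom_parent_allele)
  risk <- unname(phase$risk_allele[inf$snp_id])
  usable <- !is.na(attributed)
  mendel_conflict <- gt != "NC" & !usable  # counted as conflicting evidence
  match_v <- attributed == risk
  support <- sum(match_v[usable])
  conflict <- sum(!match_v[usable]) + sum(mendel_conflict, na.rm = TRUE)
  skipped <- nrow(inf) - sum(usable) - sum(mendel_conflict, na.rm = TRUE)
  per_flank <- do.call(rbind, lapply(
    c("upstream_5p", "in_gene", "downstream_3p"), function(fl) {
      s <- usable & inf$flank == fl
      data.frame(flank = fl, support = sum(match_v[s]),
                 conflict = sum(!match_v[s]), stringsAsFactors = FALSE)
    }))
  n_evidence <- support + conflict
  if (n_evidence < min_informative)
    return(new_haplotype_call(embryo$sample_id, phase$parent, "NOCALL",
                              support, conflict, skipped, per_flank, NULL,
                              "NOCALL"))
  # recombination scan: anchor runs of >= min_block consecutive same-state
  pos <- inf$position[usable]; mv <- match_v[usable]
  r <- rle(mv)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  anchors <- which(r$lengths >= min_block)
  verdict <- NULL; bp <- NULL; locus_side <- NULL
  if (length(anchors) >= 2 && length(unique(r$values[anchors])) == 2) {
    verdict <- "RECOMBINANT"
    # breakpoint between the first two opposing anchors
    a1 <- anchors[1]
    a2 <- anchors[which(r$values[anchors] != r$values[a1])[1]]
    bp <- c(pos[ends[a1]], pos[starts[a2]])
    bp <- sort(bp)
    locus <- c(config$locus$start, config$locus$end)
    if (bp[1] <= locus[2] && bp[2] >= locus[1]) {
      locus_side <- "UNDETERMINED"
    } else {
      # risk status at the locus = state of the anchor on the locus side
      locus_mid <- mean(locus)
      near_anchor <- if (abs(pos[ends[a1]] - locus_mid) <
                           abs(pos[starts[a2]] - locus_mid)) a1 else a2
      locus_side <- if (r$values[near_anchor]) "RISK" else "NONRISK"
    }
  } else {
    verdict <- if (support / n_evidence >= majority) "RISK"
    else if (conflict / n_evidence >= majority) "NONRISK"
    else "NOCALL"
    locus_side <- verdict
  }
  new_haplotype_call(embryo$sample_id, phase$parent, verdict, support,
                     conflict, skipped, per_flank, bp, locus_side)
}

new_haplotype_call <- function(embryo_id, parent, verdict, support, conflict,
                               skipped, per_flank, breakpoint_interval,
                               locus_side_verdict) {
  structure(list(embryo_id = embryo_id, parent = parent, verdict = verdict,
                 support = support, conflict = conflict, skipped = skipped,
                 per_flank = per_flank,
                 breakpoint_interval = breakpoint_interval,
                 locus_side_verdict = locus_side_verdict),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat(sprintf("<haplotype_call> %s/%s: %s (%d support, %d conflict, %d skipped)\n",
              x$embryo_id, x$parent, x$verdict, x$support, x$conflict,
              x$skipped))
  if (!is.null(x$breakpoint_interval))
    cat(sprintf("  breakpoint in [%s, %s]\n", x$breakpoint_interval[1],
                x$breakpoint_interval[2]))
  invisible(x)
}

#' Combine the two parental haplotype calls into a SEA genotype
#'
#' RISK+RISK is AFFECTED, NONRISK+NONRISK NORMAL, mixed CARRIER (annotated
#' with the contributing parent, e.g. "maternal heterozygous"). A
#' RECOMBINANT call contributes its locus-side risk status with a
#' low-confidence flag; a breakpoint spanning the locus, or any NOCALL,
#' gives UNDETERMINED.
#'
#' @param paternal,maternal `haplotype_call` objects
#' @return list of class `haplo_genotype`: `genotype` (NORMAL / CARRIER /
#'   AFFECTED / UNDETERMINED), `annotation`, `low_confidence`,
#'   `risk_from` (named logical), plus the two calls
#' @export
haplotype_genotype <- function(paternal, maternal) {
  eff <- function(call) {
    if (call$verdict %in% c("RISK", "NONRISK")) call$verdict
    else if (call$verdict == "RECOMBINANT") call$locus_side_verdict
    else "NOCALL"
  }
  pv <- eff(paternal); mv <- eff(maternal)
  low <- paternal$verdict %in% c("RECOMBINANT", "NOCALL") ||
    maternal$verdict %in% c("RECOMBINANT", "NOCALL")
  if (pv %in% c("NOCALL", "UNDETERMINED") ||
      mv %in% c("NOCALL", "UNDETERMINED")) {
    out <- list(genotype = "UNDETERMINED", annotation = "haplotype unavailable",
                low_confidence = TRUE,
                risk_from = c(father = NA, mother = NA))
  } else {
    risk_from <- c(father = pv == "RISK", mother = mv == "RISK")
    genotype <- if (all(risk_from)) "AFFECTED"
    else if (!any(risk_from)) "NORMAL" else "CARRIER"
    annotation <- switch(genotype,
      AFFECTED = "abnormal homozygous",
      NORMAL = "normal homozygous",
      CARRIER = if (risk_from[["mother"]]) "maternal heterozygous"
      else "paternal heterozygous")
    out <- list(genotype = genotype, annotation = annotation,
                low_confidence = low, risk_from = risk_from)
  }
  out$paternal <- paternal; out$maternal <- maternal
  class(out) <- "haplo_genotype"
  out
}

#' @export
print.haplo_genotype <- function(x, ...) {
  cat(sprintf("<haplo_genotype> %s (%s)%s\n", x$genotype, x$annotation,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}
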