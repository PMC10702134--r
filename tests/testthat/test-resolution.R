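hap_stub <- function(paternal, maternal) {
  mk <- function(parent, verdict)
    alphapgt:::new_haplotype_call("E", parent, verdict,
      support = if (verdict == "RISK") 10L else 0L,
      conflict = if (verdict == "NONRISK") 10L else 0L,
      skipped = 0L, per_flank = NULL, breakpoint_interval = NULL,
      locus_side_verdict = verdict)
  haplotype_genotype(mk("father", paternal), mk("mother", maternal))
}

cnv2 <- function() alphapgt:::new_cnv_call("16", 2L)

screen_of <- function(cnv) structure(
  list(calls = setNames(list(cnv), "16"),
       euploid = !is.na(cnv$copy_number) && cnv$copy_number == 2L,
       status = "ok"),
  class = "genome_screen")

test_that("compare_calls distinguishes concordant from discordant pairs", {
  expect_true(compare_calls("CARRIER", hap_stub("NONRISK", "RISK"))$concordant)
  expect_false(compare_calls("NORMAL", hap_stub("NONRISK", "RISK"))$concordant)
  expect_false(compare_calls("CARRIER", hap_stub("RISK", "NOCALL"))$concordant)
  expect_false(compare_calls("FAIL", hap_stub("NONRISK", "NONRISK"))$concordant)
})

test_that("trisomy strings follow stage, other-parent risk and PCR feasibility", {
  # MI origin always contributes exactly one risk allele
  expect_equal(alphapgt:::trisomy_genotype_string("MI", TRUE, "CARRIER"),
               "--/--/αα")
  expect_equal(alphapgt:::trisomy_genotype_string("MI", FALSE, "CARRIER"),
               "--/αα/αα")
  # MII duplicates one chromatid: 0 or 2 risk copies, PCR breaks the tie
  expect_equal(alphapgt:::trisomy_genotype_string("MII", FALSE, "NORMAL"),
               "αα/αα/αα")
  expect_equal(alphapgt:::trisomy_genotype_string("MII", TRUE, "AFFECTED"),
               "--/--/--")
  expect_equal(alphapgt:::trisomy_genotype_string("MII", FALSE, "CARRIER"),
               "--/--/αα")
  # irreducible ambiguity yields NA
  expect_true(is.na(alphapgt:::trisomy_genotype_string(NA, TRUE, "FAIL")))
})

test_that("chromosome-16 trisomy outranks every other cause", {
  tri <- alphapgt:::new_cnv_call("16", 3L, origin_parent = "mother",
                                 stage = "MI")
  res <- resolve_discordance("CARRIER", hap_stub("RISK", "NOCALL"), tri,
                             call_rate = 0.85,  # even below QC
                             retest = function() "CARRIER")
  expect_equal(res$cause, "TRISOMY16_BPH")
  expect_equal(res$final_genotype, "--/--/αα")
})

test_that("monosomy 16 reports the retained haplotype's genotype", {
  mono <- alphapgt:::new_cnv_call("16", 1L, origin_parent = "mother",
                                  retained_parent = "father",
                                  retained_risk = FALSE)
  res <- resolve_discordance("NORMAL", hap_stub("NONRISK", "RISK"), mono,
                             call_rate = 0.96)
  expect_equal(res$cause, "MONOSOMY16")
  expect_equal(res$final_genotype, "αα")
})

test_that("a retest that flips to the haplotype genotype proves ADO", {
  res <- resolve_discordance("NORMAL", hap_stub("NONRISK", "RISK"), cnv2(),
                             call_rate = 0.96,
                             retest = function() "CARRIER")
  expect_equal(res$cause, "ADO_MUTANT_ALLELE")
  expect_equal(res$final_genotype, "--/αα")
  res2 <- resolve_discordance("AFFECTED", hap_stub("NONRISK", "RISK"), cnv2(),
                              call_rate = 0.96,
                              retest = function() "CARRIER")
  expect_equal(res2$cause, "ADO_NORMAL_ALLELE")
})

test_that("low call rate with a concurring rebiopsy is poor WGA quality", {
  res <- resolve_discordance("AFFECTED", hap_stub("NONRISK", "RISK"), cnv2(),
                             call_rate = 0.88,
                             retest = function() "AFFECTED",
                             rebiopsy = function()
                               list(pcr = "AFFECTED", call_rate = 0.95))
  expect_equal(res$cause, "POOR_WGA_QUALITY")
  expect_equal(res$final_genotype, "--/--")
})

test_that("an unexplained persistent conflict stays UNRESOLVED", {
  res <- resolve_discordance("NORMAL", hap_stub("RISK", "RISK"), cnv2(),
                             call_rate = 0.97,
                             retest = function() "NORMAL")
  expect_equal(res$cause, "UNRESOLVED")
})

test_that("finalize_embryo shortcuts concordant pairs", {
  rep1 <- finalize_embryo("E01", "CARRIER", hap_stub("NONRISK", "RISK"),
                          screen_of(cnv2()), call_rate = 0.97)
  expect_equal(rep1$cause, "CONCORDANT")
  expect_equal(rep1$final_genotype, "--/αα")
  expect_true(rep1$euploid)
})

test_that("percentages print with the cohort rounding convention", {
  expect_equal(alphapgt:::printed_pct(162, 172), 94.2)
  expect_equal(alphapgt:::printed_pct(2, 172), 1.16)
  expect_equal(alphapgt:::printed_pct(105, 170), 61.8)
  expect_equal(alphapgt:::printed_pct(1, 300), 0.33)
})

test_that("cohort_summary aggregates causes, rates and distributions", {
  mk <- function(id, g, cause = "CONCORDANT", concord = TRUE)
    embryo_report(id, pcr_genotype = g, haplotype_genotype = g,
                  final_genotype = genotype_string(g), cause = cause,
                  concordant = concord, euploid = TRUE, call_rate = 0.97)
  reports <- list(mk("a", "NORMAL"), mk("b", "CARRIER"),
                  mk("c", "CARRIER", "ADO_MUTANT_ALLELE", FALSE),
                  mk("d", "AFFECTED"))
  cs <- cohort_summary(reports)
  expect_equal(cs$n_embryos, 4)
  expect_equal(cs$n_concordant, 3)
  expect_equal(cs$n_ado, 1)
  expect_equal(unname(cs$cause_counts[["ADO_MUTANT_ALLELE"]]), 1)
  expect_equal(unname(cs$pcr_distribution[["CARRIER"]]), 2)
})

test_that("transfer priority ranks normals first and excludes risks", {
  mk <- function(id, g, euploid = TRUE, cause = "CONCORDANT", cr = 0.97)
    embryo_report(id, pcr_genotype = g, haplotype_genotype = g,
                  final_genotype = genotype_string(g), cause = cause,
                  concordant = TRUE, euploid = euploid, call_rate = cr)
  reports <- list(
    mk("aff", "AFFECTED"),
    mk("car", "CARRIER"),
    mk("nor", "NORMAL"),
    mk("nor_aneu", "NORMAL", euploid = FALSE),
    mk("nor_lowcr", "NORMAL", cr = 0.92))
  tp <- transfer_priority(reports)
  expect_false("aff" %in% tp$embryo_id)
  expect_false("nor_aneu" %in% tp$embryo_id)
  expect_equal(tp$embryo_id[1:2], c("nor", "nor_lowcr"))
  expect_true("car" %in% tp$embryo_id)
  expect_true(all(which(tp$final_genotype == "αα/αα") <
                    which(tp$final_genotype == "--/αα")))
})

test_that("missing upstream informative SNPs flag carrier transfers", {
  mk <- function(id, g)
    embryo_report(id, pcr_genotype = g, haplotype_genotype = g,
                  final_genotype = genotype_string(g), cause = "CONCORDANT",
                  concordant = TRUE, euploid = TRUE, call_rate = 0.97)
  inf <- data.frame(snp_id = "s1", chromosome = "16", position = 3e6,
                    informative_for = "mother", het_parent_gt = "AB",
                    hom_parent_allele = "A", flank = "downstream_3p",
                    stringsAsFactors = FALSE)
  tp <- transfer_priority(list(mk("car", "CARRIER"), mk("nor", "NORMAL")),
                          informative = inf)
  car_row <- tp[tp$embryo_id == "car", ]
  expect_match(car_row$flag, "misdiagnosis")
})

test_that("the published discordant cases resolve to the printed outcomes", {
  cases <- published_discordant_cases()
  expect_length(cases, 10)
  for (case in cases) {
    rep <- resolve_published_case(case)
    expect_equal(rep$final_genotype, case$published$final, info = case$id)
    expect_equal(rep$cause, case$published$cause, info = case$id)
  }
})
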