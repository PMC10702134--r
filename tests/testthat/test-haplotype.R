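# A compact configuration so constructed positions are easy to reason about:
# locus 16:1000-2000 with 500-bp flanks.
tiny_cfg <- function() family_config(locus = list(chrom = "16", start = 1000L,
                                                  end = 2000L),
                                     flank_bp = 500)

test_that("informative SNPs are het in one parent, hom in the other", {
  ids <- paste0("s", 1:6)
  pos <- c(600, 700, 1500, 2100, 2200, 2300)
  father <- mini_array("F", "father", ids,
                       c("AB", "AA", "AB", "AB", "AA", "NC"), pos)
  mother <- mini_array("M", "mother", ids,
                       c("AA", "AB", "AB", "BB", "AB", "AB"), pos)
  inf <- find_informative_snps(father, mother, tiny_cfg())
  # s1: father het / mother hom-A; s4: father het / mother hom-B;
  # s5: mother het / father hom-A. s2 would be mother-informative too.
  # s3 double-het and s6 NC are not informative.
  expect_setequal(inf$snp_id, c("s1", "s2", "s4", "s5"))
  expect_equal(inf$informative_for[inf$snp_id == "s1"], "father")
  expect_equal(inf$informative_for[inf$snp_id == "s5"], "mother")
  expect_equal(inf$hom_parent_allele[inf$snp_id == "s4"], "B")
  expect_equal(inf$flank[inf$snp_id == "s1"], "upstream_5p")
  expect_equal(inf$flank[inf$snp_id == "s4"], "downstream_3p")
})

test_that("carrier parents yield no informative SNPs inside the deletion", {
  fam <- zn_family()
  inf <- zn_informative()
  expect_gt(nrow(inf), 0)
  expect_false(any(inf$flank == "in_gene"))
})

test_that("transmitted_allele performs Mendelian subtraction", {
  # hom parent carries A: embryo AB -> het parent gave B; AA -> gave A;
  # BB contradicts the hom parent; NC/NA unusable
  expect_equal(
    alphapgt:::transmitted_allele(c("AB", "AA", "BB", "NC", NA), rep("A", 5)),
    c("B", "A", NA, NA, NA))
  expect_equal(alphapgt:::transmitted_allele("AB", "B"), "A")
})

test_that("reference-embryo phasing recovers the simulated truth exactly", {
  fam <- zn_family()
  inf <- zn_informative()
  pcr <- vapply(fam$embryos, function(e)
    as.character(call_pcr_genotype(e$peaks)), character(1))
  for (kind in c("AFFECTED", "NORMAL")) {
    ref <- names(pcr)[pcr == kind][1]
    if (is.na(ref)) next
    ph <- phase_from_reference(fam$embryos[[ref]]$array, kind, inf)
    for (p in c("father", "mother")) {
      truth <- truth_phase(fam, inf, p)
      expect_equal(ph[[p]]$risk_allele[names(truth)], truth)
    }
  }
})

test_that("phase_from_reference rejects het references and bad Mendel rates", {
  fam <- zn_family(); inf <- zn_informative()
  expect_error(
    phase_from_reference(fam$embryos$E01$array, "CARRIER", inf),
    "homozygous")
  # corrupt an embryo so its calls contradict the hom parent massively
  pcr <- vapply(fam$embryos, function(e)
    as.character(call_pcr_genotype(e$peaks)), character(1))
  ref <- names(pcr)[pcr == "AFFECTED"][1]
  bad <- fam$embryos[[ref]]$array
  idx <- match(inf$snp_id, bad$records$snp_id)
  bad$records$gtype[idx] <- ifelse(inf$hom_parent_allele == "A", "BB", "AA")
  expect_error(phase_from_reference(bad, "AFFECTED", inf), "inconsistent")
})

test_that("a carrier pair with opposite risk parents phases uniquely", {
  fam <- zn_family(); inf <- zn_informative()
  pcr <- vapply(fam$embryos, function(e)
    as.character(call_pcr_genotype(e$peaks)), character(1))
  carriers <- names(pcr)[pcr == "CARRIER"]
  risk_f <- vapply(fam$embryos, function(e)
    e$truth$inherited_risk[["father"]], numeric(1))
  e1 <- carriers[risk_f[carriers] == 1][1]
  e2 <- carriers[risk_f[carriers] == 0][1]
  ph <- phase_from_carrier_pair(fam$embryos[[e1]]$array,
                                fam$embryos[[e2]]$array, inf,
                                config = fam$config,
                                father = fam$father_array,
                                mother = fam$mother_array)
  expect_false(is.null(ph$father))
  for (p in c("father", "mother")) {
    truth <- truth_phase(fam, inf, p)
    shared <- intersect(names(ph[[p]]$risk_allele), names(truth))
    expect_gt(length(shared), 0)
    expect_equal(ph[[p]]$risk_allele[shared], truth[shared])
  }
})

test_that("without locus evidence the carrier pair is ambiguous", {
  fam <- zn_family(); inf <- zn_informative()
  pcr <- vapply(fam$embryos, function(e)
    as.character(call_pcr_genotype(e$peaks)), character(1))
  carriers <- names(pcr)[pcr == "CARRIER"]
  risk_f <- vapply(fam$embryos, function(e)
    e$truth$inherited_risk[["father"]], numeric(1))
  e1 <- carriers[risk_f[carriers] == 1][1]
  e2 <- carriers[risk_f[carriers] == 0][1]
  ph <- phase_from_carrier_pair(fam$embryos[[e1]]$array,
                                fam$embryos[[e2]]$array, inf)
  expect_equal(ph$verdict, "NOCALL")
  expect_match(ph$reason, "ambiguous")
})

test_that("embryo haplotype calls agree with truth on a zero-noise family", {
  fam <- zn_family(); inf <- zn_informative()
  pcr <- vapply(fam$embryos, function(e)
    as.character(call_pcr_genotype(e$peaks)), character(1))
  ref <- names(pcr)[pcr == "AFFECTED"][1]
  ph <- phase_from_reference(fam$embryos[[ref]]$array, "AFFECTED", inf)
  for (id in names(fam$embryos)) {
    tr <- fam$embryos[[id]]$truth
    for (p in c("father", "mother")) {
      hc <- call_embryo_haplotype(fam$embryos[[id]]$array, ph[[p]], inf,
                                  fam$config)
      expected <- if (tr$inherited_risk[[p]] > 0) "RISK" else "NONRISK"
      expect_true(hc$verdict == expected ||
                    (hc$verdict == "RECOMBINANT" &&
                       hc$locus_side_verdict == expected),
                  info = paste(id, p))
    }
  }
})

test_that("a haplotype switch away from the locus is called RECOMBINANT", {
  cfg <- tiny_cfg()
  ids <- paste0("d", 1:12)
  pos <- seq(2050, 2490, length.out = 12)
  phase <- structure(list(parent = "father",
                          risk_allele = setNames(rep("A", 12), ids),
                          source = "ref", reference_kind = "affected",
                          n_used = 12L, n_conflict = 0L),
                     class = "parental_phase")
  inf <- data.frame(snp_id = ids, chromosome = "16", position = pos,
                    informative_for = "father", het_parent_gt = "AB",
                    hom_parent_allele = "A", flank = "downstream_3p",
                    stringsAsFactors = FALSE)
  # first 6 SNPs transmit A (risk: embryo AA), last 6 transmit B (AB)
  emb <- mini_array("E", "embryo", ids,
                    c(rep("AA", 6), rep("AB", 6)), pos)
  hc <- call_embryo_haplotype(emb, phase, inf, cfg)
  expect_equal(hc$verdict, "RECOMBINANT")
  # the breakpoint lies between the 6th and 7th SNP
  expect_true(hc$breakpoint_interval[1] >= pos[6] &&
                hc$breakpoint_interval[2] <= pos[7])
  # the anchor nearest the locus (upstream block) carries the risk allele
  expect_equal(hc$locus_side_verdict, "RISK")
})

test_that("recombination across the locus leaves the verdict undetermined", {
  cfg <- tiny_cfg()
  ids <- paste0("x", 1:12)
  pos <- c(seq(520, 970, length.out = 6), seq(2050, 2490, length.out = 6))
  phase <- structure(list(parent = "father",
                          risk_allele = setNames(rep("A", 12), ids),
                          source = "ref", reference_kind = "affected",
                          n_used = 12L, n_conflict = 0L),
                     class = "parental_phase")
  inf <- data.frame(snp_id = ids, chromosome = "16", position = pos,
                    informative_for = "father", het_parent_gt = "AB",
                    hom_parent_allele = "A",
                    flank = rep(c("upstream_5p", "downstream_3p"), each = 6),
                    stringsAsFactors = FALSE)
  emb <- mini_array("E", "embryo", ids, c(rep("AA", 6), rep("AB", 6)), pos)
  hc <- call_embryo_haplotype(emb, phase, inf, cfg)
  expect_equal(hc$verdict, "RECOMBINANT")
  expect_equal(hc$locus_side_verdict, "UNDETERMINED")
  other <- alphapgt:::new_haplotype_call("E", "mother", "NONRISK", 10L, 0L, 0L, NULL,
                              NULL, "NONRISK")
  hg <- haplotype_genotype(hc, other)
  expect_equal(hg$genotype, "UNDETERMINED")
  expect_true(hg$low_confidence)
})

test_that("too few informative SNPs give NOCALL", {
  cfg <- tiny_cfg()
  ids <- c("a1", "a2")
  phase <- structure(list(parent = "father",
                          risk_allele = setNames(c("A", "A"), ids),
                          source = "ref", reference_kind = "affected",
                          n_used = 2L, n_conflict = 0L),
                     class = "parental_phase")
  inf <- data.frame(snp_id = ids, chromosome = "16", position = c(2100, 2200),
                    informative_for = "father", het_parent_gt = "AB",
                    hom_parent_allele = "A", flank = "downstream_3p",
                    stringsAsFactors = FALSE)
  emb <- mini_array("E", "embryo", ids, c("AA", "AA"), c(2100, 2200))
  hc <- call_embryo_haplotype(emb, phase, inf, cfg)
  expect_equal(hc$verdict, "NOCALL")
})

test_that("haplotype verdict pairs combine into genotypes with annotations", {
  mk <- function(parent, verdict)
    alphapgt:::new_haplotype_call("E", parent, verdict,
                       support = if (verdict == "RISK") 10L else 0L,
                       conflict = if (verdict == "NONRISK") 10L else 0L,
                       skipped = 0L, per_flank = NULL,
                       breakpoint_interval = NULL,
                       locus_side_verdict = verdict)
  expect_equal(haplotype_genotype(mk("father", "RISK"),
                                  mk("mother", "RISK"))$genotype, "AFFECTED")
  hg <- haplotype_genotype(mk("father", "NONRISK"), mk("mother", "RISK"))
  expect_equal(hg$genotype, "CARRIER")
  expect_equal(hg$annotation, "maternal heterozygous")
  expect_equal(haplotype_genotype(mk("father", "NONRISK"),
                                  mk("mother", "NONRISK"))$genotype, "NORMAL")
  hg2 <- haplotype_genotype(mk("father", "NOCALL"), mk("mother", "RISK"))
  expect_equal(hg2$genotype, "UNDETERMINED")
  expect_true(hg2$low_confidence)
})

test_that("informative_snp_stats reproduces means and SDs from counts", {
  df <- data.frame(
    family = rep(c("f1", "f2"), each = 2),
    parent = rep(c("father", "mother"), 2),
    flank = "downstream_3p",
    n = c(10, 20, 20, 40), stringsAsFactors = FALSE)
  st <- informative_snp_stats(df)$stats
  row <- st[st$parent == "mother" & st$flank == "downstream_3p", ]
  expect_equal(row$mean, 30)
  expect_equal(row$sd, sd(c(20, 40)))
})
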