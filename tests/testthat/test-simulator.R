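test_that("simulated parents satisfy the carrier invariants", {
  fam <- zn_family()
  for (p in list(fam$father, fam$mother)) {
    expect_true(p$risk_index %in% 1:2)
    arr <- if (p$sample_id == fam$father$sample_id) fam$father_array
           else fam$mother_array
    # outside the deletion the unphased genotype equals the haplotype pair
    del <- alphapgt:::deletion_mask(fam$panel, fam$config)
    hap <- p$hap
    exp_gt <- ifelse(hap[, 1] == hap[, 2], paste0(hap[, 1], hap[, 2]), "AB")
    exp_gt[exp_gt == "BA"] <- "AB"
    expect_equal(arr$records$gtype[!del], exp_gt[!del])
    # inside the deletion the risk haplotype is gone: hemizygous calls show
    # the retained allele as homozygous
    retained <- hap[del, 3 - p$risk_index]
    expect_equal(arr$records$gtype[del], paste0(retained, retained))
  }
})

test_that("zero-noise euploid embryos are Mendelian-consistent everywhere", {
  fam <- zn_family()
  del <- alphapgt:::deletion_mask(fam$panel, fam$config)
  fh <- fam$father$hap; mh <- fam$mother$hap
  for (e in fam$embryos) {
    gt <- e$array$records$gtype[!del]
    poss <- mapply(function(f1, f2, m1, m2, g) {
      combos <- c(paste0(f1, m1), paste0(f1, m2), paste0(f2, m1),
                  paste0(f2, m2))
      combos <- vapply(combos, function(x)
        paste(sort(strsplit(x, "")[[1]]), collapse = ""), character(1))
      g %in% combos
    }, fh[!del, 1], fh[!del, 2], mh[!del, 1], mh[!del, 2], gt)
    expect_true(all(poss))
  }
})

test_that("ground-truth genotype matches the PCR peak simulation", {
  fam <- zn_family()
  for (e in fam$embryos) {
    call <- as.character(call_pcr_genotype(e$peaks))
    expect_equal(genotype_string(call), e$truth$true_genotype)
  }
})

test_that("trisomy and monosomy render the expected copy structure", {
  cfg <- family_config(); panel <- test_panel()
  events <- list(
    tri_MI = aneuploidy_spec("trisomy", "16", "mother", "MI"),
    tri_MII = aneuploidy_spec("trisomy", "16", "father", "MII"),
    mono = aneuploidy_spec("monosomy", "16", "mother"))
  fam <- simulate_family(cfg, panel, n_embryos = 3, noise = no_noise(),
                         aneuploidy = unname(events), seed = 5)
  chr16 <- fam$panel$chromosome == "16"
  lrr <- lapply(fam$embryos, function(e) e$array$records$lrr[chr16])
  expect_equal(median(lrr[[1]]), log2(3 / 2), tolerance = 1e-9)
  expect_equal(median(lrr[[2]]), log2(3 / 2), tolerance = 1e-9)
  expect_equal(median(lrr[[3]]), -1, tolerance = 1e-9)
  expect_length(fam$embryos$E01$truth$chr16_copies, 3)
  expect_length(fam$embryos$E03$truth$chr16_copies, 1)
  # MI trisomy: the two extra maternal copies are the two distinct homologs
  par16 <- vapply(fam$embryos$E01$truth$chr16_copies, `[[`, character(1),
                  "parent")
  expect_equal(sum(par16 == "mother"), 2)
  # monosomy of the maternal chromosome leaves a paternal copy
  expect_equal(fam$embryos$E03$truth$chr16_copies[[1]]$parent, "father")
})

test_that("WGA noise produces no-calls at roughly the configured rate", {
  cfg <- family_config(); panel <- test_panel()
  nm <- noise_model(ado_rate = 0, miscall_rate = 0, nocall_rate = 0.05,
                    pcr_ado_rate = 0)
  fam <- simulate_family(cfg, panel, n_embryos = 8, noise = nm, seed = 13)
  nc <- vapply(fam$embryos, function(e)
    mean(e$array$records$gtype == "NC"), numeric(1))
  n <- nrow(panel)
  expect_lt(abs(mean(nc) - 0.05), 4 * sqrt(0.05 * 0.95 / (8 * n)))
})

test_that("simulation is reproducible and substreams are independent", {
  cfg <- family_config(); panel <- test_panel()
  f1 <- simulate_family(cfg, panel, n_embryos = 3, seed = 99)
  f2 <- simulate_family(cfg, panel, n_embryos = 3, seed = 99)
  expect_identical(f1$embryos$E02$array$records,
                   f2$embryos$E02$array$records)
  f3 <- simulate_family(cfg, panel, n_embryos = 3, seed = 100)
  expect_false(identical(f1$embryos$E02$array$records$gtype,
                         f3$embryos$E02$array$records$gtype))
  expect_true(all(vapply(1:50, function(i)
    alphapgt:::substream_seed(99, i), numeric(1)) < 2^31))
})

test_that("carrier-by-carrier truth genotypes approach 1:2:1", {
  cfg <- family_config()
  panel <- default_panel(cfg, backbone_per_chrom = 2,
                         flank_counts = c(upstream_5p = 4, in_gene = 4,
                                          downstream_3p = 6))
  g <- character(0)
  for (b in 1:2) {
    fam <- simulate_family(cfg, panel, n_embryos = 200, noise = no_noise(),
                           seed = alphapgt:::substream_seed(207, b))
    g <- c(g, vapply(fam$embryos, function(e) e$truth$true_genotype,
                     character(1)))
  }
  n <- length(g)
  n_aff <- sum(g == "--/--"); n_car <- sum(g == "--/αα")
  expect_lt(abs(n_aff - n / 4), 4 * sqrt(n * 0.25 * 0.75))
  expect_lt(abs(n_car - n / 2), 4 * sqrt(n * 0.25))
})

test_that("an explicit aneuploidy list accepts NULL entries as euploid", {
  fam <- simulate_family(family_config(), test_panel(), n_embryos = 2,
                         noise = no_noise(),
                         aneuploidy = list(NULL,
                           aneuploidy_spec("monosomy", "16", "father")),
                         seed = 3)
  expect_equal(fam$embryos$E01$truth$aneuploidy$kind, "none")
  expect_equal(fam$embryos$E02$truth$aneuploidy$kind, "monosomy")
})

test_that("aneuploidy_spec validates its arguments", {
  expect_error(aneuploidy_spec("trisomy", "16", "mother"), "stage")
  expect_error(aneuploidy_spec("trisomy", "99", "mother", "MI"))
  expect_silent(aneuploidy_spec("monosomy", "7", "father"))
})
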