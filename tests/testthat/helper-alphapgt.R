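# Shared fixtures, memoized so expensive simulations run once per session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small panel: full genome coverage but a light backbone, enough for
# copy-number calls (>= 20 SNPs per chromosome) and haplotype work.
test_panel <- function() memo("panel", function()
  default_panel(family_config(), backbone_per_chrom = 60))

# Zero-noise euploid family: 12 embryos, fixed seed.
zn_family <- function() memo("zn_family", function()
  simulate_family(family_config(), test_panel(), n_embryos = 12,
                  noise = no_noise(), seed = 42))

zn_informative <- function() memo("zn_informative", function() {
  fam <- zn_family()
  find_informative_snps(fam$father_array, fam$mother_array, fam$config)
})

# The phase implied by the simulator's ground truth: risk_allele[snp] is the
# allele on the parent's risk haplotype.
truth_phase <- function(fam, informative, parent) {
  par <- fam[[parent]]
  sel <- informative$informative_for == parent
  ids <- informative$snp_id[sel]
  idx <- match(ids, fam$panel$snp_id)
  setNames(par$hap[idx, par$risk_index], ids)
}

# Build a tiny sample_array from parallel vectors (defaults chromosome 16).
mini_array <- function(id, role, snp_id, gtype, position = seq_along(snp_id),
                       chromosome = "16", baf = NA_real_, lrr = NA_real_) {
  sample_array(id, role, data.frame(
    snp_id = snp_id, chromosome = chromosome, position = position,
    gtype = gtype, baf = baf, lrr = lrr, stringsAsFactors = FALSE))
}

# Run the full pipeline on a simulated family with simulator-backed
# retest/rebiopsy providers.
analyze_sim_family <- function(fam, noise, seed) {
  prov <- simulation_providers(fam, noise, seed = seed)
  analyze_family(fam$father_array, fam$mother_array,
                 lapply(fam$embryos, `[[`, "array"),
                 do.call(rbind, lapply(fam$embryos, `[[`, "peaks")),
                 fam$config,
                 retest_provider = prov$retest,
                 rebiopsy_provider = prov$rebiopsy)
}
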