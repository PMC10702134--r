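# Synthetic family/embryo generator: phased carrier parents, meioses with
# recombination, whole-chromosome aneuploidy, SEA-deletion rendering and WGA
# noise, with ground truth retained so every downstream caller can be tested
# against a known answer.

#' Default simulated SNP panel
#'
#' Mirrors the array layout relevant to SEA-type PGT: a customised chr16
#' flank of 42 upstream-5' / 10 in-gene / 355 downstream-3' SNPs around the
#' HBA1+HBA2 locus, embedded in an evenly spaced genome-wide backbone used
#' for aneuploidy screening. The backbone defaults to 2,000 SNPs per
#' chromosome (a desk-scale stand-in for the ~300,000-SNP array).
#'
#' @param config a [family_config()]
#' @param backbone_per_chrom evenly spaced backbone SNPs per chromosome
#' @param flank_counts named vector: custom SNP counts for `upstream_5p`,
#'   `in_gene`, `downstream_3p`
#' @param chromosomes chromosomes to include (default: all autosomes)
#' @return a [snp_panel()]
#' @export
default_panel <- function(config = family_config(),
                          backbone_per_chrom = 2000,
                          flank_counts = c(upstream_5p = 42, in_gene = 10,
                                           downstream_3p = 355),
                          chromosomes = AUTOSOMES) {
  part <- partition_region(config)
  ids <- character(); chr <- character(); pos <- integer()
  add <- function(p, c_, prefix) {
    p <- unique(as.integer(round(p)))
    ids <<- c(ids, sprintf("%s_%s_%d", prefix, c_, p))
    chr <<- c(chr, rep(c_, length(p)))
    pos <<- c(pos, p)
  }
  even <- function(iv, n) if (n <= 0 || iv[1] > iv[2]) integer() else
    seq(iv[1], iv[2], length.out = n + 2)[-c(1, n + 2)]
  lc <- config$locus$chrom
  add(even(part$upstream_5p, flank_counts[["upstream_5p"]]), lc, "cust5p")
  add(even(part$in_gene, flank_counts[["in_gene"]]), lc, "gene")
  add(even(part$downstream_3p, flank_counts[["downstream_3p"]]), lc, "cust3p")
  for (c_ in chromosomes)
    add(even(c(1, CHROM_LENGTH[[c_]]), backbone_per_chrom), c_, "bb")
  keep <- !duplicated(paste(chr, pos))
  snp_panel(ids[keep], chr[keep], pos[keep])
}

#' WGA / array / PCR noise model
#'
#' @param ado_rate per-allele dropout probability during WGA before genotype
#'   calling
#' @param miscall_rate probability a called genotype is replaced by a wrong one
#' @param nocall_rate probability a called genotype is reported as NC
#' @param baf_sd,lrr_sd Gaussian noise SD added to ideal BAF / LRR
#' @param pcr_ado_rate per-allele dropout probability in the Gap-PCR
#' @return object of class `noise_model`
#' @export
noise_model <- function(ado_rate = 0.05, miscall_rate = 0.002,
                        nocall_rate = 0.02, baf_sd = 0.03, lrr_sd = 0.15,
                        pcr_ado_rate = 0.01) {
  p <- c(ado_rate, miscall_rate, nocall_rate, pcr_ado_rate)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (baf_sd < 0 || lrr_sd < 0) stop("noise SDs must be >= 0")
  structure(list(ado_rate = ado_rate, miscall_rate = miscall_rate,
                 nocall_rate = nocall_rate, baf_sd = baf_sd, lrr_sd = lrr_sd,
                 pcr_ado_rate = pcr_ado_rate), class = "noise_model")
}

#' Zero-noise model (oracle runs)
#' @return a [noise_model()] with every rate and SD at 0
#' @export
no_noise <- function() noise_model(0, 0, 0, 0, 0, 0)

#' Whole-chromosome aneuploidy event specification
#'
#' @param kind "none", "trisomy" or "monosomy"
#' @param chromosome affected chromosome (required unless kind = "none")
#' @param origin parent of origin: "father" or "mother" (for trisomy the
#'   parent contributing the extra material; for monosomy the parent whose
#'   homolog is lost)
#' @param stage "MI" or "MII" (trisomy only): MI transmits both of the origin
#'   parent's homologs (both parental homologs, BPH, at the pericentromere);
#'   MII transmits one recombined chromatid twice (single parental homolog,
#'   SPH)
#' @return object of class `aneuploidy_spec`
#' @export
aneuploidy_spec <- function(kind = c("none", "trisomy", "monosomy"),
                            chromosome = NA, origin = NA, stage = NA) {
  kind <- match.arg(kind)
  if (kind == "none")
    return(structure(list(kind = "none", chromosome = NA, origin = NA,
                          stage = NA), class = "aneuploidy_spec"))
  chromosome <- check_chromosome(chromosome)
  origin <- match.arg(origin, c("father", "mother"))
  if (kind == "trisomy") {
    if (is.na(stage)) stop("trisomy requires stage MI or MII")
    stage <- match.arg(stage, c("MI", "MII"))
  } else stage <- NA
  structure(list(kind = kind, chromosome = chromosome, origin = origin,
                 stage = stage), class = "aneuploidy_spec")
}

#' Simulate a pair of phased carrier parents
#'
#' Each haplotype allele is drawn independently as B with the per-SNP
#' frequency `maf`; each parent has exactly one haplotype flagged as the risk
#' haplotype carrying the SEA deletion over the configured deletion interval.
#'
#' @param panel a [snp_panel()]
#' @param config a [family_config()]
#' @param maf scalar or per-SNP B-allele frequency
#' @param seed optional integer seed
#' @return list with `father` and `mother`, each of class `phased_parent`
#' @export
simulate_parents <- function(panel, config = family_config(), maf = 0.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(panel) == 0L) stop("panel is empty")
  maf <- rep_len(maf, nrow(panel))
  if (any(maf < 0 | maf > 1)) stop("maf must lie in [0, 1]")
  mk <- function(id, role) {
    hap <- matrix(ifelse(runif(2L * nrow(panel)) < rep(maf, 2), "B", "A"),
                  ncol = 2)
    structure(list(sample_id = id, role = role, panel = panel, hap = hap,
                   risk_index = sample(1:2, 1), config = config),
              class = "phased_parent")
  }
  list(father = mk(config$father_id, "father"),
       mother = mk(config$mother_id, "mother"))
}

#' Render a phased parent as an unphased sample array
#'
#' Parental genotypes come from peripheral blood, so they are rendered
#' noise-free: exact AB calls, BAF at {0, 1/2, 1}, LRR 0. SNPs falling inside
#' the deletion interval on the risk haplotype are hemizygous: the remaining
#' allele is reported as a homozygous call with BAF 0 or 1.
#'
#' @param parent a `phased_parent`
#' @return a [sample_array()]
#' @export
parent_array <- function(parent) {
  panel <- parent$panel
  del <- deletion_mask(panel, parent$config)
  a1 <- parent$hap[, 1]; a2 <- parent$hap[, 2]
  drop1 <- del & parent$risk_index == 1L
  drop2 <- del & parent$risk_index == 2L
  nb <- (a1 == "B" & !drop1) + (a2 == "B" & !drop2)
  cn <- (!drop1) + (!drop2)
  gt <- ifelse(cn == 2L, c("AA", "AB", "BB")[nb + 1L],
               ifelse(nb > 0L, "BB", "AA"))
  sample_array(parent$sample_id, parent$role, data.frame(
    snp_id = panel$snp_id, chromosome = panel$chromosome,
    position = panel$position, gtype = gt,
    baf = ifelse(cn > 0L, nb / cn, NA_real_),
    lrr = ifelse(cn > 0L, 0, NA_real_), stringsAsFactors = FALSE))
}

deletion_mask <- function(panel, config) {
  panel$chromosome == config$locus$chrom &
    panel$position >= config$deletion$start &
    panel$position <= config$deletion$end
}

#' Default recombination map
#'
#' One expected crossover per 100 Mb per chromosome (~1 cM/Mb). On the locus
#' chromosome, crossovers are restricted to positions downstream (centromere
#' side) of the HBA locus: observed recombination hotspots in the region all
#' lie downstream of the genes and the telomere-side upstream segment is
#' effectively recombination-free.
#'
#' @param config a [family_config()]
#' @param rate_per_bp expected crossovers per base pair
#' @return data.frame with `chromosome`, `lambda`, `min_pos`, `max_pos`
#' @export
default_recomb_map <- function(config = family_config(),
                               rate_per_bp = 1e-8) {
  df <- data.frame(chromosome = CHROMOSOMES,
                   lambda = unname(CHROM_LENGTH[CHROMOSOMES]) * rate_per_bp,
                   min_pos = 1,
                   max_pos = unname(CHROM_LENGTH[CHROMOSOMES]),
                   stringsAsFactors = FALSE)
  i <- df$chromosome == config$locus$chrom
  df$min_pos[i] <- config$locus$end + 1
  df
}

#' Simulate one meiosis of a phased parent
#'
#' Crossover counts are Poisson(`lambda`) per chromosome, positions uniform on
#' the map's allowed interval; the transmitted chromatid starts from a random
#' homolog and switches source at each crossover. With zero intensity the
#' transmitted chromatid is one parental haplotype intact.
#'
#' @param parent a `phased_parent`
#' @param recomb_map as from [default_recomb_map()]
#' @param seed optional integer seed
#' @return object of class `meiosis_event` with `crossovers` (named list of
#'   sorted positions) and `start_hap` (named 1/2 vector)
#' @export
simulate_meiosis <- function(parent, recomb_map = default_recomb_map(parent$config),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(recomb_map$lambda < 0)) stop("recombination intensity must be >= 0")
  chroms <- unique(parent$panel$chromosome)
  xo <- list(); start <- integer()
  for (c_ in chroms) {
    r <- recomb_map[recomb_map$chromosome == c_, , drop = FALSE]
    k <- if (nrow(r) && r$lambda[1] > 0) rpois(1, r$lambda[1]) else 0L
    xo[[c_]] <- if (k > 0) sort(runif(k, r$min_pos[1], r$max_pos[1])) else numeric()
    start[[c_]] <- sample(1:2, 1)
  }
  structure(list(parent = parent$role, crossovers = xo, start_hap = start),
            class = "meiosis_event")
}

# Source haplotype (1/2) of the transmitted chromatid at each panel SNP.
meiosis_source <- function(parent, meiosis) {
  panel <- parent$panel
  src <- integer(nrow(panel))
  for (c_ in unique(panel$chromosome)) {
    i <- which(panel$chromosome == c_)
    n_xo <- findInterval(panel$position[i], meiosis$crossovers[[c_]])
    s <- meiosis$start_hap[[c_]]
    src[i] <- ifelse(n_xo %% 2L == 0L, s, 3L - s)
  }
  src
}

# One transmitted chromosome copy: alleles over the panel, per-SNP source
# haplotype and the parent it came from.
chromatid <- function(parent, source) {
  list(parent = parent$role,
       alleles = parent$hap[cbind(seq_len(nrow(parent$panel)), source)],
       source = source, risk_index = parent$risk_index)
}

intact_chromatid <- function(parent, hap_index) {
  chromatid(parent, rep(hap_index, nrow(parent$panel)))
}

#' Simulate one embryo biopsy sample
#'
#' Builds the embryo's chromosome copies from one meiosis per parent (plus the
#' requested aneuploidy event), renders the SEA deletion (risk-haplotype
#' copies contribute no allele inside the deletion interval), computes ideal
#' BAF = nB/copy-number and LRR = log2(CN/2), applies the WGA noise model, and
#' returns the observed [sample_array()] together with the retained ground
#' truth.
#'
#' @param parents list with `father`, `mother` (`phased_parent`s)
#' @param config a [family_config()]
#' @param aneuploidy an [aneuploidy_spec()]
#' @param noise a [noise_model()]
#' @param embryo_id sample id for the embryo
#' @param recomb_map recombination map for the parental meioses
#' @param seed optional integer seed
#' @return list with `array` ([sample_array()]) and `truth` (`embryo_truth`)
#' @export
simulate_embryo <- function(parents, config = family_config(),
                            aneuploidy = aneuploidy_spec(),
                            noise = noise_model(), embryo_id = "E1",
                            recomb_map = default_recomb_map(config),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  father <- parents$father; mother <- parents$mother
  panel <- father$panel
  n <- nrow(panel)
  if (identical(aneuploidy$kind, "trisomy") && is.na(aneuploidy$stage))
    stop("trisomy requires a meiotic stage (MI or MII)")

  pat_mei <- simulate_meiosis(father, recomb_map)
  mat_mei <- simulate_meiosis(mother, recomb_map)
  pat_copy <- chromatid(father, meiosis_source(father, pat_mei))
  mat_copy <- chromatid(mother, meiosis_source(mother, mat_mei))

  copies <- list(pat_copy, mat_copy)
  aneu_idx <- if (aneuploidy$kind == "none") integer() else
    which(panel$chromosome == aneuploidy$chromosome)
  if (length(aneu_idx)) {
    op <- if (aneuploidy$origin == "father") father else mother
    oc <- if (aneuploidy$origin == "father") 1L else 2L
    if (aneuploidy$kind == "trisomy") {
      extra <- if (aneuploidy$stage == "MI") {
        # MI non-disjunction: both homologs of the origin parent, intact
        list(intact_chromatid(op, 1L), intact_chromatid(op, 2L))
      } else {
        # MII: the origin parent's recombined chromatid, twice
        orig <- copies[[oc]]
        list(orig, orig)
      }
      # splice: replace origin copy on the affected chromosome with the pair
      copies[[oc]] <- mask_copy(copies[[oc]], aneu_idx, drop = TRUE)
      extra <- lapply(extra, function(cp) mask_copy(cp, aneu_idx, drop = FALSE))
      copies <- c(copies, extra)
    } else { # monosomy: origin parent contributes nothing on that chromosome
      copies[[oc]] <- mask_copy(copies[[oc]], aneu_idx, drop = TRUE)
    }
  }

  del <- deletion_mask(panel, config)
  present <- vapply(copies, function(cp) {
    p <- cp$active
    if (is.null(p)) p <- rep(TRUE, n)
    p & !(del & cp$source == cp$risk_index)
  }, logical(n))
  is_b <- vapply(copies, function(cp) cp$alleles == "B", logical(n))
  cn <- rowSums(present)
  nb <- rowSums(is_b & present)

  baf_ideal <- ifelse(cn > 0, nb / cn, NA_real_)
  lrr_ideal <- ifelse(cn > 0, log2(cn / 2), NA_real_)
  baf <- pmin(1, pmax(0, baf_ideal + rnorm(n, 0, noise$baf_sd)))
  lrr <- lrr_ideal + rnorm(n, 0, noise$lrr_sd)

  # WGA allele dropout operates on the present allele copies before calling
  kept <- present & matrix(runif(n * length(copies)) >= noise$ado_rate,
                           nrow = n)
  has_a <- rowSums(kept & !is_b) > 0L
  has_b <- rowSums(kept & is_b) > 0L
  gt <- rep("NC", n)
  gt[has_a & !has_b] <- "AA"
  gt[has_a & has_b] <- "AB"
  gt[!has_a & has_b] <- "BB"
  mis <- gt != "NC" & runif(n) < noise$miscall_rate
  if (any(mis)) {
    alt <- vapply(gt[mis], function(g)
      sample(setdiff(c("AA", "AB", "BB"), g), 1), character(1))
    gt[mis] <- alt
  }
  gt[runif(n) < noise$nocall_rate] <- "NC"

  arr <- sample_array(embryo_id, "embryo", data.frame(
    snp_id = panel$snp_id, chromosome = panel$chromosome,
    position = panel$position, gtype = gt, baf = baf, lrr = lrr,
    stringsAsFactors = FALSE))

  # chr16 copy bookkeeping for the truth record
  locus_i <- which(panel$chromosome == config$locus$chrom &
                     panel$position >= config$locus$start &
                     panel$position <= config$locus$end)[1]
  if (is.na(locus_i)) {
    nearest <- which(panel$chromosome == config$locus$chrom)
    locus_i <- nearest[which.min(abs(panel$position[nearest] -
                                       config$locus$start))]
  }
  chr16_copies <- lapply(copies, function(cp) {
    p <- cp$active; if (is.null(p)) p <- rep(TRUE, n)
    if (!p[locus_i]) return(NULL)
    list(parent = cp$parent,
         risk = cp$source[locus_i] == cp$risk_index)
  })
  chr16_copies <- Filter(Negate(is.null), chr16_copies)
  risks <- vapply(chr16_copies, `[[`, logical(1), "risk")
  true_genotype <- paste(
    c(rep(ALLELE_DEL, sum(risks)), rep(ALLELE_NORM, sum(!risks))),
    collapse = "/")
  truth <- structure(list(
    embryo_id = embryo_id, paternal_meiosis = pat_mei,
    maternal_meiosis = mat_mei, aneuploidy = aneuploidy,
    chr16_copies = chr16_copies, true_genotype = true_genotype,
    inherited_risk = c(
      father = sum(risks[vapply(chr16_copies, `[[`, character(1), "parent") == "father"]),
      mother = sum(risks[vapply(chr16_copies, `[[`, character(1), "parent") == "mother"]))
  ), class = "embryo_truth")
  list(array = arr, truth = truth)
}

# Restrict (drop = TRUE) or confine (drop = FALSE) a copy to a chromosome's
# SNP indices via an activity mask.
mask_copy <- function(cp, idx, drop) {
  n <- length(cp$alleles)
  act <- cp$active
  if (is.null(act)) act <- rep(TRUE, n)
  if (drop) act[idx] <- FALSE else act[setdiff(seq_len(n), idx)] <- FALSE
  cp$active <- act
  cp
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat(sprintf("<embryo_truth> %s: %s", x$embryo_id, x$true_genotype))
  if (x$aneuploidy$kind != "none")
    cat(sprintf(" [%s chr%s %s%s]", x$aneuploidy$kind,
                x$aneuploidy$chromosome, x$aneuploidy$origin,
                if (!is.na(x$aneuploidy$stage))
                  paste0(" ", x$aneuploidy$stage) else ""))
  cat("\n")
  invisible(x)
}

#' Simulate the fluorescent Gap-PCR of an embryo biopsy
#'
#' Each intact (normal) chromosome-16 copy yields a 280-bp FAM product and
#' each SEA-deletion copy a 178-bp HEX product; every product is dropped
#' independently with the PCR allele-dropout probability. Peak heights are
#' log-normal.
#'
#' @param truth an `embryo_truth`
#' @param noise a [noise_model()] (uses `pcr_ado_rate`)
#' @param seed optional integer seed
#' @return data.frame of peaks (`sample`, `size_bp`, `dye`, `height`),
#'   possibly empty
#' @export
simulate_gap_pcr <- function(truth, noise = noise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  risks <- vapply(truth$chr16_copies, `[[`, logical(1), "risk")
  kept <- risks[runif(length(risks)) >= noise$pcr_ado_rate]
  n <- length(kept)
  if (n == 0L)
    return(data.frame(sample = character(), size_bp = integer(),
                      dye = character(), height = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(sample = truth$embryo_id,
             size_bp = ifelse(kept, 178L, 280L),
             dye = ifelse(kept, "HEX", "FAM"),
             height = round(rlnorm(n, log(2000), 0.3)),
             stringsAsFactors = FALSE)
}

# Deterministic per-embryo substream seed below 2^31.
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629
}

#' Simulate a whole carrier x carrier family
#'
#' Generates phased parents and `n_embryos` embryo biopsies (arrays, ground
#' truth, Gap-PCR peaks). Aneuploidy events can be supplied per embryo or
#' drawn with probability `aneuploidy_rate` (uniform over chr16-biased event
#' types, see `aneuploidy_chrom_weights`).
#'
#' @param config a [family_config()]
#' @param panel a [snp_panel()]
#' @param n_embryos number of embryos
#' @param noise a [noise_model()]
#' @param aneuploidy either a list of [aneuploidy_spec()] (length
#'   `n_embryos`) or NULL to draw events with `aneuploidy_rate`
#' @param aneuploidy_rate probability an embryo carries a whole-chromosome
#'   event when `aneuploidy` is NULL
#' @param chr16_weight probability an aneuploid embryo's event hits the locus
#'   chromosome (the clinically interfering case) rather than a random other
#'   autosome
#' @param maf B-allele frequency for parental haplotypes
#' @param seed integer seed driving every random draw (per-embryo substreams)
#' @return list: `config`, `panel`, `father`, `mother` (phased),
#'   `father_array`, `mother_array`, `embryos` (list of
#'   `list(array, truth, peaks)`)
#' @export
simulate_family <- function(config = family_config(),
                            panel = default_panel(config),
                            n_embryos = 8, noise = noise_model(),
                            aneuploidy = NULL, aneuploidy_rate = 0,
                            chr16_weight = 0.5, maf = 0.5, seed = 1) {
  parents <- simulate_parents(panel, config, maf = maf, seed = seed)
  rmap <- default_recomb_map(config)
  ids <- sprintf("E%02d", seq_len(n_embryos))
  embryos <- vector("list", n_embryos)
  chroms <- intersect(unique(panel$chromosome), AUTOSOMES)
  for (i in seq_len(n_embryos)) {
    es <- substream_seed(seed, i)
    set.seed(es)
    spec <- if (!is.null(aneuploidy))
      aneuploidy[[i]] %||% aneuploidy_spec()
    else if (runif(1) < aneuploidy_rate) {
      chrom <- if (runif(1) < chr16_weight) config$locus$chrom
      else sample(setdiff(chroms, config$locus$chrom), 1)
      kind <- sample(c("trisomy", "monosomy"), 1)
      origin <- sample(c("father", "mother"), 1)
      stage <- if (kind == "trisomy") sample(c("MI", "MII"), 1) else NA
      aneuploidy_spec(kind, chrom, origin, stage)
    } else aneuploidy_spec()
    sim <- simulate_embryo(parents, config, spec, noise, embryo_id = ids[i],
                           recomb_map = rmap)
    sim$peaks <- simulate_gap_pcr(sim$truth, noise)
    embryos[[i]] <- sim
  }
  cfg <- config; cfg$embryo_ids <- ids
  list(config = cfg, panel = panel, father = parents$father,
       mother = parents$mother,
       father_array = parent_array(parents$father),
       mother_array = parent_array(parents$mother),
       embryos = setNames(embryos, ids))
}

#' Retest and rebiopsy providers backed by the simulator
#'
#' In the clinical workflow a discordant embryo's amplified sample can be
#' re-run through the Gap-PCR (retest) or the embryo re-biopsied and
#' re-amplified (rebiopsy). For simulated families both are new measurements
#' of the same underlying embryo: fresh PCR dropout draws from the retained
#' ground truth.
#'
#' @param fam a family from [simulate_family()]
#' @param noise a [noise_model()]
#' @param seed integer seed for the provider draws
#' @return list with `retest` and `rebiopsy` functions of `embryo_id`
#' @export
simulation_providers <- function(fam, noise = noise_model(), seed = 1) {
  counter <- new.env(parent = emptyenv())
  draw <- function(embryo_id, tag) {
    n <- (get0(embryo_id, counter) %||% 0L) + 1L
    assign(embryo_id, n, counter)
    i <- match(embryo_id, names(fam$embryos))
    substream_seed(seed + 1e6 * n, i)
  }
  retest <- function(embryo_id) {
    truth <- fam$embryos[[embryo_id]]$truth
    call_pcr_genotype(simulate_gap_pcr(truth, noise,
                                       seed = draw(embryo_id, "retest")))
  }
  rebiopsy <- function(embryo_id) {
    truth <- fam$embryos[[embryo_id]]$truth
    s <- draw(embryo_id, "rebiopsy")
    list(pcr = call_pcr_genotype(simulate_gap_pcr(truth, noise, seed = s)),
         call_rate = 0.97)
  }
  list(retest = retest, rebiopsy = rebiopsy)
}
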