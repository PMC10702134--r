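#' Family configuration
#'
#' Describes one carrier x carrier family: pedigree sample ids, the HBA1+HBA2
#' locus interval, the flank size used for informative-SNP selection, and the
#' deletion interval rendered by the simulator. All coordinates are 1-based
#' inclusive on GRCh37. The default locus is the printed HBA1+HBA2 interval
#' 16:222846-227521; the true SEA breakpoints are not modelled and the
#' deletion interval defaults to the locus itself (configurable).
#'
#' @param family_id family identifier
#' @param father_id,mother_id parental sample ids
#' @param embryo_ids ordered character vector of embryo sample ids
#' @param locus list with `chrom`, `start`, `end` (defaults to the HBA locus)
#' @param flank_bp flank size in base pairs on each side of the locus
#' @param deletion list with `start`, `end` on the locus chromosome; must
#'   contain the locus interval. Default: the locus interval.
#' @param genome_build assembly label (display only)
#' @return object of class `family_config`
#' @export
family_config <- function(family_id = "FAM1",
                          father_id = "father",
                          mother_id = "mother",
                          embryo_ids = character(),
                          locus = list(chrom = "16", start = 222846L,
                                       end = 227521L),
                          flank_bp = 2e6,
                          deletion = NULL,
                          genome_build = "GRCh37") {
  locus$chrom <- check_chromosome(locus$chrom)
  locus$start <- as.integer(locus$start); locus$end <- as.integer(locus$end)
  if (locus$start >= locus$end) stop("locus start must be < end")
  if (flank_bp <= 0) stop("flank_bp must be > 0")
  if (is.null(deletion)) deletion <- list(start = locus$start, end = locus$end)
  deletion$start <- as.integer(deletion$start)
  deletion$end <- as.integer(deletion$end)
  if (deletion$start > locus$start || deletion$end < locus$end)
    stop("deletion interval must contain the locus interval")
  structure(list(family_id = family_id, father_id = father_id,
                 mother_id = mother_id,
                 embryo_ids = as.character(embryo_ids),
                 locus = locus, flank_bp = as.numeric(flank_bp),
                 deletion = deletion, genome_build = genome_build),
            class = "family_config")
}

#' @export
print.family_config <- function(x, ...) {
  cat("Family", x$family_id, "(", x$genome_build, ")\n")
  cat("  father:", x$father_id, " mother:", x$mother_id,
      " embryos:", length(x$embryo_ids), "\n")
  cat(sprintf("  locus chr%s:%d-%d, flank %s bp\n", x$locus$chrom,
              x$locus$start, x$locus$end, format(x$flank_bp, big.mark = ",")))
  invisible(x)
}

#' Read a family configuration from YAML or JSON
#'
#' Keys: `family_id`, `father`, `mother`, `embryos`, `locus`
#' (`chrom`/`start`/`end`), `flank_bp`, `deletion` (`start`/`end`), `build`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return a [family_config()] object
#' @export
read_family_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  family_config(
    family_id = raw$family_id %||% "FAM1",
    father_id = raw$father %||% "father",
    mother_id = raw$mother %||% "mother",
    embryo_ids = unlist(raw$embryos %||% character()),
    locus = if (!is.null(raw$locus)) raw$locus
            else list(chrom = "16", start = 222846L, end = 227521L),
    flank_bp = raw$flank_bp %||% 2e6,
    deletion = raw$deletion,
    genome_build = raw$build %||% "GRCh37"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition the flanked locus region into 5' flank, gene, 3' flank
#'
#' The upstream 5' flank is the telomere side (lower coordinates; HBA sits at
#' the tip of 16p so this flank is clipped at position 1), the downstream 3'
#' flank the centromere side. Intervals are 1-based closed; an interval with
#' `start > end` is empty.
#'
#' @param config a [family_config()]
#' @return list of class `region_partition` with elements `upstream_5p`,
#'   `in_gene`, `downstream_3p`, each `c(start, end)`, plus `chrom`
#' @export
partition_region <- function(config) {
  s <- config$locus$start; e <- config$locus$end; f <- config$flank_bp
  structure(list(
    chrom = config$locus$chrom,
    upstream_5p = c(max(1, s - f), s - 1),
    in_gene = c(s, e),
    downstream_3p = c(e + 1, e + f)
  ), class = "region_partition")
}

#' Tag positions with the flank they fall in
#' @param positions integer positions on the partition chromosome
#' @param part a `region_partition`
#' @return character vector: "upstream_5p", "in_gene", "downstream_3p" or NA
#' @keywords internal
flank_of <- function(positions, part) {
  out <- rep(NA_character_, length(positions))
  inside <- function(iv) positions >= iv[1] & positions <= iv[2]
  out[inside(part$upstream_5p)] <- "upstream_5p"
  out[inside(part$in_gene)] <- "in_gene"
  out[inside(part$downstream_3p)] <- "downstream_3p"
  out
}
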