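# Readers/writers for the GenomeStudio-final-report-like TSV dialect and for
# fluorescent Gap-PCR peak CSV files.

#' Default SNP-table column mapping (GenomeStudio Final Report names)
#' @return named character vector mapping internal field -> file column
#' @export
snp_table_columns <- function() {
  c(sample_id = "Sample ID", snp_id = "SNP Name", chromosome = "Chr",
    position = "Position", gtype = "GType", baf = "B Allele Freq",
    lrr = "Log R Ratio")
}

#' Read a SNP-array genotype table
#'
#' Parses a tab-separated table with one row per SNP per sample (GenomeStudio
#' final-report dialect by default; remappable column names) into one
#' [sample_array()] per distinct sample. Unparseable BAF/LRR values become
#' missing, never errors. Genotype strings other than AA/AB/BB are read as NC.
#'
#' @param path TSV file path
#' @param panel optional [snp_panel()]; when given, records are validated
#'   against it (unknown SNPs error) and ordered by it
#' @param columns column mapping as from [snp_table_columns()]
#' @param roles optional named character vector sample_id -> role; samples not
#'   named default to "embryo"
#' @return named list of [sample_array()] objects
#' @export
read_snp_table <- function(path, panel = NULL, columns = snp_table_columns(),
                           roles = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss))
    stop("SNP table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df <- data.frame(
    sample_id = raw[[columns[["sample_id"]]]],
    snp_id = raw[[columns[["snp_id"]]]],
    chromosome = as.character(raw[[columns[["chromosome"]]]]),
    position = suppressWarnings(as.integer(raw[[columns[["position"]]]])),
    gtype = raw[[columns[["gtype"]]]],
    baf = suppressWarnings(as.numeric(raw[[columns[["baf"]]]])),
    lrr = suppressWarnings(as.numeric(raw[[columns[["lrr"]]]])),
    stringsAsFactors = FALSE)
  df$gtype[!(df$gtype %in% c("AA", "AB", "BB"))] <- "NC"
  df$baf[!is.na(df$baf) & (df$baf < 0 | df$baf > 1)] <- NA_real_
  key <- paste(df$sample_id, df$snp_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("sample_id", "snp_id")][1, ]
    stop(sprintf("duplicate row for sample '%s', SNP '%s'",
                 dup$sample_id, dup$snp_id))
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$snp_id), panel$snp_id)
    if (length(unknown))
      stop("SNP(s) not in panel: ", paste(head(unknown, 5), collapse = ", "))
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    sid <- d$sample_id[1]
    role <- if (!is.null(roles) && sid %in% names(roles)) roles[[sid]] else "embryo"
    sample_array(sid, role, d[, c("snp_id", "chromosome", "position",
                                  "gtype", "baf", "lrr")])
  })
  out[unique(df$sample_id)]
}

#' Write sample arrays as a SNP-array genotype table
#'
#' Inverse of [read_snp_table()]: genotypes round-trip exactly, BAF/LRR to six
#' decimals. All samples must share one panel (same SNP set).
#'
#' @param samples list of [sample_array()] objects
#' @param path output TSV path
#' @param columns column mapping as from [snp_table_columns()]
#' @return `path`, invisibly
#' @export
write_snp_table <- function(samples, path, columns = snp_table_columns()) {
  if (length(samples)) {
    ref <- samples[[1]]$records$snp_id
    same <- vapply(samples, function(s) identical(s$records$snp_id, ref),
                   logical(1))
    if (!all(same)) stop("samples do not share one panel")
  }
  rows <- lapply(samples, function(s) {
    d <- s$records
    data.frame(a = s$sample_id, b = d$snp_id, c = d$chromosome,
               d = d$position, e = d$gtype,
               f = ifelse(is.na(d$baf), "", sprintf("%.6f", d$baf)),
               g = ifelse(is.na(d$lrr), "", sprintf("%.6f", d$lrr)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), c = character(),
               d = integer(), e = character(), f = character(),
               g = character(), stringsAsFactors = FALSE)
  names(out) <- unname(columns[c("sample_id", "snp_id", "chromosome",
                                 "position", "gtype", "baf", "lrr")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fluorescent Gap-PCR peaks
#'
#' CSV with columns `sample`, `size_bp`, `dye`, `height`; `dye` may be empty.
#'
#' @param path CSV path
#' @return data.frame of peaks (all samples)
#' @export
read_pcr_peaks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "size_bp", "height")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$dye)) df$dye <- NA_character_
  if (any(df$size_bp <= 0)) stop("peak sizes must be positive")
  if (any(df$height <= 0)) stop("peak heights must be positive")
  df[, c("sample", "size_bp", "dye", "height")]
}

#' Write fluorescent Gap-PCR peaks
#' @param peaks data.frame as returned by [read_pcr_peaks()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_pcr_peaks <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
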