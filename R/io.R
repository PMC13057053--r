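#' Read a genetic map from CSV
#'
#' Expects a header `chrom,marker,pos_cM`. Markers are sorted by position
#' within chromosome; duplicate marker names and negative or non-numeric
#' positions are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @return A `"genetic_map"`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chrom", "marker", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map CSV must have header chrom,marker,pos_cM")
  pos <- suppressWarnings(as.numeric(df$pos_cM))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad))
    stop("invalid position at data line ", bad[1], " of ", path)
  dup <- df$marker[duplicated(df$marker)]
  if (length(dup)) stop("duplicate marker name: ", dup[1])
  genetic_map(df$chrom, df$marker, pos)
}

#' Read a DH genotype matrix from CSV
#'
#' First column: line id; remaining columns: marker names with cells in
#' `{A, B, NA}` mapped to `{+1, -1, missing}` (A = first-parent allele).
#' Heterozygote codes are rejected: doubled haploids are fully homozygous.
#' Columns absent from the map are dropped with a warning; columns are
#' returned in map order.
#'
#' @param path CSV file path.
#' @param map A `"genetic_map"` used to order/validate the marker columns.
#' @return Lines x markers matrix of +1/-1/NA.
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  g <- as.matrix(df[-1])
  codes <- unique(stats::na.omit(as.vector(g)))
  bad <- setdiff(codes, c("A", "B"))
  if (length(bad))
    stop("genotype code '", bad[1], "' is not allowed: a DH population ",
         "carries only homozygous parental alleles (A or B)")
  num <- matrix(NA_real_, nrow(g), ncol(g), dimnames = list(ids, colnames(g)))
  num[g == "A"] <- 1
  num[g == "B"] <- -1
  unknown <- setdiff(colnames(num), map$marker)
  if (length(unknown)) {
    warning("dropping marker(s) not in map: ", paste(unknown, collapse = ", "))
    num <- num[, setdiff(colnames(num), unknown), drop = FALSE]
  }
  num[, intersect(map$marker, colnames(num)), drop = FALSE]
}

#' Read germination and seedling CSV tables
#'
#' Germination: header `genotype,treatment,replicate,total_seeds,d1..d12`;
#' seedling: header `genotype,treatment,replicate,fw_g,sl_cm,rl_cm,rno`.
#' `NA` is the only missing-value token.
#'
#' @param path CSV file path.
#' @return Data frame ready for [assemble_trait_table()].
#' @export
read_germination_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "treatment", "replicate", "total_seeds")
  if (!all(need %in% names(df)))
    stop("germination CSV must start with header ", paste(need, collapse = ","))
  df
}

#' @rdname read_germination_csv
#' @export
read_seedling_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "treatment", "replicate", "fw_g", "sl_cm", "rl_cm", "rno")
  if (!all(need %in% names(df)))
    stop("seedling CSV must have header ", paste(need, collapse = ","))
  df
}

#' Write / read the trait table
#'
#' Genotypes as rows, trait abbreviations as columns, `NA` for missing.
#' @param traits A `"trait_table"`.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "directions") <- trait_directions(setdiff(names(df), "genotype"))
  class(df) <- c("trait_table", "data.frame")
  df
}

QTL_REPORT_COLS <- c("qtl", "trait", "chrom", "pos", "left_marker",
                     "right_marker", "lod", "pve", "add", "ci_left",
                     "ci_right", "environment")

#' Write a QTL report TSV
#'
#' Fixed column order `qtl trait chrom pos left_marker right_marker lod pve
#' add ci_left ci_right environment`; numeric columns at 2 decimals in the
#' report view and a parallel `<path>.full.tsv` at full precision.
#'
#' @param calls A `"qtl_calls"` data frame.
#' @param path Output TSV path.
#' @param full Also write the full-precision companion file (default TRUE).
#' @export
write_qtl_report <- function(calls, path, full = TRUE) {
  df <- as.data.frame(calls)[intersect(QTL_REPORT_COLS, names(calls))]
  if (full)
    utils::write.table(df, paste0(sub("\\.tsv$", "", path), ".full.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a QTL report TSV
#'
#' Parses a QTL record table in the layout written by [write_qtl_report()].
#' The `strength` classification is (re)derived from the PVE column with
#' [classify_qtl()].
#'
#' @param path TSV file path.
#' @return A `"qtl_calls"` data frame.
#' @export
read_qtl_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(QTL_REPORT_COLS, names(df))
  if (length(miss))
    stop("QTL report missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("pos", "lod", "pve", "add", "ci_left", "ci_right"))
    df[[cc]] <- as.numeric(df[[cc]])
  df$chrom <- as.character(df$chrom)
  df$strength <- classify_qtl(df$pve)
  class(df) <- c("qtl_calls", "data.frame")
  df
}

#' Write a map summary TSV
#'
#' Layout: one row per chromosome, then the genome-group rollups and the
#' total row; densities displayed at 2 decimals.
#'
#' @param summary Output of [map_summary()].
#' @param path Output TSV path.
#' @export
write_map_summary <- function(summary, path) {
  df <- summary
  df$length_cM <- sprintf("%.2f", df$length_cM)
  df$density <- sprintf("%.2f", df$density)
  df$density_ratio <- sprintf("%.2f", df$density_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scan result TSV
#' @param scan A `"qtl_scan"`.
#' @param path Output TSV path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Bundled QTL records for a wheat DH drought study
#'
#' Twelve QTL records for germination and seedling-establishment traits
#' detected by single-marker analysis in a wheat DH population under
#' control/drought x unprimed/nano-primed treatments, shipped as a
#' plain-text report for examples and for exercising the report
#' bookkeeping.
#'
#' @return A `"qtl_calls"` data frame (12 records).
#' @examples
#' q <- dh_qtl_records()
#' table(q$chrom)
#' @export
dh_qtl_records <- function() {
  read_qtl_report(system.file("extdata", "dh_qtl_records.tsv",
                              package = "seedqtl", mustWork = TRUE))
}
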