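#' Build a per-SNP (or per-window) score table
#'
#' Standard container for scan statistics (FST, LSBL, IHS, XPCLR).
#' Ranks are ascending over the finite values (ties broken by input
#' order so ranks stay unique); percentiles are `100 * rank / n_finite`.
#' Non-finite values keep `NA` rank and percentile and are excluded from
#' the empirical distribution.
#'
#' @param unit_id SNP or window identifier.
#' @param chrom chromosome label per unit.
#' @param pos bp position (window midpoint for windowed statistics).
#' @param statistic single statistic name (`"FST"`, `"LSBL"`, `"IHS"`,
#'   `"XPCLR"`, ...).
#' @param value statistic values; `NA`/non-finite allowed.
#' @return A data frame of class `score_table` with columns `unit_id`,
#'   `chrom`, `pos`, `statistic`, `value`, `rank`, `percentile`, sorted
#'   by (chrom, pos).
#' @export
score_table <- function(unit_id, chrom, pos, statistic, value) {
  if (length(statistic) != 1) stop("one statistic per table")
  df <- data.frame(unit_id = as.character(unit_id),
                   chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   statistic = statistic,
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  fin <- is.finite(df$value)
  df$rank <- NA_integer_
  df$rank[fin] <- rank(df$value[fin], ties.method = "first")
  df$percentile <- 100 * df$rank / sum(fin)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Write a score table to TSV
#'
#' Tab-separated with header, rows ordered by (chrom, pos); full
#' precision is preserved so that a write/read round trip is exact.
#'
#' @param table a `score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  if (!inherits(table, "score_table")) stop("not a score_table")
  if (nrow(table) == 0) stop("refusing to write an empty score table")
  df <- as.data.frame(table)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  df$value <- sprintf("%.17g", df$value)
  df$percentile <- sprintf("%.17g", df$percentile)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path TSV path.
#' @return A `score_table`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(unit_id = "character",
                                         chrom = "character"))
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read gene annotation from a BED file
#'
#' BED is 0-based half-open; intervals are converted on read to 1-based
#' inclusive coordinates, the convention used throughout the package.
#'
#' @param path BED file (first four columns chrom, start, end, name).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED gene file needs chrom/start/end/name")
  genes <- data.frame(gene_id = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]) + 1L,
                      end = as.integer(tab[[3]]),
                      stringsAsFactors = FALSE)
  if (any(genes$start > genes$end)) stop("malformed BED interval")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids")
  genes
}

#' Read a GMT-style gene-set file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of sets; each element is a character vector of
#'   gene ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with no members: ", parts[1])
    members <- unique(parts[-(1:2)])
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' Read a per-sample phenotype/covariate table
#'
#' Expects tab-separated columns `sample`, `hemoglobin_gdl`, `age`,
#' `altitude_m`, `population`.
#'
#' @param path TSV path.
#' @return Data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "hemoglobin_gdl", "age", "altitude_m", "population")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicated sample ids")
  if (any(df$hemoglobin_gdl <= 0)) stop("hemoglobin must be positive")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table to TSV
#' @param pheno a `phenotype_table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an outgroup allele table
#'
#' Tab-separated columns `snp_id` followed by one column per outgroup
#' species (e.g. chimp, orang, macaque); missing alleles are `.` or `NA`.
#'
#' @param path TSV path.
#' @return Data frame with `snp_id` plus outgroup columns.
#' @export
read_outgroup_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  if (names(df)[1] != "snp_id") stop("first column must be snp_id")
  df
}
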