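# Plain-text readers/writers for the formats the package exchanges:
# GCTA-style summary statistics, square LD matrices, case-report CSVs and
# result tables. All files are tab-delimited UTF-8 unless noted.

#' Read summary statistics (SNP/CHR/BP/A1/A2/EAF/BETA/SE/P/N)
#'
#' Tab-delimited with header `SNP CHR BP A1 A2 EAF BETA SE P N`; `A1` is
#' the effect allele. Empty fields are missing. The column set matches the
#' GCTA-COJO `.ma` format extended with chromosome and position.
#'
#' @param path file path.
#' @return validated summary-statistics data.frame (see [assoc_records()]).
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  expected <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P", "N")
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols)) {
    stop("summary-statistics file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  assoc_records(data.frame(
    snp_id = df$SNP, chrom = df$CHR, pos_bp = df$BP,
    effect_allele = df$A1, other_allele = df$A2,
    eaf = df$EAF, beta = df$BETA, se = df$SE, pval = df$P, n = df$N,
    stringsAsFactors = FALSE
  ))
}

#' Write summary statistics in the format [read_summary_stats()] reads
#'
#' @param assoc summary-statistics data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(assoc, path) {
  assoc <- assoc_records(assoc)
  out <- data.frame(
    SNP = assoc$snp_id, CHR = assoc$chrom, BP = assoc$pos_bp,
    A1 = assoc$effect_allele, A2 = assoc$other_allele,
    EAF = assoc$eaf, BETA = assoc$beta, SE = assoc$se, P = assoc$pval,
    N = assoc$n, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a square LD correlation matrix
#'
#' Tab-delimited square matrix with SNP ids as the first row and first
#' column.
#'
#' @param path file path.
#' @return correlation matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square")
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column SNP ids disagree")
  }
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric")
  m
}

#' Write a square LD correlation matrix
#'
#' @param ld correlation matrix with SNP-id dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read case reports from CSV
#'
#' Comma-separated with header `case_id,version,drug,role,pt,sex,
#' age_years,weight_kg,reporter,country,year`; empty fields are missing.
#'
#' @param path file path.
#' @return validated case-report data.frame (see [case_reports()]).
#' @export
read_case_reports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  case_reports(df)
}

#' Write case reports to CSV
#'
#' @param reports case-report data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case_reports <- function(reports, path) {
  reports <- case_reports(reports)
  utils::write.csv(reports, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write ROR signal results as TSV
#'
#' One row per signal: label, the four cells, ROR, CI bounds and verdict.
#'
#' @param signals a `signal_result` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_results <- function(signals, path) {
  if (inherits(signals, "signal_result")) signals <- list(signals)
  rows <- do.call(rbind, lapply(signals, function(s) {
    data.frame(label = s$label, a = s$a, b = s$b, c = s$c, d = s$d,
               ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
               is_signal = s$is_signal, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
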