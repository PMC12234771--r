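#' Round half away from zero
#'
#' Base `round()` rounds half to even; published percentage tables in this
#' field round half up, so all reported reals go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage share, rounded half-up to two decimals
#'
#' @param part,whole Non-negative counts with `0 <= part <= whole`.
#' @return `100 * part / whole` rounded half-up to 2 decimals; `NA` when
#'   `whole` is zero (undefined share).
#' @export
percent_share <- function(part, whole) {
  stopifnot(length(part) == length(whole))
  if (any(part < 0 | whole < 0, na.rm = TRUE)) {
    stop("percent_share: counts must be non-negative")
  }
  if (any(part > whole, na.rm = TRUE)) {
    stop("percent_share: part must not exceed whole")
  }
  out <- ifelse(whole == 0, NA_real_, round_half_up(100 * part / whole, 2))
  out
}

# Write a TSV with a commented header line describing the table.
write_tsv_commented <- function(df, path, comment) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Comma-joined carrier sets <-> character vectors, kept in a fixed order.
join_strains <- function(x) paste(x, collapse = ",")
split_strains <- function(x) strsplit(x, ",", fixed = TRUE)
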