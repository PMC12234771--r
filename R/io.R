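# Reading/writing alignments and strain metadata, consensus building, and
# CDS extraction from alignment rows.

#' Construct a strain table
#'
#' A strain table maps each strain to one of exactly two lineage labels and
#' fixes the display/merge order used throughout the pipeline.
#'
#' @param strain_id Character vector of unique strain identifiers.
#' @param lineage Character vector of lineage labels; exactly two distinct
#'   values must be present, each with at least one strain.
#' @param ord Optional integer display order (defaults to input order).
#' @return A `data.frame` of class `strain_table` with columns
#'   `strain_id`, `lineage`, `ord`.
#' @export
strain_table <- function(strain_id, lineage, ord = seq_along(strain_id)) {
  strain_id <- as.character(strain_id)
  lineage <- as.character(lineage)
  if (length(strain_id) < 2L) stop("strain_table: need at least two strains")
  if (anyDuplicated(strain_id)) stop("strain_table: strain ids must be unique")
  if (length(unique(lineage)) != 2L) {
    stop("strain_table: exactly two lineage labels required, got ",
         length(unique(lineage)))
  }
  df <- data.frame(strain_id = strain_id, lineage = lineage,
                   ord = as.integer(ord), stringsAsFactors = FALSE)
  df <- df[order(df$ord), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("strain_table", "data.frame")
  df
}

#' Read a strain table from TSV
#'
#' @param path Two- or three-column TSV (`strain_id`, `lineage`, optional
#'   `ord`); lines starting with `#` are ignored.
#' @return A [strain_table()].
#' @export
read_strain_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("strain_id", "lineage") %in% names(df))) {
    stop("strain table must have columns 'strain_id' and 'lineage'")
  }
  ord <- if ("ord" %in% names(df)) df$ord else seq_len(nrow(df))
  strain_table(df$strain_id, df$lineage, ord)
}

#' Write a strain table to TSV
#' @param strains A [strain_table()].
#' @param path Output file.
#' @export
write_strain_table <- function(strains, path) {
  write_tsv_commented(as.data.frame(strains)[, c("strain_id", "lineage", "ord")],
                      path, "camscan strain table: strain_id, lineage, ord")
}

#' Lineage labels of a strain table, in display order
#' @param strains A [strain_table()].
#' @return Character vector of the two lineage labels.
#' @export
lineages <- function(strains) unique(strains$lineage)

#' Strains belonging to one lineage
#' @param strains A [strain_table()].
#' @param lineage One of the two lineage labels.
#' @return Character vector of strain ids.
#' @export
lineage_strains <- function(strains, lineage) {
  out <- strains$strain_id[strains$lineage == lineage]
  if (length(out) == 0L) stop("no strains in lineage '", lineage, "'")
  out
}

#' Construct a gene alignment
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the alphabet `A C G T N -`.
#' @return Object of class `gene_alignment` with fields `gene_id`, `seqs`,
#'   `length`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("gene_alignment: sequences must be named by strain")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment-shape error: rows of gene '", gene_id,
         "' have unequal lengths (", paste(unique(widths), collapse = ", "), ")")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("alphabet error: gene '", gene_id, "', strain(s) ",
         paste(names(seqs)[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N,-}")
  }
  structure(list(gene_id = gene_id, seqs = seqs, length = unname(widths[1])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment>", x$gene_id, "-", length(x$seqs), "strains x",
      x$length, "columns\n")
  invisible(x)
}

#' Read one gene's aligned FASTA
#'
#' @param path Aligned FASTA file (gap character `-`); every record header
#'   must be a known strain id when `strains` is supplied.
#' @param strains Optional [strain_table()] used to validate headers.
#' @param gene_id Gene identifier; default is the file name without extension.
#' @return A [gene_alignment()].
#' @export
read_alignment <- function(path, strains = NULL, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(fa|fasta|fna|aln)$", "", basename(path),
                   ignore.case = TRUE)
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(stats::setNames(as.character(ss), names(ss)))
  if (!is.null(strains)) {
    unknown <- setdiff(names(seqs), strains$strain_id)
    if (length(unknown) > 0L) {
      stop("metadata error: header(s) not in strain table: ",
           paste(unknown, collapse = ", "))
    }
  }
  gene_alignment(gene_id, seqs)
}

#' Write a gene alignment as aligned FASTA
#' @param aln A [gene_alignment()].
#' @param path Output FASTA path.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a directory of per-gene aligned FASTA files
#'
#' @param dir Directory containing one aligned FASTA per gene
#'   (`<gene_id>.fasta`).
#' @param strains Optional [strain_table()] for header validation.
#' @return Named list of [gene_alignment()] objects, sorted by gene id.
#' @export
read_panel <- function(dir, strains = NULL) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna|aln)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("input stage: no FASTA files found in '", dir, "'")
  alns <- lapply(sort(files), read_alignment, strains = strains)
  stats::setNames(alns, vapply(alns, `[[`, "", "gene_id"))
}

# Character matrix view of an alignment (rows = strains).
aln_matrix <- function(aln, strain_ids = names(aln$seqs)) {
  m <- matrix("", nrow = length(strain_ids), ncol = aln$length,
              dimnames = list(strain_ids, NULL))
  for (s in strain_ids) m[s, ] <- strsplit(aln$seqs[[s]], "", fixed = TRUE)[[1]]
  m
}

#' Majority-rule lineage consensus of an alignment
#'
#' Per column, the most frequent symbol among the selected lineage's rows;
#' the gap symbol votes like a base, so a lineage-wide deletion yields a
#' gapped reference. Ties are broken by the fixed symbol priority
#' `A < C < G < T < N < -`.
#'
#' @param aln A [gene_alignment()].
#' @param strains A [strain_table()].
#' @param lineage Lineage label whose rows are polled.
#' @return Aligned consensus sequence (single string, same length as `aln`).
#' @export
build_consensus <- function(aln, strains, lineage) {
  ids <- intersect(strains$strain_id[strains$lineage == lineage], names(aln$seqs))
  if (length(ids) == 0L) {
    stop("selection error: no strains of lineage '", lineage,
         "' present in alignment '", aln$gene_id, "'")
  }
  m <- aln_matrix(aln, ids)
  counts <- vapply(CONSENSUS_SYMBOLS,
                   function(sym) colSums(m == sym),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, CONSENSUS_SYMBOLS))
  # First index of the column maximum follows the declared symbol priority.
  pick <- max.col(counts, ties.method = "first")
  paste(CONSENSUS_SYMBOLS[pick], collapse = "")
}

#' Extract and validate a CDS from an alignment row
#'
#' Removes gaps, applies the eligibility rule for codon statistics (ungapped
#' length strictly greater than `min_len`), optionally sets aside the
#' terminal codon, and flags frame and internal-stop violations rather than
#' failing: ortholog panels routinely contain incomplete or pseudogenised
#' copies and the pipeline must carry them through with a warning.
#'
#' @param aln_row Aligned sequence (single string) or an ungapped CDS.
#' @param gene_id,strain_id Identifiers stored on the record.
#' @param min_len Eligibility threshold in nt (strictly greater-than).
#' @param drop_terminal If `TRUE`, the final codon is recorded separately and
#'   excluded from the codon-counting body.
#' @return Object of class `cds_record`: `gene_id`, `strain_id`, `seq`
#'   (ungapped), `length`, `eligible`, `frame_ok`, `terminal` (final codon or
#'   `NA`), `body` (sequence used for codon counting), `internal_stops`.
#' @export
degap_and_validate <- function(aln_row, gene_id = NA_character_,
                               strain_id = NA_character_,
                               min_len = 300L, drop_terminal = TRUE) {
  seq <- gsub("-", "", aln_row, fixed = TRUE)
  len <- nchar(seq)
  frame_ok <- len > 0L && len %% 3L == 0L
  if (!frame_ok && len > 0L) {
    warning("frame warning: gene '", gene_id, "', strain '", strain_id,
            "': ungapped length ", len, " is not a multiple of 3",
            call. = FALSE)
  }
  cods <- split_codons(seq)
  terminal <- NA_character_
  body <- seq
  if (drop_terminal && length(cods) >= 1L && frame_ok) {
    terminal <- cods[length(cods)]
    body <- substr(seq, 1L, len - 3L)
    cods <- cods[-length(cods)]
  }
  internal_stops <- sum(cods %in% STOP_CODONS)
  structure(list(gene_id = gene_id, strain_id = strain_id,
                 seq = seq, length = len,
                 eligible = len > min_len,
                 frame_ok = frame_ok,
                 terminal = terminal,
                 body = body,
                 internal_stops = internal_stops),
            class = "cds_record")
}
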