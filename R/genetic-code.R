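# Genetic code tables (bacterial/plastid code, translation table 11).
# The codon -> amino-acid map of table 11 is identical to the standard code;
# the tables differ only in permitted initiators, which is irrelevant for
# codon counting, so Biostrings' standard table is used directly.

CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

STOP_CODONS <- sort(names(CODON_AA)[CODON_AA == "*"])   # TAA TAG TGA
SENSE_CODONS <- sort(names(CODON_AA)[CODON_AA != "*"])  # 61 codons

# Synonymous families over the 61 sense codons, keyed by amino acid.
SYN_FAMILIES <- local({
  aa <- CODON_AA[SENSE_CODONS]
  split(names(aa), aa)
})

FAMILY_SIZE_BY_AA <- vapply(SYN_FAMILIES, length, integer(1))

# Per-codon family size (1, 2, 3, 4 or 6).
CODON_FAMILY_SIZE <- local({
  fs <- FAMILY_SIZE_BY_AA[CODON_AA[SENSE_CODONS]]
  stats::setNames(as.integer(fs), SENSE_CODONS)
})

# Met and Trp: single-codon families, excluded from RSCU preference,
# SVC and codon-aversion reporting (RSCU carries no information there).
SINGLETON_CODONS <- names(CODON_FAMILY_SIZE)[CODON_FAMILY_SIZE == 1L]
REPORTABLE_CODONS <- setdiff(SENSE_CODONS, SINGLETON_CODONS)

# The five four-fold degenerate families used for the default PR2 accumulation.
FOURFOLD_AAS <- names(FAMILY_SIZE_BY_AA)[FAMILY_SIZE_BY_AA == 4L]

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
DNA_BASES <- c("A", "C", "G", "T")

# Symbol priority used for consensus tie-breaking.
CONSENSUS_SYMBOLS <- c("A", "C", "G", "T", "N", "-")

#' Split an in-frame nucleotide sequence into codons
#'
#' @param seq Single character string; length need not be a multiple of
#'   three — trailing bases short of a full codon are dropped.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  substring(seq, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}

#' Translate codons under the bacterial genetic code
#'
#' @param codons Character vector of codons; codons containing characters
#'   outside A/C/G/T translate to `NA`.
#' @return Character vector of single-letter amino acids ("*" for stop).
#' @export
translate_codons <- function(codons) {
  unname(CODON_AA[codons])
}
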