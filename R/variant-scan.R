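# SNP and INDEL calling against a (consensus or ancestral) reference row,
# with the classification, identity and divergence statistics.

INDEL_CATEGORIES <- c("small_deletion", "small_insertion",
                      "large_deletion", "large_insertion")

#' Classify a substitution as transition or transversion
#'
#' @param ref,alt Distinct bases in `A C G T` (vectorised).
#' @return `"transition"` when both bases are purines or both pyrimidines,
#'   else `"transversion"`.
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (any(!(ref %in% DNA_BASES) | !(alt %in% DNA_BASES))) {
    stop("domain error: bases must be in {A,C,G,T}")
  }
  if (any(ref == alt)) stop("domain error: ref and alt must differ")
  ifelse((ref %in% PURINES) == (alt %in% PURINES), "transition", "transversion")
}

#' Call SNPs for strains against a reference row
#'
#' One record per (strain, column) where both the reference and the strain
#' carry an unambiguous base and they differ. Columns where either side is
#' a gap or N are skipped — gap runs belong to the INDEL caller.
#'
#' @param aln A [gene_alignment()].
#' @param reference Aligned reference sequence, same length as `aln`.
#' @param strains Strain ids to scan (default: all rows of `aln`).
#' @return `data.frame`: `gene_id`, `strain_id`, `column` (1-based), `ref`,
#'   `alt`, `class`.
#' @export
call_snps <- function(aln, reference, strains = names(aln$seqs)) {
  if (nchar(reference) != aln$length) {
    stop("alignment-shape error: reference length ", nchar(reference),
         " != alignment length ", aln$length)
  }
  r <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  ref_ok <- r %in% DNA_BASES
  out <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    s <- strsplit(aln$seqs[[strains[i]]], "", fixed = TRUE)[[1]]
    hit <- which(ref_ok & (s %in% DNA_BASES) & s != r)
    if (length(hit) == 0L) next
    out[[i]] <- data.frame(
      gene_id = aln$gene_id, strain_id = strains[i], column = hit,
      ref = r[hit], alt = s[hit],
      class = classify_substitution(r[hit], s[hit]),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), strain_id = character(0),
                      column = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Transition/transversion ratio of a SNP set
#'
#' @param snps SNP table from [call_snps()].
#' @return List: `transitions`, `transversions`, `ratio`
#'   (`Inf` when transversions are absent but transitions present; `NaN`
#'   when the set is empty), `defined`.
#' @export
tstv_ratio <- function(snps) {
  ts <- sum(snps$class == "transition")
  tv <- sum(snps$class == "transversion")
  ratio <- if (tv == 0L && ts == 0L) NaN else if (tv == 0L) Inf else ts / tv
  list(transitions = ts, transversions = tv, ratio = ratio,
       defined = is.finite(ratio))
}

# Maximal TRUE-runs of a logical vector as (start, length) pairs.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Call INDELs for strains against a reference row
#'
#' A maximal run of columns where the strain is gapped over reference bases
#' is a deletion; a maximal run where the reference is gapped under strain
#' bases is an insertion. Identical events (same start, length, polarity
#' and sequence) across strains merge into one record with the union
#' carrier set; events differing in any of those stay separate. Deletion
#' sequences are taken from the reference, insertion sequences from the
#' carrier strain.
#'
#' @inheritParams call_snps
#' @return `data.frame`: `gene_id`, `start` (1-based column), `length`,
#'   `polarity`, `size_class` (small iff length <= 40), `frame_preserving`
#'   (length divisible by 3), `sequence`, `carriers` (comma-joined, in
#'   scan order), `n_carriers`.
#' @export
call_indels <- function(aln, reference, strains = names(aln$seqs)) {
  if (nchar(reference) != aln$length) {
    stop("alignment-shape error: reference length ", nchar(reference),
         " != alignment length ", aln$length)
  }
  r <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  ref_base <- r != "-"
  recs <- list()
  for (st in strains) {
    s <- strsplit(aln$seqs[[st]], "", fixed = TRUE)[[1]]
    s_base <- s != "-"
    for (pol in c("deletion", "insertion")) {
      mask <- if (pol == "deletion") (!s_base) & ref_base else (!ref_base) & s_base
      runs <- logical_runs(mask)
      if (nrow(runs) == 0L) next
      for (k in seq_len(nrow(runs))) {
        span <- runs$start[k]:(runs$start[k] + runs$length[k] - 1L)
        seq <- paste(if (pol == "deletion") r[span] else s[span], collapse = "")
        recs[[length(recs) + 1L]] <- data.frame(
          gene_id = aln$gene_id, start = runs$start[k], length = runs$length[k],
          polarity = pol, sequence = seq, carrier = st,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0L) return(empty_indel_table())
  df <- do.call(rbind, recs)
  key <- paste(df$start, df$length, df$polarity, df$sequence, sep = "\r")
  merged <- lapply(split(df, key), function(grp) {
    carriers <- grp$carrier[order(match(grp$carrier, strains))]
    data.frame(gene_id = grp$gene_id[1], start = grp$start[1],
               length = grp$length[1], polarity = grp$polarity[1],
               size_class = ifelse(grp$length[1] <= 40L, "small", "large"),
               frame_preserving = grp$length[1] %% 3L == 0L,
               sequence = grp$sequence[1],
               carriers = join_strains(carriers),
               n_carriers = length(carriers), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$start, out$polarity, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_indel_table <- function() {
  data.frame(gene_id = character(0), start = integer(0), length = integer(0),
             polarity = character(0), size_class = character(0),
             frame_preserving = logical(0), sequence = character(0),
             carriers = character(0), n_carriers = integer(0),
             stringsAsFactors = FALSE)
}

indel_category <- function(records) {
  paste(records$size_class, records$polarity, sep = "_")
}

#' Per-category INDEL identity
#'
#' Fraction of a category's records whose carrier set contains every member
#' of the group — the "shared / total" identity statistic.
#'
#' @param records INDEL table from [call_indels()] (possibly several genes
#'   row-bound).
#' @param category One of `"small_deletion"`, `"small_insertion"`,
#'   `"large_deletion"`, `"large_insertion"`, or `NULL` for all records.
#' @param group Character vector of strain ids (>= 2).
#' @return Fraction in `[0, 1]`, or `NA` when the category is empty.
#' @export
indel_identity <- function(records, category = NULL, group) {
  if (length(group) < 2L) stop("group must contain at least two strains")
  if (!is.null(category)) {
    records <- records[indel_category(records) == category, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(NA_real_)
  shared <- vapply(split_strains(records$carriers),
                   function(cs) all(group %in% cs), TRUE)
  mean(shared)
}

#' Per-alignment INDEL divergence
#'
#' Summed INDEL lengths over the total alignment column count (gap columns
#' included in the denominator).
#'
#' @param aln The [gene_alignment()] the records belong to.
#' @param records INDEL records for that gene.
#' @param category Optional category filter as in [indel_identity()].
#' @return Fraction in `[0, 1]`.
#' @export
indel_divergence <- function(aln, records, category = NULL) {
  records <- records[records$gene_id == aln$gene_id, , drop = FALSE]
  if (!is.null(category)) {
    records <- records[indel_category(records) == category, , drop = FALSE]
  }
  sum(records$length) / aln$length
}

#' Summarise an INDEL record set
#'
#' Counts and half-up 2-decimal percentage shares per category, the
#' frame-preserving fraction, and — when alignments and a strain group are
#' supplied — per-category identity and per-gene divergence (mean and SD
#' over genes carrying at least one record of the category).
#'
#' @param records Row-bound INDEL tables from [call_indels()].
#' @param alignments Optional named list of [gene_alignment()]s for
#'   divergence.
#' @param group Optional strain group (>= 2 ids) for identity.
#' @return List of class `indel_summary`: `n_total`, `categories`
#'   (data.frame with `category`, `count`, `share_pct`, `identity`,
#'   `divergence_mean`, `divergence_sd`), `frame_preserving_fraction`.
#' @export
summarize_indels <- function(records, alignments = NULL, group = NULL) {
  cat <- factor(indel_category(records), levels = INDEL_CATEGORIES)
  counts <- as.integer(table(cat))
  n <- nrow(records)
  shares <- if (n > 0L) percent_share(counts, rep(n, 4L)) else rep(NA_real_, 4L)
  identity <- rep(NA_real_, 4L)
  div_mean <- rep(NA_real_, 4L)
  div_sd <- rep(NA_real_, 4L)
  if (!is.null(group)) {
    identity <- vapply(INDEL_CATEGORIES, function(cc)
      indel_identity(records, cc, group), numeric(1))
  }
  if (!is.null(alignments)) {
    for (i in seq_along(INDEL_CATEGORIES)) {
      cc <- INDEL_CATEGORIES[i]
      genes <- unique(records$gene_id[indel_category(records) == cc])
      if (length(genes) == 0L) next
      d <- vapply(genes, function(g)
        indel_divergence(alignments[[g]], records, cc), numeric(1))
      div_mean[i] <- mean(d)
      div_sd[i] <- if (length(d) > 1L) stats::sd(d) else 0
    }
  }
  structure(list(
    n_total = n,
    categories = data.frame(category = INDEL_CATEGORIES, count = counts,
                            share_pct = shares, identity = identity,
                            divergence_mean = div_mean, divergence_sd = div_sd,
                            stringsAsFactors = FALSE),
    frame_preserving_fraction = if (n > 0L) mean(records$frame_preserving)
                                else NA_real_),
    class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat("<indel_summary>", x$n_total, "records; frame-preserving fraction",
      format(x$frame_preserving_fraction, digits = 4), "\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}
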