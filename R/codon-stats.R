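# Codon-usage statistics: codon counting, RSCU, Wright's effective number
# of codons, PR2 third-position biases, significantly variable codons,
# stop-codon preference and the F-test-then-t-test group comparison.

#' Count codons of a validated CDS
#'
#' In-frame triplet counts over the record's counting body (terminal codon
#' set aside by [degap_and_validate()]); codons containing N are skipped.
#' Frame-flagged records are counted over `floor(len/3)` codons.
#'
#' @param cds A `cds_record` from [degap_and_validate()].
#' @return Object of class `codon_counts`: `gene_id`, `strain_id`, `counts`
#'   (named integer over the 64 codons), `terminal`, `eligible`,
#'   `n_codons`.
#' @export
count_codons <- function(cds) {
  cods <- split_codons(cds$body)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  counts <- stats::setNames(integer(length(CODON_AA)), names(CODON_AA))
  if (length(cods) > 0L) {
    tab <- table(factor(cods, levels = names(CODON_AA)))
    counts[] <- as.integer(tab)
  }
  structure(list(gene_id = cds$gene_id, strain_id = cds$strain_id,
                 counts = counts, terminal = cds$terminal,
                 eligible = cds$eligible, n_codons = sum(counts)),
            class = "codon_counts")
}

#' Pool codon counts across records
#'
#' Count-pooling (summing) is how group-level RSCU is computed for the SVC
#' comparison: it weights every codon occurrence equally and is robust to
#' short genes, unlike averaging per-strain RSCU values.
#'
#' @param counts_list List of `codon_counts`.
#' @return A pooled `codon_counts` (gene/strain ids joined with `+`).
#' @export
pool_counts <- function(counts_list) {
  counts <- Reduce(`+`, lapply(counts_list, `[[`, "counts"))
  structure(list(
    gene_id = paste(unique(vapply(counts_list, `[[`, "", "gene_id")),
                    collapse = "+"),
    strain_id = paste(unique(vapply(counts_list, `[[`, "", "strain_id")),
                      collapse = "+"),
    counts = counts, terminal = NA_character_,
    eligible = all(vapply(counts_list, `[[`, TRUE, "eligible")),
    n_codons = sum(counts)), class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = n_c * family_size / family_total`: the ratio of observed to
#' expected usage under uniform synonymous choice. A family with zero total
#' usage gets RSCU 0 for all members, flagged `absent`.
#'
#' @param counts A `codon_counts`.
#' @return `data.frame` over the 61 sense codons: `codon`, `aa`,
#'   `family_size`, `count`, `rscu`, `absent`.
#' @export
rscu <- function(counts) {
  n <- counts$counts[SENSE_CODONS]
  aa <- CODON_AA[SENSE_CODONS]
  fam_tot <- tapply(n, aa, sum)[aa]
  fs <- CODON_FAMILY_SIZE[SENSE_CODONS]
  val <- ifelse(fam_tot > 0, n * fs / fam_tot, 0)
  data.frame(codon = SENSE_CODONS, aa = unname(aa),
             family_size = unname(fs), count = unname(n),
             rscu = unname(val), absent = unname(fam_tot == 0),
             stringsAsFactors = FALSE)
}

#' Wright's effective number of codons
#'
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where each `F` is the mean codon
#' homozygosity `(n * sum(p^2) - 1) / (n - 1)` over the families of one
#' degeneracy class; families with `n <= 1` are excluded from their class
#' mean. A class with no estimable family (or a non-positive mean) is
#' imputed at its uniform expectation `1/k` and flagged. The result is
#' clipped to `[20, 61]`.
#'
#' @param counts A `codon_counts`.
#' @return List of class `enc_value`: `gene_id`, `strain_id`, `enc`,
#'   `fbar` (named F2/F3/F4/F6), `imputed` (class names), `defined`.
#' @export
enc <- function(counts) {
  n_by_aa <- tapply(counts$counts[SENSE_CODONS], CODON_AA[SENSE_CODONS], sum)
  class_sizes <- c("2" = 2L, "3" = 3L, "4" = 4L, "6" = 6L)
  fbar <- stats::setNames(rep(NA_real_, 4L), paste0("F", names(class_sizes)))
  imputed <- character(0)
  any_estimable <- FALSE
  for (ci in seq_along(class_sizes)) {
    k <- class_sizes[ci]
    fams <- names(FAMILY_SIZE_BY_AA)[FAMILY_SIZE_BY_AA == k]
    fvals <- numeric(0)
    for (aa in fams) {
      fam_codons <- SYN_FAMILIES[[aa]]
      nv <- counts$counts[fam_codons]
      n <- sum(nv)
      if (n <= 1L) next
      p <- nv / n
      fvals <- c(fvals, (n * sum(p^2) - 1) / (n - 1))
    }
    if (length(fvals) == 0L || mean(fvals) <= 0) {
      fbar[ci] <- 1 / k
      imputed <- c(imputed, names(fbar)[ci])
    } else {
      fbar[ci] <- mean(fvals)
      any_estimable <- TRUE
    }
  }
  value <- 2 + 9 / fbar[["F2"]] + 1 / fbar[["F3"]] +
    5 / fbar[["F4"]] + 3 / fbar[["F6"]]
  value <- min(max(value, 20), 61)
  structure(list(gene_id = counts$gene_id, strain_id = counts$strain_id,
                 enc = value, fbar = fbar, imputed = imputed,
                 defined = any_estimable), class = "enc_value")
}

#' PR2 (parity rule 2) point for one gene
#'
#' Third-position base counts accumulated by default over the five
#' four-fold degenerate families (Ala, Gly, Pro, Thr, Val), where the
#' third position is free of amino-acid constraint; `fourfold_only =
#' FALSE` accumulates over all sense codons instead. The plot coordinates
#' are `x = G3/(G3+C3)` and `y = A3/(A3+T3)`.
#'
#' @param counts A `codon_counts`.
#' @param fourfold_only Restrict to four-fold degenerate families
#'   (default).
#' @return List of class `pr2_point`: `gene_id`, `strain_id`, `A3`, `T3`,
#'   `G3`, `C3`, `x`, `y`, `defined` (FALSE when a denominator is zero).
#' @export
pr2_point <- function(counts, fourfold_only = TRUE) {
  cods <- if (fourfold_only) {
    unlist(SYN_FAMILIES[FOURFOLD_AAS], use.names = FALSE)
  } else SENSE_CODONS
  third <- substr(cods, 3L, 3L)
  n <- counts$counts[cods]
  tot <- tapply(n, factor(third, levels = DNA_BASES), sum)
  tot[is.na(tot)] <- 0L
  a3 <- tot[["A"]]; t3 <- tot[["T"]]; g3 <- tot[["G"]]; c3 <- tot[["C"]]
  x <- if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_
  y <- if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_
  structure(list(gene_id = counts$gene_id, strain_id = counts$strain_id,
                 A3 = a3, T3 = t3, G3 = g3, C3 = c3, x = x, y = y,
                 defined = !is.na(x) && !is.na(y)), class = "pr2_point")
}

#' Significantly variable codons between two groups
#'
#' Codons preferred (RSCU > 1) in exactly one of the two groups; the
#' boundary RSCU = 1 counts as unpreferred. Single-codon families (ATG,
#' TGG) are excluded — their RSCU is constant.
#'
#' @param rscu_a,rscu_b RSCU tables from [rscu()] (typically on
#'   count-pooled group counts).
#' @return Sorted character vector of SVC codons.
#' @export
svc <- function(rscu_a, rscu_b) {
  stopifnot(identical(rscu_a$codon, rscu_b$codon))
  keep <- rscu_a$codon %in% REPORTABLE_CODONS
  a <- rscu_a$rscu[keep] > 1
  b <- rscu_b$rscu[keep] > 1
  sort(rscu_a$codon[keep][xor(a, b)])
}

#' Tally terminal (stop) codon usage
#'
#' @param terminals Character vector of terminal codons for one group's
#'   genes; non-stop entries are dropped with a warning.
#' @return `data.frame` (`codon`, `count`, `rank`) ordered by descending
#'   count with ties broken `TAA < TAG < TGA`.
#' @export
stop_codon_tally <- function(terminals) {
  terminals <- terminals[!is.na(terminals)]
  bad <- !(terminals %in% STOP_CODONS)
  if (any(bad)) {
    warning("dropping ", sum(bad), " non-stop terminal codon(s)",
            call. = FALSE)
    terminals <- terminals[!bad]
  }
  counts <- table(factor(terminals, levels = STOP_CODONS))
  df <- data.frame(codon = STOP_CODONS, count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$codon), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' F-test-then-t-test comparison of per-group ENC values
#'
#' A two-sided F-test at level `alpha` decides between the pooled-variance
#' and the unequal-variance (Welch) two-sided t-test. Degenerate inputs:
#' when both groups have zero variance, p is 1 for equal means and 0
#' otherwise (the limit of the pooled t statistic).
#'
#' @param gene_id Identifier carried into the result.
#' @param enc_a,enc_b Numeric vectors of ENC values (>= 2 each).
#' @param alpha Significance level of the variance pre-test.
#' @return List of class `group_comparison`: group means/SDs, `f_p`,
#'   `variant` (`"pooled"`/`"welch"`), `t_p`, `tier` (`">0.05"`,
#'   `"<0.05"`, `"<0.01"`).
#' @export
enc_group_test <- function(gene_id, enc_a, enc_b, alpha = 0.05) {
  if (length(enc_a) < 2L || length(enc_b) < 2L) {
    stop("need at least two values per group")
  }
  va <- stats::var(enc_a); vb <- stats::var(enc_b)
  if (va == 0 && vb == 0) {
    f_p <- 1
    variant <- "pooled"
    t_p <- if (isTRUE(all.equal(mean(enc_a), mean(enc_b)))) 1 else 0
  } else {
    f_p <- stats::var.test(enc_a, enc_b)$p.value
    variant <- if (f_p >= alpha) "pooled" else "welch"
    t_p <- tryCatch(
      stats::t.test(enc_a, enc_b, var.equal = (variant == "pooled"))$p.value,
      error = function(e) NA_real_)
  }
  tier <- if (is.na(t_p)) NA_character_
          else if (t_p < 0.01) "<0.01"
          else if (t_p < 0.05) "<0.05" else ">0.05"
  structure(list(gene_id = gene_id,
                 mean_a = mean(enc_a), sd_a = stats::sd(enc_a),
                 mean_b = mean(enc_b), sd_b = stats::sd(enc_b),
                 f_p = f_p, variant = variant, t_p = t_p, tier = tier),
            class = "group_comparison")
}

#' GC content of a sequence or codon count table
#'
#' @param x Nucleotide string (gaps ignored) or a `codon_counts`.
#' @param positions `"all"` or `"third"` (third codon position only; for a
#'   string input the frame starts at base 1).
#' @return `(G + C) / (A + C + G + T)` with N excluded from the
#'   denominator; `NA` when the denominator is empty.
#' @export
gc_content <- function(x, positions = c("all", "third")) {
  positions <- match.arg(positions)
  if (inherits(x, "codon_counts")) {
    cods <- names(x$counts)
    n <- x$counts
    chars <- if (positions == "third") substr(cods, 3L, 3L) else cods
    if (positions == "third") {
      gc <- sum(n[chars %in% c("G", "C")])
      at <- sum(n[chars %in% c("A", "T")])
    } else {
      per <- vapply(seq_along(cods), function(i) {
        b <- strsplit(cods[i], "", fixed = TRUE)[[1]]
        c(gc = sum(b %in% c("G", "C")), at = sum(b %in% c("A", "T")))
      }, numeric(2))
      gc <- sum(per["gc", ] * n)
      at <- sum(per["at", ] * n)
    }
  } else {
    s <- gsub("-", "", x, fixed = TRUE)
    if (positions == "third") {
      cods <- split_codons(s)
      s <- paste(substr(cods, 3L, 3L), collapse = "")
    }
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    gc <- sum(b %in% c("G", "C"))
    at <- sum(b %in% c("A", "T"))
  }
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}
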