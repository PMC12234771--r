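# Shared fixtures, all built in code.

empty_indel_table_for_tests <- function() camscan:::empty_indel_table()

two_lineage_strains <- function() {
  strain_table(c("A1", "A2", "A3", "B1", "B2", "B3", "B4"),
               c("A", "A", "A", "B", "B", "B", "B"))
}

# Codon-count object from a named vector of codon counts.
counts_from <- function(..., gene_id = "g", strain_id = "s") {
  v <- c(...)
  counts <- stats::setNames(integer(64), names(camscan:::CODON_AA))
  counts[names(v)] <- as.integer(v)
  structure(list(gene_id = gene_id, strain_id = strain_id, counts = counts,
                 terminal = NA_character_, eligible = TRUE,
                 n_codons = sum(counts)),
            class = "codon_counts")
}

# Counts with every sense codon used equally.
uniform_counts <- function(n_each = 10L) {
  v <- stats::setNames(rep(n_each, length(camscan:::SENSE_CODONS)),
                       camscan:::SENSE_CODONS)
  do.call(counts_from, as.list(v))
}

# One codon per family, used heavily: the minimum-diversity usage.
single_codon_counts <- function(n_each = 100L) {
  first <- vapply(camscan:::SYN_FAMILIES, `[[`, "", 1L)
  v <- stats::setNames(rep(n_each, length(first)), unname(first))
  do.call(counts_from, as.list(v))
}

# A quiet mid-size panel reused by several scanner tests (memoised).
.test_panel_env <- new.env()
scanner_test_panel <- function() {
  if (is.null(.test_panel_env$panel)) {
    cfg <- sim_config(n_genes = 10, len_range = c(300, 1500),
                      sub_rate = 0.02, indel_rate = 0.002,
                      stem_mult = 1, seed = 42)
    .test_panel_env$panel <- simulate_panel(cfg)
  }
  .test_panel_env$panel
}

# Group scanner SNP records into merged (column, ref, alt) -> carriers form.
merged_snps <- function(sn) {
  if (nrow(sn) == 0L) return(sn)
  key <- paste(sn$gene_id, sn$column, sn$ref, sn$alt, sep = "\r")
  do.call(rbind, lapply(split(sn, key), function(grp) {
    data.frame(gene_id = grp$gene_id[1], column = grp$column[1],
               ref = grp$ref[1], alt = grp$alt[1],
               carriers = paste(sort(grp$strain_id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

# Fraction of non-interfering truth events exactly recovered by the
# scanners (coordinates, lengths, polarities, sequences, carrier sets).
truth_recovery <- function(panel) {
  ev <- panel$truth$events
  ok_snp <- 0L; n_snp <- 0L; ok_ind <- 0L; n_ind <- 0L
  for (g in names(panel$alignments)) {
    aln <- panel$alignments[[g]]
    ref <- panel$truth$ancestor_aln[[g]]
    sn <- merged_snps(call_snps(aln, ref))
    ind <- call_indels(aln, ref)
    tev <- ev[ev$gene_id == g & !ev$interferes, , drop = FALSE]
    subs <- tev[tev$type == "substitution", , drop = FALSE]
    n_snp <- n_snp + nrow(subs)
    for (i in seq_len(nrow(subs))) {
      hit <- sn[sn$column == subs$column[i] & sn$ref == subs$from[i] &
                  sn$alt == subs$to[i], , drop = FALSE]
      want <- paste(sort(strsplit(subs$carriers[i], ",")[[1]]), collapse = ",")
      if (nrow(hit) == 1L && hit$carriers == want) ok_snp <- ok_snp + 1L
    }
    tind <- tev[tev$type != "substitution", , drop = FALSE]
    n_ind <- n_ind + nrow(tind)
    for (i in seq_len(nrow(tind))) {
      pol <- if (tind$type[i] == "deletion") "deletion" else "insertion"
      hit <- ind[ind$start == tind$column[i] & ind$length == tind$length[i] &
                   ind$polarity == pol, , drop = FALSE]
      want <- sort(strsplit(tind$carriers[i], ",")[[1]])
      got <- if (nrow(hit) == 1L) sort(strsplit(hit$carriers, ",")[[1]])
             else character(0)
      if (nrow(hit) == 1L && identical(want, got) &&
          hit$sequence == tind$seq[i]) ok_ind <- ok_ind + 1L
    }
  }
  list(snp_ok = ok_snp, snp_n = n_snp, ind_ok = ok_ind, ind_n = n_ind)
}

# Zero-rate 7-strain panel with planted aversions giving every strain a
# unique motif profile; plants are chosen among codons actually used.
planted_cam_panel <- function(seed = 7, merge_last_two = FALSE) {
  cfg <- sim_config(n_genes = 5, len_range = c(600, 900),
                    sub_rate = 0, indel_rate = 0, seed = seed)
  panel <- simulate_panel(cfg)
  usable <- function(g, k) {
    cc <- count_codons(degap_and_validate(panel$alignments[[g]]$seqs[["A1"]],
                                          g, "A1"))
    cands <- camscan:::REPORTABLE_CODONS[
      cc$counts[camscan:::REPORTABLE_CODONS] > 0L &
        camscan:::CODON_FAMILY_SIZE[camscan:::REPORTABLE_CODONS] >= 2L]
    cands[seq_len(k)]
  }
  p1 <- usable("g001", 1)
  panel <- plant_cam_difference(panel, "g001", p1, "B")      # group marker
  p2 <- usable("g002", 2)
  panel <- plant_cam_difference(panel, "g002", p2[1], "A1")
  panel <- plant_cam_difference(panel, "g002", p2[2], "A2")
  p3 <- usable("g003", 2)
  panel <- plant_cam_difference(panel, "g003", p3[1], "B1")
  panel <- plant_cam_difference(panel, "g003", p3[2], "B2")
  p4 <- usable("g004", 1)
  target4 <- if (merge_last_two) c("B3", "B4") else "B3"
  panel <- plant_cam_difference(panel, "g004", p4, target4)
  panel
}

panel_cam_table <- function(panel, min_len = 300L) {
  counts <- list()
  for (g in names(panel$alignments)) {
    for (s in names(panel$alignments[[g]]$seqs)) {
      cds <- suppressWarnings(degap_and_validate(
        panel$alignments[[g]]$seqs[[s]], g, s, min_len))
      counts[[paste(g, s)]] <- count_codons(cds)
    }
  }
  cam_table(counts)
}
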