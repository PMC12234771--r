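# End-to-end orchestration: simulate or load a panel, scan variants against
# the first lineage's consensus, profile codon usage, build the CAM map and
# assemble a reproducible report.

#' Run configuration
#'
#' Exactly one input source: either a directory of per-gene aligned FASTA
#' plus a strain table, or a [sim_config()] to simulate from.
#'
#' @param input_dir Directory with `alignments/` or FASTA files plus
#'   `strains.tsv` (as written by [write_panel()]), or `NULL`.
#' @param sim A [sim_config()], or `NULL`.
#' @param out_dir Output directory for tables and the report.
#' @param min_len Codon-statistics eligibility threshold in nt (strict
#'   greater-than).
#' @param fourfold_only PR2 restricted to four-fold degenerate families.
#' @param alpha Level of the variance pre-test in the ENC comparison.
#' @param lineage_first Root the CAM map at a group-diagnostic gene.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, sim = NULL, out_dir,
                       min_len = 300L, fourfold_only = TRUE, alpha = 0.05,
                       lineage_first = TRUE) {
  if (is.null(input_dir) == is.null(sim)) {
    stop("run_config: exactly one of input_dir and sim must be given")
  }
  structure(list(input_dir = input_dir, sim = sim, out_dir = out_dir,
                 min_len = as.integer(min_len),
                 fourfold_only = fourfold_only, alpha = alpha,
                 lineage_first = lineage_first),
            class = "run_config")
}

load_input_panel <- function(cfg) {
  if (!is.null(cfg$sim)) {
    panel <- simulate_panel(cfg$sim)
    return(list(alignments = panel$alignments, strains = panel$strains,
                truth = panel$truth))
  }
  dir <- cfg$input_dir
  aln_dir <- if (dir.exists(file.path(dir, "alignments")))
    file.path(dir, "alignments") else dir
  strains <- read_strain_table(file.path(dir, "strains.tsv"))
  list(alignments = read_panel(aln_dir, strains), strains = strains,
       truth = NULL)
}

#' Run the full comparative pipeline
#'
#' Stages: input (or simulation), variant scan of the second lineage's
#' strains against the first lineage's consensus, codon-usage statistics
#' with the per-gene ENC group test, CAM extraction and identification-map
#' construction, and report assembly. All outputs are written under
#' `cfg$out_dir`; identical configuration and seed give identical outputs.
#'
#' @param cfg A [run_config()].
#' @return The report (list), invisibly written as `report.json`.
#' @export
run_pipeline <- function(cfg) {
  stage <- "input"
  result <- tryCatch({
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    inp <- load_input_panel(cfg)
    alns <- inp$alignments
    strains <- inp$strains
    ls <- lineages(strains)
    ref_lineage <- ls[1]; alt_lineage <- ls[2]
    alt_ids <- lineage_strains(strains, alt_lineage)

    stage <- "variant_scan"
    snps_all <- list(); indels_all <- list(); tstv_rows <- list()
    for (g in names(alns)) {
      ref <- build_consensus(alns[[g]], strains, ref_lineage)
      ids <- intersect(alt_ids, names(alns[[g]]$seqs))
      if (length(ids) == 0L) next
      sn <- call_snps(alns[[g]], ref, ids)
      ind <- call_indels(alns[[g]], ref, ids)
      snps_all[[g]] <- sn
      indels_all[[g]] <- ind
      tt <- tstv_ratio(sn)
      tstv_rows[[g]] <- data.frame(gene_id = g, n_snps = nrow(sn),
                                   transitions = tt$transitions,
                                   transversions = tt$transversions,
                                   tstv = tt$ratio, stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, c(snps_all, list(make.row.names = FALSE)))
    if (is.null(snps)) {
      snps <- call_snps(alns[[1]], alns[[1]]$seqs[[1]], character(0))
    }
    indels <- do.call(rbind, c(indels_all, list(make.row.names = FALSE)))
    if (is.null(indels)) indels <- empty_indel_table()
    tstv_tab <- do.call(rbind, c(tstv_rows, list(make.row.names = FALSE)))
    if (!is.null(tstv_tab)) {
      write_tsv_commented(tstv_tab, file.path(cfg$out_dir, "tstv.tsv"),
                          "camscan per-gene transition/transversion ratios")
    }
    indel_sum <- summarize_indels(indels, alns, alt_ids)
    write_tsv_commented(snps, file.path(cfg$out_dir, "snps.tsv"),
                        "camscan SNPs vs first-lineage consensus")
    write_tsv_commented(indels, file.path(cfg$out_dir, "indels.tsv"),
                        "camscan INDELs vs first-lineage consensus")

    stage <- "codon_stats"
    counts <- list()
    for (g in names(alns)) {
      for (s in names(alns[[g]]$seqs)) {
        cds <- suppressWarnings(
          degap_and_validate(alns[[g]]$seqs[[s]], g, s, cfg$min_len))
        counts[[paste(g, s)]] <- count_codons(cds)
      }
    }
    eligible <- Filter(function(cc) cc$eligible, counts)
    enc_rows <- list(); pr2_rows <- list(); test_rows <- list()
    svc_rows <- list(); term_rows <- list()
    genes_elig <- unique(vapply(eligible, `[[`, "", "gene_id"))
    for (g in genes_elig) {
      cc_g <- Filter(function(cc) cc$gene_id == g, eligible)
      sid <- vapply(cc_g, `[[`, "", "strain_id")
      lin <- strains$lineage[match(sid, strains$strain_id)]
      encs <- vapply(cc_g, function(cc) enc(cc)$enc, numeric(1))
      enc_rows[[g]] <- data.frame(gene_id = g, strain_id = sid, lineage = lin,
                                  enc = round_half_up(encs, 2),
                                  stringsAsFactors = FALSE)
      for (i in seq_along(cc_g)) {
        p <- pr2_point(cc_g[[i]], cfg$fourfold_only)
        pr2_rows[[paste(g, sid[i])]] <- data.frame(
          gene_id = g, strain_id = sid[i],
          x = round_half_up(p$x, 2), y = round_half_up(p$y, 2),
          A3 = p$A3, T3 = p$T3, G3 = p$G3, C3 = p$C3,
          stringsAsFactors = FALSE)
      }
      ea <- encs[lin == ref_lineage]; eb <- encs[lin == alt_lineage]
      if (length(ea) >= 2L && length(eb) >= 2L) {
        gt <- enc_group_test(g, ea, eb, cfg$alpha)
        test_rows[[g]] <- data.frame(
          gene_id = g, mean_a = round_half_up(gt$mean_a, 2),
          sd_a = round_half_up(gt$sd_a, 2),
          mean_b = round_half_up(gt$mean_b, 2),
          sd_b = round_half_up(gt$sd_b, 2),
          f_p = gt$f_p, variant = gt$variant, t_p = gt$t_p, tier = gt$tier,
          stringsAsFactors = FALSE)
      }
      ra <- rscu(pool_counts(cc_g[lin == ref_lineage]))
      rb <- rscu(pool_counts(cc_g[lin == alt_lineage]))
      sv <- svc(ra, rb)
      svc_rows[[g]] <- data.frame(gene_id = g, n_svc = length(sv),
                                  svc = paste(sv, collapse = ","),
                                  stringsAsFactors = FALSE)
      term_rows[[g]] <- data.frame(gene_id = g, strain_id = sid, lineage = lin,
                                   terminal = vapply(cc_g, `[[`, "", "terminal"),
                                   stringsAsFactors = FALSE)
    }
    enc_tab <- do.call(rbind, c(enc_rows, list(make.row.names = FALSE)))
    pr2_tab <- do.call(rbind, c(pr2_rows, list(make.row.names = FALSE)))
    test_tab <- do.call(rbind, c(test_rows, list(make.row.names = FALSE)))
    svc_tab <- do.call(rbind, c(svc_rows, list(make.row.names = FALSE)))
    term_tab <- do.call(rbind, c(term_rows, list(make.row.names = FALSE)))
    stop_tallies <- lapply(stats::setNames(ls, ls), function(l) {
      stop_codon_tally(term_tab$terminal[term_tab$lineage == l])
    })
    write_tsv_commented(enc_tab, file.path(cfg$out_dir, "enc.tsv"),
                        "camscan per-gene/strain effective number of codons")
    write_tsv_commented(pr2_tab, file.path(cfg$out_dir, "pr2.tsv"),
                        "camscan PR2 third-position biases")
    if (!is.null(test_tab)) {
      write_tsv_commented(test_tab, file.path(cfg$out_dir, "group_tests.tsv"),
                          "camscan ENC group comparisons (F-test then t-test)")
    }
    write_tsv_commented(svc_tab, file.path(cfg$out_dir, "svc.tsv"),
                        "camscan significantly variable codons per gene")

    stage <- "cam"
    cams <- cam_table(eligible)
    write_tsv_commented(cams, file.path(cfg$out_dir, "cams.tsv"),
                        "camscan codon aversion motifs")
    diag_genes <- suppressWarnings(group_diagnostic_genes(cams, strains))
    sscam <- strain_specific_cams(cams, strains)
    map <- build_identification_map(cams, strains, cfg$lineage_first)
    write_map_json(map, file.path(cfg$out_dir, "identification_map.json"))
    write_map_dot(map, file.path(cfg$out_dir, "identification_map.dot"))
    self_id <- vapply(strains$strain_id, function(s) {
      q <- stats::setNames(cams$motif[cams$strain_id == s],
                           cams$gene_id[cams$strain_id == s])
      res <- identify_strain(as.list(q), map)
      identical(res$strain_id, s)
    }, TRUE)

    stage <- "report"
    tt_all <- tstv_ratio(snps)
    report <- list(
      provenance = list(
        package_version = as.character(utils::packageVersion("camscan")),
        seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA,
        min_len = cfg$min_len, alpha = cfg$alpha,
        fourfold_only = cfg$fourfold_only, lineage_first = cfg$lineage_first),
      panel = list(n_genes = length(alns),
                   n_strains = nrow(strains),
                   lineages = as.list(table(strains$lineage))),
      snp = list(total = nrow(snps),
                 per_strain = as.list(table(snps$strain_id)),
                 transitions = tt_all$transitions,
                 transversions = tt_all$transversions,
                 tstv = tt_all$ratio),
      indel = list(
        total = indel_sum$n_total,
        categories = indel_sum$categories,
        frame_preserving_fraction = indel_sum$frame_preserving_fraction),
      codon = list(n_eligible_gene_strain = length(eligible),
                   stop_tallies = stop_tallies,
                   n_significant_genes =
                     if (is.null(test_tab)) 0L else sum(test_tab$tier != ">0.05"),
                   svc_total = sum(svc_tab$n_svc)),
      cam = list(n_group_diagnostic = length(diag_genes),
                 group_diagnostic_genes = diag_genes,
                 perfect_genes = sscam$by_gene$gene_id[sscam$by_gene$perfect],
                 n_unresolved_leaves = length(map_unresolved(map)),
                 self_identification = mean(self_id)))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    report
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
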