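#!/usr/bin/env Rscript
# Codon-usage profile of the simulated panel: per-gene/strain ENC, PR2
# third-position biases, group-pooled RSCU with significantly variable
# codons, stop-codon preference, and the F-test-then-t-test ENC comparison
# between the two clades.

suppressMessages(library(camscan))

strains <- read_strain_table("results/panel/strains.tsv")
alns <- read_panel("results/panel/alignments", strains)
ls <- lineages(strains)

counts <- list()
for (g in names(alns)) {
  for (s in names(alns[[g]]$seqs)) {
    cds <- suppressWarnings(degap_and_validate(alns[[g]]$seqs[[s]], g, s))
    if (cds$eligible) counts[[paste(g, s)]] <- count_codons(cds)
  }
}
gene_of <- vapply(counts, `[[`, "", "gene_id")
strain_of <- vapply(counts, `[[`, "", "strain_id")
lin_of <- strains$lineage[match(strain_of, strains$strain_id)]

enc_tab <- data.frame(gene_id = gene_of, strain_id = strain_of,
                      lineage = lin_of,
                      enc = round_half_up(vapply(counts, function(cc)
                        enc(cc)$enc, numeric(1)), 2))
tests <- list(); svcs <- list()
for (g in unique(gene_of)) {
  ea <- enc_tab$enc[enc_tab$gene_id == g & enc_tab$lineage == ls[1]]
  eb <- enc_tab$enc[enc_tab$gene_id == g & enc_tab$lineage == ls[2]]
  if (length(ea) >= 2 && length(eb) >= 2) {
    gt <- enc_group_test(g, ea, eb)
    tests[[g]] <- data.frame(gene_id = g,
                             mean_a = round_half_up(gt$mean_a, 2),
                             mean_b = round_half_up(gt$mean_b, 2),
                             variant = gt$variant, t_p = gt$t_p,
                             tier = gt$tier)
  }
  ra <- rscu(pool_counts(counts[gene_of == g & lin_of == ls[1]]))
  rb <- rscu(pool_counts(counts[gene_of == g & lin_of == ls[2]]))
  sv <- svc(ra, rb)
  svcs[[g]] <- data.frame(gene_id = g, n_svc = length(sv),
                          svc = paste(sv, collapse = ","))
}
tests <- do.call(rbind, tests)
svcs <- do.call(rbind, svcs)

write.table(enc_tab, "results/enc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tests, "results/enc_group_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(svcs, "results/svc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("ENC over %d eligible gene x strain profiles: %.2f - %.2f\n",
            nrow(enc_tab), min(enc_tab$enc), max(enc_tab$enc)))
cat(sprintf("group ENC comparisons: %d genes, %d below p = 0.05\n",
            nrow(tests), sum(tests$tier != ">0.05")))
cat(sprintf("SVC counts per gene: %d - %d (panel total %d)\n",
            min(svcs$n_svc), max(svcs$n_svc), sum(svcs$n_svc)))
for (l in ls) {
  term <- vapply(counts[lin_of == l], `[[`, "", "terminal")
  tl <- stop_codon_tally(term)
  cat("stop-codon preference, lineage", l, ":",
      paste(sprintf("%s=%d", tl$codon, tl$count), collapse = " "), "\n")
}
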