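test_that("motif extraction returns exactly the unused reportable codons", {
  full <- uniform_counts()
  expect_identical(extract_cam(full), character(0))
  gapped <- uniform_counts()
  gapped$counts[c("CGC", "TTA")] <- 0L
  expect_identical(extract_cam(gapped), c("CGC", "TTA"))
  # singleton families never enter the motif
  noatg <- uniform_counts()
  noatg$counts[c("ATG", "TGG")] <- 0L
  expect_identical(extract_cam(noatg), character(0))
  inel <- uniform_counts()
  inel$eligible <- FALSE
  expect_warning(m <- extract_cam(inel), "ineligible")
  expect_identical(m, character(0))
})

test_that("motifs are disjoint from used codons and shrink monotonically", {
  set.seed(41)
  for (i in 1:20) {
    cods <- sample(camscan:::SENSE_CODONS, sample(50:400, 1), replace = TRUE)
    v <- table(cods)
    cc <- do.call(counts_from, as.list(stats::setNames(as.integer(v), names(v))))
    m <- extract_cam(cc)
    used <- names(cc$counts)[cc$counts > 0]
    expect_length(intersect(m, used), 0)
    # adding occurrences can only shrink or preserve the motif
    cc2 <- cc
    extra <- sample(camscan:::SENSE_CODONS, 5)
    cc2$counts[extra] <- cc2$counts[extra] + 1L
    expect_true(all(extract_cam(cc2) %in% m))
  }
})

test_that("group diagnosticity requires disjoint motif-value sets", {
  st <- two_lineage_strains()
  mk <- function(gene, motifs) data.frame(
    gene_id = gene, strain_id = st$strain_id, motif = motifs,
    n_codons_absent = lengths(strsplit(motifs, ",")), stringsAsFactors = FALSE)
  cams <- rbind(
    mk("g1", c("TTA", "TTA", "TTA", "CGC", "CGC", "CGC", "CGC")),  # disjoint
    mk("g2", rep("TTA", 7)),                                       # shared
    mk("g3", c("TTA", "", "TTA", "", "CGC", "CGC", "CGC")))        # "" shared
  expect_identical(group_diagnostic_genes(cams, st), "g1")
  # missing strain -> excluded with a warning
  cams4 <- rbind(cams, mk("g4", c("GGT", "GGT", "GGT", "ACC", "ACC", "ACC",
                                  "ACC"))[-7, ])
  expect_warning(d <- group_diagnostic_genes(cams4, st), "missing")
  expect_identical(d, "g1")
})

test_that("strain-specific motifs report uniqueness and partition blocks", {
  st <- two_lineage_strains()
  motifs <- c("", "AAT", "ACC", "AGG", "CAT", "CCG", "CGA")
  cams <- data.frame(gene_id = "gp", strain_id = st$strain_id, motif = motifs,
                     n_codons_absent = 1L, stringsAsFactors = FALSE)
  out <- strain_specific_cams(cams, st)
  expect_true(out$by_gene$perfect)
  expect_identical(out$by_gene$n_blocks, 7L)
  expect_identical(out$by_strain$A1, "gp")

  motifs2 <- motifs; motifs2[6:7] <- "SHARED"
  cams2 <- data.frame(gene_id = "gq", strain_id = st$strain_id,
                      motif = motifs2, n_codons_absent = 1L,
                      stringsAsFactors = FALSE)
  out2 <- strain_specific_cams(cams2, st)
  expect_false(out2$by_gene$perfect)
  expect_identical(out2$by_gene$n_blocks, 6L)
  uniq <- strsplit(out2$by_gene$unique_strains, ",")[[1]]
  expect_setequal(uniq, st$strain_id[1:5])
})

test_that("the decision map separates strains with planted aversions", {
  panel <- planted_cam_panel()
  cams <- panel_cam_table(panel)
  map <- build_identification_map(cams, panel$strains)
  part <- map_partition(map)
  expect_identical(unname(sort(lengths(part))), rep(1L, 7L))
  expect_length(map_unresolved(map), 0)
  # root uses a group-diagnostic gene under lineage_first
  diag <- group_diagnostic_genes(cams, panel$strains)
  expect_true(map$root$gene %in% diag)
  # identification is the identity on training strains
  for (s in panel$strains$strain_id) {
    q <- stats::setNames(as.list(cams$motif[cams$strain_id == s]),
                         cams$gene_id[cams$strain_id == s])
    res <- identify_strain(q, map)
    expect_identical(res$status, "identified")
    expect_identical(res$strain_id, s)
  }
})

test_that("inseparable strains end in a single flagged leaf", {
  panel <- planted_cam_panel(merge_last_two = TRUE)
  cams <- panel_cam_table(panel)
  map <- build_identification_map(cams, panel$strains)
  unres <- map_unresolved(map)
  expect_length(unres, 1)
  expect_setequal(unres[[1]], c("B3", "B4"))
  q <- stats::setNames(as.list(cams$motif[cams$strain_id == "B3"]),
                       cams$gene_id[cams$strain_id == "B3"])
  res <- identify_strain(q, map)
  expect_identical(res$status, "non_separable")
  expect_setequal(res$candidates, c("B3", "B4"))
})

test_that("novel and missing motifs degrade to explicit ambiguity", {
  panel <- planted_cam_panel()
  cams <- panel_cam_table(panel)
  map <- build_identification_map(cams, panel$strains)
  root_gene <- map$root$gene
  q <- stats::setNames(as.list(cams$motif[cams$strain_id == "A1"]),
                       cams$gene_id[cams$strain_id == "A1"])
  q[[root_gene]] <- "ZZZ"   # motif value seen in no training strain
  res <- identify_strain(q, map)
  expect_identical(res$status, "novel_motif")
  expect_setequal(res$candidates, panel$strains$strain_id)
  q2 <- q[setdiff(names(q), root_gene)]
  res2 <- identify_strain(q2, map)
  expect_identical(res2$status, "missing_gene")
  expect_setequal(res2$candidates, panel$strains$strain_id)
})

test_that("greedy separability matches exhaustive search on small instances", {
  # oracle: strains are separable exactly when their full motif profiles
  # differ; the greedy map's leaf partition must equal profile equality
  set.seed(43)
  motif_pool <- c("", "AAT", "ACC", "AGG")
  for (rep in 1:25) {
    n_s <- sample(2:4, 1); n_g <- sample(2:5, 1)
    st <- strain_table(paste0("S", 1:n_s),
                      c("A", rep("B", n_s - 1)))
    cams <- do.call(rbind, lapply(1:n_g, function(gi) {
      data.frame(gene_id = paste0("g", gi), strain_id = st$strain_id,
                 motif = sample(motif_pool, n_s, replace = TRUE),
                 n_codons_absent = 1L, stringsAsFactors = FALSE)
    }))
    profile <- vapply(st$strain_id, function(s) {
      sub <- cams[cams$strain_id == s, ]
      paste(sub$motif[order(sub$gene_id)], collapse = "|")
    }, "")
    oracle_part <- sort(vapply(split(st$strain_id, profile),
                               function(b) paste(sort(b), collapse = ","), ""))
    map <- build_identification_map(cams, st, lineage_first = FALSE)
    greedy_part <- sort(vapply(map_partition(map),
                               function(b) paste(sort(b), collapse = ","), ""))
    expect_identical(unname(greedy_part), unname(oracle_part))
  }
})

test_that("single-strain maps and exports behave", {
  # an empty motif is a legitimate branch label and must survive export
  cams <- data.frame(gene_id = "g1", strain_id = c("S1", "S2"),
                     motif = c("AAT", ""), n_codons_absent = c(1L, 0L),
                     stringsAsFactors = FALSE)
  st <- strain_table(c("S1", "S2"), c("A", "B"))
  map <- build_identification_map(cams, st)
  jpath <- withr::local_tempfile(fileext = ".json")
  dpath <- withr::local_tempfile(fileext = ".dot")
  write_map_json(map, jpath)
  write_map_dot(map, dpath)
  expect_true(jsonlite::validate(paste(readLines(jpath), collapse = "")))
  expect_true(any(grepl("digraph", readLines(dpath))))
})
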