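test_that("substitution classification matches the purine/pyrimidine rule", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("A", "C"), "transversion")
  # brute-force enumeration of the 12 ordered base pairs
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_identical(sum(cls == "transition"), 4L)
  expect_identical(sum(cls == "transversion"), 8L)
  expect_error(classify_substitution("A", "A"), "domain")
  expect_error(classify_substitution("A", "N"), "domain")
})

test_that("call_snps reports differing unambiguous columns only", {
  aln <- gene_alignment("g", c(S1 = "ACGT", S2 = "ACGA", S3 = "ACNT"))
  expect_identical(nrow(call_snps(aln, "ACGT", "S1")), 0L)
  sn <- call_snps(aln, "ACGT", "S2")
  expect_identical(sn$column, 4L)
  expect_identical(sn$ref, "T")
  expect_identical(sn$alt, "A")
  expect_identical(sn$class, "transversion")
  # N columns are skipped on either side
  expect_identical(nrow(call_snps(aln, "ACGT", "S3")), 0L)
  # gap columns are skipped (they belong to the INDEL caller)
  aln2 <- gene_alignment("g", c(S1 = "AC-T", S2 = "ACGT"))
  expect_identical(nrow(call_snps(aln2, "AC-T", "S2")), 0L)
  expect_error(call_snps(aln, "ACGTA", "S1"), "alignment-shape")
})

test_that("ts/tv ratio handles degenerate SNP sets", {
  mk <- function(ts, tv) data.frame(
    class = c(rep("transition", ts), rep("transversion", tv)))
  expect_identical(tstv_ratio(mk(4, 2))$ratio, 2)
  r0 <- tstv_ratio(mk(0, 0))
  expect_true(is.nan(r0$ratio))
  expect_false(r0$defined)
  expect_identical(tstv_ratio(mk(3, 0))$ratio, Inf)
  # SNPs drawn uniformly over all ordered pairs: ratio is exactly 4/8
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  uni <- data.frame(class = classify_substitution(pairs$ref, pairs$alt))
  expect_identical(tstv_ratio(uni)$ratio, 0.5)
})

test_that("call_indels finds maximal gap runs with correct classification", {
  aln <- gene_alignment("g", c(S1 = "AAACCCTTT", S2 = "AAA---TTT"))
  expect_identical(nrow(call_indels(aln, "AAACCCTTT", "S1")), 0L)
  ins <- call_indels(aln, "AAA---TTT", "S1")
  expect_identical(ins$polarity, "insertion")
  expect_identical(ins$start, 4L)
  expect_identical(ins$length, 3L)
  expect_identical(ins$size_class, "small")
  expect_true(ins$frame_preserving)
  expect_identical(ins$sequence, "CCC")
  del <- call_indels(aln, "AAACCCTTT", "S2")
  expect_identical(del$polarity, "deletion")
  expect_identical(del$sequence, "CCC")   # deletion sequence from reference
})

test_that("the 40 bp boundary separates small from large", {
  ref <- paste0("AA", strrep("C", 41), "TT")
  s40 <- paste0("AA", "C", strrep("-", 40), "TT")
  s41 <- paste0("AA", strrep("-", 41), "TT")
  aln <- gene_alignment("g", c(S1 = s40, S2 = s41))
  recs <- call_indels(aln, ref)
  r40 <- recs[recs$length == 40L, ]
  r41 <- recs[recs$length == 41L, ]
  expect_identical(r40$size_class, "small")
  expect_identical(r41$size_class, "large")
  expect_false(r41$frame_preserving)
})

test_that("identical events merge carriers; different sequences stay apart", {
  ref <- "AAA---TTTGGG"
  aln <- gene_alignment("g", c(S1 = "AAACCCTTTGGG", S2 = "AAACCCTTTGGG",
                               S3 = "AAACGCTTTGGG", S4 = "AAA---TTTGGG"))
  recs <- call_indels(aln, ref)
  expect_identical(nrow(recs), 2L)
  merged <- recs[recs$sequence == "CCC", ]
  expect_identical(merged$carriers, "S1,S2")
  expect_identical(merged$n_carriers, 2L)
  expect_identical(recs$carriers[recs$sequence == "CGC"], "S3")
})

test_that("indel identity is the fully-shared fraction per category", {
  recs <- data.frame(
    gene_id = "g", start = c(1L, 10L, 20L, 30L), length = c(3L, 3L, 3L, 3L),
    polarity = "insertion", size_class = "small", frame_preserving = TRUE,
    sequence = "AAA",
    carriers = c("B1,B2,B3,B4", "B1,B2,B3,B4", "B1,B2", "B1"),
    n_carriers = c(4L, 4L, 2L, 1L), stringsAsFactors = FALSE)
  grp <- c("B1", "B2", "B3", "B4")
  expect_identical(indel_identity(recs, "small_insertion", grp), 0.5)
  expect_identical(indel_identity(recs[1:2, ], "small_insertion", grp), 1.0)
  expect_true(is.na(indel_identity(recs, "large_deletion", grp)))
  expect_error(indel_identity(recs, "small_insertion", "B1"), "two strains")
})

test_that("indel divergence is summed length over alignment columns", {
  aln <- gene_alignment("g", c(S1 = strrep("A", 100), S2 = strrep("A", 100)))
  expect_identical(indel_divergence(aln, empty_indel_table_for_tests()), 0)
  recs <- data.frame(gene_id = "g", start = 5L, length = 10L,
                     polarity = "deletion", size_class = "small",
                     frame_preserving = FALSE, sequence = strrep("A", 10),
                     carriers = "S2", n_carriers = 1L, stringsAsFactors = FALSE)
  expect_identical(indel_divergence(aln, recs), 0.10)
})

test_that("indel summaries reproduce published-style share arithmetic", {
  counts <- c(small_insertion = 261L, small_deletion = 198L,
              large_deletion = 65L, large_insertion = 53L)
  rows <- lapply(names(counts), function(cc) {
    parts <- strsplit(cc, "_")[[1]]
    len <- if (parts[1] == "small") 3L else 45L
    data.frame(gene_id = "g", start = 1L, length = len, polarity = parts[2],
               size_class = parts[1], frame_preserving = len %% 3L == 0L,
               sequence = strrep("A", len), carriers = "B1", n_carriers = 1L,
               stringsAsFactors = FALSE)[rep(1, counts[[cc]]), ]
  })
  recs <- do.call(rbind, rows)
  s <- summarize_indels(recs)
  got <- s$categories$share_pct[match(names(counts), s$categories$category)]
  expect_identical(got, c(45.23, 34.32, 11.27, 9.19))
  expect_lt(abs(sum(s$categories$share_pct) - 100), 0.02)
  one <- summarize_indels(recs[1, ])
  expect_identical(one$categories$share_pct[
    one$categories$category == "small_insertion"], 100)
})

test_that("size class is always recomputable from length", {
  p <- scanner_test_panel()
  for (g in names(p$alignments)) {
    recs <- call_indels(p$alignments[[g]], p$truth$ancestor_aln[[g]])
    if (nrow(recs) == 0) next
    expect_identical(recs$size_class,
                     ifelse(recs$length <= 40L, "small", "large"))
    expect_identical(recs$frame_preserving, recs$length %% 3L == 0L)
  }
})

test_that("scanners recover planted truth on a small panel", {
  p <- scanner_test_panel()
  rec <- truth_recovery(p)
  expect_gt(rec$snp_n, 500)
  expect_gt(rec$ind_n, 30)
  expect_identical(rec$snp_ok, rec$snp_n)
  expect_identical(rec$ind_ok, rec$ind_n)
})
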