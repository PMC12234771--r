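test_that("codon counting sets the terminal codon aside and skips N codons", {
  rec <- degap_and_validate("ATGAAATAA", "g", "s", min_len = 0)
  cc <- count_codons(rec)
  expect_identical(unname(cc$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_identical(sum(cc$counts), 2L)
  expect_identical(cc$terminal, "TAA")

  recN <- degap_and_validate("ATGANATAA", "g", "s", min_len = 0)
  ccN <- count_codons(recN)
  expect_identical(sum(ccN$counts), 1L)   # ANA skipped

  rec300 <- degap_and_validate(paste0("ATG", strrep("AAA", 98), "TAA"),
                               "g", "s")
  expect_false(count_codons(rec300)$eligible)
})

test_that("RSCU normalises to family size and marks absent codons", {
  u <- uniform_counts()
  ru <- rscu(u)
  expect_true(all(abs(ru$rscu - 1) < 1e-12))
  phe <- counts_from(TTT = 3, TTC = 1)
  rp <- rscu(phe)
  expect_identical(rp$rscu[rp$codon == "TTT"], 1.5)
  expect_identical(rp$rscu[rp$codon == "TTC"], 0.5)
  expect_identical(rp$rscu[rp$codon == "GGG"], 0)   # unused -> 0
  expect_true(rp$absent[rp$codon == "GGG"])
  # family sums equal family size wherever the family is used
  for (aa in unique(ru$aa)) {
    expect_equal(sum(ru$rscu[ru$aa == aa]), ru$family_size[ru$aa == aa][1])
  }
})

test_that("ENC spans its theoretical range", {
  lo <- enc(single_codon_counts())
  expect_identical(lo$enc, 20)
  hi <- enc(uniform_counts(100))
  expect_identical(hi$enc, 61)          # clipped at the uniform limit
  # 200 random uniform codons: high but not maximal
  set.seed(21)
  for (i in 1:5) {
    cods <- sample(camscan:::SENSE_CODONS, 200, replace = TRUE)
    v <- table(cods)
    cc <- do.call(counts_from, as.list(stats::setNames(as.integer(v), names(v))))
    e <- enc(cc)$enc
    expect_gte(e, 55)
    expect_lte(e, 61)
  }
})

test_that("ENC depends only on counts and is stable under count scaling", {
  set.seed(22)
  cods <- sample(camscan:::SENSE_CODONS, 5e4, replace = TRUE,
                 prob = runif(61, 0.2, 1))
  v <- table(cods)
  cc1 <- do.call(counts_from, as.list(stats::setNames(as.integer(v), names(v))))
  cc2 <- do.call(counts_from, as.list(stats::setNames(2L * as.integer(v), names(v))))
  expect_lt(abs(enc(cc1)$enc - enc(cc2)$enc), 0.05)
  e <- enc(cc1)
  expect_named(e$fbar, c("F2", "F3", "F4", "F6"))
})

test_that("ENC flags imputed degeneracy classes", {
  # only two-fold families used: F3/F4/F6 are imputed at 1/k
  cc <- counts_from(TTT = 10, TTC = 5, TAT = 8, TAC = 8)
  e <- enc(cc)
  expect_true(all(c("F3", "F4", "F6") %in% e$imputed))
  expect_true(e$defined)
  expect_gte(e$enc, 20)
  expect_lte(e$enc, 61)
})

test_that("PR2 coordinates follow the third-position ratios", {
  sym <- counts_from(GTA = 2, GTT = 2, GTG = 2, GTC = 2)
  p <- pr2_point(sym)
  expect_identical(c(p$x, p$y), c(0.5, 0.5))
  asym <- counts_from(GTA = 3, GTT = 1, GTG = 2, GTC = 2)
  p2 <- pr2_point(asym)
  expect_identical(p2$y, 0.75)
  expect_identical(p2$x, 0.5)
  # no four-fold usage -> undefined under the default
  p3 <- pr2_point(counts_from(TTT = 5, AAA = 5))
  expect_false(p3$defined)
})

test_that("PR2 over all codons conserves per-family third-position counts", {
  u <- uniform_counts(3)
  p <- pr2_point(u, fourfold_only = FALSE)
  third <- substr(camscan:::SENSE_CODONS, 3, 3)
  want <- tapply(u$counts[camscan:::SENSE_CODONS],
                 factor(third, levels = c("A", "C", "G", "T")), sum)
  expect_identical(c(p$A3, p$C3, p$G3, p$T3),
                   unname(c(want["A"], want["C"], want["G"], want["T"])))
})

test_that("SVC is the XOR of group preferences with boundary unpreferred", {
  a <- rscu(counts_from(TTT = 3, TTC = 1, GGT = 1, GGC = 1, GGA = 1, GGG = 1))
  expect_identical(svc(a, a), character(0))
  # TTT preferred in a (1.5) vs exactly 1.0 in b: boundary counts as unpreferred
  b <- rscu(counts_from(TTT = 2, TTC = 2, GGT = 1, GGC = 1, GGA = 1, GGG = 1))
  expect_true("TTT" %in% svc(a, b))
  expect_identical(svc(a, b), svc(b, a))
  # singleton families never appear
  expect_false(any(c("ATG", "TGG") %in% svc(a, b)))
})

test_that("stop-codon tallies rank with the documented tie order", {
  t1 <- stop_codon_tally(rep("TAA", 5))
  expect_identical(t1$codon[1], "TAA")
  expect_identical(t1$count[1], 5L)
  t2 <- stop_codon_tally(c(rep("TAG", 7), rep("TAA", 6), rep("TGA", 2)))
  expect_identical(t2$codon, c("TAG", "TAA", "TGA"))
  expect_identical(t2$count, c(7L, 6L, 2L))
  t3 <- stop_codon_tally(c(rep("TAA", 3), rep("TAG", 3)))
  expect_identical(t3$codon[1:2], c("TAA", "TAG"))   # tie -> TAA first
  expect_warning(t4 <- stop_codon_tally(c("TAA", "AAA")), "non-stop")
  expect_identical(sum(t4$count), 1L)
})

test_that("the ENC group test picks its variant from the F-test", {
  same <- enc_group_test("g", c(40, 41, 42), c(40, 41, 42, 41))
  expect_identical(same$variant, "pooled")
  expect_gt(same$t_p, 0.05)

  ident <- enc_group_test("g", c(40, 40.5, 41), c(40, 40.5, 41))
  expect_identical(ident$tier, ">0.05")

  zero <- enc_group_test("g", c(40, 40, 40), c(44, 44, 44, 44))
  expect_identical(zero$t_p, 0)
  expect_identical(zero$tier, "<0.01")
  zeq <- enc_group_test("g", c(40, 40, 40), c(40, 40, 40, 40))
  expect_identical(zeq$t_p, 1)

  # variant switches exactly at the F-test threshold
  set.seed(31)
  for (i in 1:50) {
    a <- rnorm(3, 40, runif(1, 0.1, 3))
    b <- rnorm(4, 40, runif(1, 0.1, 3))
    res <- enc_group_test("g", a, b)
    fp <- stats::var.test(a, b)$p.value
    expect_identical(res$variant, if (fp >= 0.05) "pooled" else "welch")
  }
  expect_error(enc_group_test("g", 40, c(40, 41)), "two values")
})

test_that("GC content excludes N and supports third positions", {
  expect_identical(gc_content("GGCC"), 1)
  expect_identical(gc_content("ATGC"), 0.5)
  expect_identical(gc_content("ATNN"), 0)
  expect_true(is.na(gc_content("NNNN")))
  expect_identical(gc_content("AAGAAT", positions = "third"), 0.5)
  cc <- counts_from(GTA = 1, GTG = 1)
  expect_identical(gc_content(cc, positions = "third"), 0.5)
  expect_identical(gc_content(cc), 0.5)
})
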