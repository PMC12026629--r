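test_that("the invertebrate mitochondrial code has the expected families", {
  gc5 <- genetic_code(5L)
  expect_setequal(gc5$families[["L"]],
                  c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG"))
  expect_length(gc5$families[["S"]], 8L)  # UCN + AGN
  expect_setequal(gc5$families[["M"]], c("AUA", "AUG"))
  expect_setequal(gc5$families[["W"]], c("UGA", "UGG"))
  expect_setequal(gc5$families[["*"]], c("UAA", "UAG"))
  # families partition the 64 codons
  expect_setequal(unlist(gc5$families), rna_codons())
  expect_equal(sum(lengths(gc5$families)), 64L)
})

test_that("codon extraction reports start, stop and incomplete stops", {
  g <- circular_genome("ATGTAA")
  f <- gene_features("mini", "PCG", "+", 1, 6)
  cod <- extract_codons(g, f)
  expect_equal(cod$codons, c("AUG", "UAA"))
  expect_equal(cod$start_codon, "ATG")
  expect_equal(cod$stop_codon, "TAA")
  expect_false(cod$incomplete_stop)

  # atp8-sized CDS: 159 bp = 53 codons
  set.seed(61)
  body <- paste(sample(c("AAA", "CTT", "GGA", "TTC"), 51, TRUE), collapse = "")
  g2 <- circular_genome(paste0("ATT", body, "TAA"))
  cod2 <- extract_codons(g2, gene_features("atp8like", "PCG", "+", 1, 159))
  expect_length(cod2$codons, 53L)
  expect_equal(cod2$start_codon, "ATT")

  # nad4-sized CDS: 1339 = 446 codons + trailing T -> incomplete "T(AA)"
  body3 <- paste(sample(c("AAA", "CTT", "GGA", "TTC"), 445, TRUE), collapse = "")
  g3 <- circular_genome(paste0("ATG", body3, "T"))
  cod3 <- extract_codons(g3, gene_features("nad4like", "PCG", "+", 1, 1339))
  expect_length(cod3$codons, 446L)
  expect_equal(cod3$stop_codon, "T(AA)")
  expect_true(cod3$incomplete_stop)
  expect_equal(extract_codons(
    circular_genome("ATGAAATA"),
    gene_features("x", "PCG", "+", 1, 8))$stop_codon, "TA(A)")
  expect_error(extract_codons(circular_genome("ATGAA"),
                              gene_features("short", "PCG", "+", 1, 5)),
               "too short")
})

test_that("minus-strand extraction equals plus-strand on the flipped genome", {
  set.seed(62)
  for (i in 1:10) {
    L <- 120L
    s <- random_dna(L)
    st <- 13L; en <- 72L
    g <- circular_genome(s)
    minus <- extract_codons(g, gene_features("m", "PCG", "-", st, en))
    gflip <- circular_genome(revcomp(s))
    plus <- extract_codons(gflip, gene_features("p", "PCG", "+",
                                                L - en + 1L, L - st + 1L))
    expect_identical(minus$codons, plus$codons)
  }
})

test_that("RSCU reproduces the published leucine value and its invariants", {
  leu <- c(UUA = 305, UUG = 55, CUU = 115, CUC = 26, CUA = 62, CUG = 15)
  r <- rscu(leu)
  expect_equal(round(r[["UUA"]], 2), 3.17)
  expect_equal(sum(r), 6)  # family normalization
  # uniform usage -> RSCU exactly 1
  expect_equal(unname(rscu(c(GAU = 7, GAC = 7))), c(1, 1))
  # scale invariance
  expect_equal(rscu(leu * 13), r)
  # zero-total family
  expect_warning(r0 <- rscu(c(CAU = 0, CAC = 0)), "zero total")
  expect_equal(unname(r0), c(0, 0))
  expect_error(rscu(c(XXX = 5)), "valid RNA codons")
})

test_that("every published RSCU value is recomputed within 0.01", {
  cu <- caridina_codon_usage()
  r <- rscu(setNames(cu$count, cu$codon))
  expect_true(all(abs(r[cu$codon] - cu$rscu_published) <= 0.01 + 1e-9))
  # stop codons form a scored two-codon family: UAA 10 + UAG 2 = 12
  expect_equal(cu$count[cu$codon == "UAA"] + cu$count[cu$codon == "UAG"], 12)
  expect_equal(round(r[["UAA"]], 2), 1.67)
})

test_that("pooled codon counts recover the simulator's planted truth", {
  sim <- sim_fixture(1L)
  counts <- pooled_codon_counts(sim$genome)
  expect_identical(as.integer(counts), as.integer(sim$truth$codon_counts))
  # one-gene toy genome
  ag <- annotated_genome(circular_genome("ATGTAAAC"),
                         gene_features("mini", "PCG", "+", 1, 6))
  cnt <- pooled_codon_counts(ag)
  expect_equal(cnt[["AUG"]], 1L)
  expect_equal(cnt[["UAA"]], 1L)
  expect_equal(sum(cnt), 2L)
})

test_that("start/stop tabulation matches the published usage pattern", {
  sim <- sim_fixture(1L)
  ss <- start_stop_table(sim$genome)
  # six ATG starts: atp6, cob, cox2, cox3, nad4, nad4L
  expect_equal(unname(ss$start_counts[["ATG"]]), 6L)
  expect_setequal(ss$table$gene[ss$table$start_codon == "ATG"],
                  c("atp6", "cob", "cox2", "cox3", "nad4", "nad4L"))
  # TAG stops exactly cob and nad1
  expect_setequal(ss$table$gene[ss$table$stop_codon == "TAG"],
                  c("cob", "nad1"))
  # the one incomplete stop is nad4's T(AA)
  expect_equal(ss$n_incomplete, 1L)
  expect_equal(ss$table$gene[ss$table$incomplete_stop], "nad4")
})
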