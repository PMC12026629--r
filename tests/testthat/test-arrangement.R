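test_that("the census reproduces the published intergenic column exactly", {
  ag <- caridina_annotation()
  lay <- caridina_gene_layout()
  cen <- adjacency_census(ag)
  expect_identical(cen$gap, lay$intergenic)
  expect_equal(cen$gap[cen$upstream == "rrnL" & cen$downstream == "trnV"], 50L)
  expect_equal(cen$gap[cen$upstream == "trnL1" & cen$downstream == "rrnL"], -40L)
  # wrap-around record on the last feature's row
  expect_equal(cen$upstream[nrow(cen)], "trnY")
  expect_equal(cen$downstream[nrow(cen)], "cox1")
  expect_equal(cen$gap[nrow(cen)], 2L)
})

test_that("spacer/overlap summary matches the published census", {
  cen <- adjacency_census(caridina_annotation())
  s <- summarize_arrangement(cen)
  expect_equal(s$n_spacers, 16L)
  expect_equal(s$spacer_range, c(1L, 50L))
  expect_equal(unname(s$largest_spacer), c("rrnL", "trnV"))
  expect_equal(s$n_overlaps, 12L)
  expect_equal(s$overlap_range, c(1L, 40L))
  expect_equal(unname(s$largest_overlap), c("trnL1", "rrnL"))
})

test_that("abutting features on a closed circle have zero gaps", {
  ag <- annotated_genome(circular_genome(length = 10),
                         gene_features(c("a", "b"), "tRNA", "+",
                                       c(1, 6), c(5, 10)))
  cen <- adjacency_census(ag)
  expect_equal(cen$gap, c(0L, 0L))
  s <- summarize_arrangement(cen)
  expect_equal(c(s$n_spacers, s$n_overlaps), c(0L, 0L))
})

test_that("gaps plus feature lengths conserve the circle exactly", {
  set.seed(71)
  for (rep in 1:25) {
    L <- sample(300:600, 1L)
    n <- sample(4:10, 1L)
    starts <- sort(sample(seq_len(L - 40L), n))
    ends <- pmin(starts + sample(5:60, n, replace = TRUE), L)
    ag <- annotated_genome(circular_genome(length = L),
                           gene_features(paste0("g", seq_len(n)),
                                         "tRNA", "+", starts, ends))
    cen <- adjacency_census(ag)
    lens <- feature_length(starts, ends, L)
    expect_equal(sum(cen$gap) + sum(lens), L)
  }
})

test_that("the gene-order signature is anchored, signed and rotation-invariant", {
  ag <- caridina_annotation()
  sig <- gene_order_signature(ag)
  expect_match(sig, "^cox1 trnL2 cox2 trnK trnD atp8 ")
  expect_match(sig, "-nad5 ")  # minus-strand genes carry the sign

  # rotating all coordinates leaves the signature unchanged
  lay <- caridina_gene_layout()
  L <- caridina_genome_length()
  shift <- 4000L
  rot <- function(p) ((p + shift - 1L) %% L) + 1L
  ag_rot <- annotated_genome(circular_genome(length = L),
                             gene_features(lay$name, lay$category, lay$strand,
                                           rot(lay$start), rot(lay$end)))
  expect_identical(gene_order_signature(ag_rot), sig)
})

test_that("reverse-complementing the genome flips and reverses the signature", {
  lay <- caridina_gene_layout()
  L <- caridina_genome_length()
  ag <- caridina_annotation()
  rc <- annotated_genome(circular_genome(length = L),
                         gene_features(lay$name, lay$category,
                                       ifelse(lay$strand == "+", "-", "+"),
                                       L - lay$end + 1L, L - lay$start + 1L))
  got <- strsplit(gene_order_signature(rc), " ")[[1]]
  # expected: reverse the token order, flip every sign, re-anchor at cox1
  tok <- strsplit(gene_order_signature(ag), " ")[[1]]
  flipped <- rev(ifelse(startsWith(tok, "-"), sub("^-", "", tok),
                        paste0("-", tok)))
  k <- which(sub("^-", "", flipped) == "cox1")
  expected <- flipped[c(k:length(flipped), seq_len(k - 1L))]
  expect_identical(got, expected)
})

test_that("duplicate gene names are suffixed deterministically", {
  ag <- annotated_genome(circular_genome(length = 100),
                         gene_features(c("trnX", "trnX", "cox1"), "tRNA", "+",
                                       c(1, 30, 60), c(20, 50, 90)))
  sig <- gene_order_signature(ag)
  expect_equal(sig, "cox1 trnX trnX.2")
})
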