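test_that("a hand-built perfect cloverleaf is recovered exactly", {
  seq <- handmade_cloverleaf()  # 71 nt, all Watson-Crick stems
  expect_equal(nchar(seq), 7L + 2L + 16L + 1L + 17L + 4L + 17L + 7L)
  st <- fold_cloverleaf(seq)
  expect_false(st$fold_failed)
  expect_equal(unname(unlist(
    st$geometry[c("g1", "d", "d_loop", "g2", "t", "t_loop", "v")])),
    c(2L, 4L, 8L, 1L, 5L, 7L, 4L))
  expect_true(all(unlist(st$pair_labels) == "WC"))
  expect_equal(st$score, 2 * (7 + 4 + 5 + 5))
  expect_equal(st$anticodon, "UGC")
  # anticodon constraint accepts the planted triplet and rejects others
  expect_silent(fold_cloverleaf(seq, anticodon = "TGC"))
  expect_error(fold_cloverleaf(seq, anticodon = "GGG"), "anticodon")
})

test_that("a single planted wobble in the acceptor stem is censused once", {
  seq <- handmade_cloverleaf(acc = "GGCGGCA")
  # turn acceptor slot 2 (G against C) into G against U
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  ch[L - 1L] <- "U"
  st <- fold_cloverleaf(paste(ch, collapse = ""))
  census <- pair_census(st)
  expect_equal(unname(census[["GU"]]), 1L)
  expect_equal(unname(census[["WC"]]), 20L)
  expect_equal(sum(census), 21L)
})

test_that("folding score is invariant under the T/U alphabet choice", {
  seq_rna <- handmade_cloverleaf()
  seq_dna <- chartr("U", "T", seq_rna)
  a <- fold_cloverleaf(seq_rna)
  b <- fold_cloverleaf(seq_dna)
  expect_equal(a$score, b$score)
  expect_identical(structure_pairs(a), structure_pairs(b))
})

test_that("the search equals brute-force enumeration on random sequences", {
  set.seed(81)
  for (i in 1:20) {
    seq <- random_dna(sample(62:70, 1L))
    st <- fold_cloverleaf(seq)
    oracle <- brute_force_fold_score(seq)
    expect_equal(st$score, oracle$score, info = paste("case", i))
    expect_equal(st$geometry$g1, oracle$g1, info = paste("case", i))
  }
})

test_that("D-armless structures are detected and the margin is honoured", {
  armless <- handmade_cloverleaf(d_armless = TRUE, v = 6)
  st <- fold_cloverleaf(armless)
  expect_null(st$d_arm)
  expect_true(detect_missing_arms(st)$d_arm_absent)
  # a prohibitive margin suppresses the call
  expect_false(detect_missing_arms(st, margin = 1000)$d_arm_absent)
  full <- fold_cloverleaf(handmade_cloverleaf())
  expect_false(detect_missing_arms(full)$d_arm_absent)
})

test_that("the pair census is additive over structures", {
  a <- fold_cloverleaf(handmade_cloverleaf())
  b <- fold_cloverleaf(handmade_cloverleaf(d_armless = TRUE, v = 6))
  ca <- pair_census(a); cb <- pair_census(b)
  expect_identical(pair_census(list(a, b)), ca + cb)
  expect_equal(sum(pair_census(a)), 21L)
  expect_true(all(pair_census(a)[c("CC", "UU", "CA", "UC", "other")] == 0L))
})

test_that("sequences outside the tRNA size range are rejected", {
  expect_error(fold_cloverleaf(random_dna(40)), "outside supported range")
  expect_error(fold_cloverleaf(random_dna(90)), "outside supported range")
})

test_that("an unattainable minimum score flags fold failure", {
  cfg <- cloverleaf_config(min_score = 1000)
  expect_warning(st <- fold_cloverleaf(handmade_cloverleaf(), config = cfg),
                 "fold failure")
  expect_true(st$fold_failed)
  expect_s3_class(st, "cloverleaf")  # best partial structure still returned
})

test_that("planted structures are recovered at the documented rates", {
  plant <- mitochar:::plant_cloverleaf
  # all-WC plants: exact recovery in every one of 200 seeded draws
  set.seed(777)
  ok <- 0L
  for (i in 1:200) {
    pl <- plant(sample(62:70, 1L))
    st <- fold_cloverleaf(pl$seq)
    ok <- ok + identical(structure_pairs(st),
                         pl$pairs[order(pl$pairs[, 1L]), , drop = FALSE])
  }
  expect_equal(ok, 200L)
  # with up to two planted mismatch slots: at least 95% recovery
  set.seed(778)
  ok2 <- 0L
  for (i in 1:200) {
    mm <- sample(c("GU", "CC", "UU", "CA", "UC"), sample(1:2, 1L),
                 replace = TRUE)
    pl <- plant(sample(62:70, 1L), mismatches = mm)
    st <- fold_cloverleaf(pl$seq)
    ok2 <- ok2 + identical(structure_pairs(st),
                           pl$pairs[order(pl$pairs[, 1L]), , drop = FALSE])
  }
  expect_gte(ok2, 190L)
})

test_that("dot-bracket output is balanced and matches the pair count", {
  st <- fold_cloverleaf(handmade_cloverleaf())
  db <- as_dot_bracket(st)
  expect_equal(nchar(db), st$length)
  expect_equal(lengths(regmatches(db, gregexpr("(", db, fixed = TRUE))), 21L)
  expect_equal(lengths(regmatches(db, gregexpr(")", db, fixed = TRUE))), 21L)
})
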