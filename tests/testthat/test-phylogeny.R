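test_that("supermatrix concatenation records partitions and gap-fills", {
  alns <- list(g1 = c(A = "AAAAAAAAAA", B = "CCCCCCCCCC", C = "GGGGGGGGGG"),
               g2 = c(A = strrep("AT", 10), B = strrep("GC", 10),
                      C = strrep("TA", 10)))
  sm <- concat_supermatrix(alns)
  expect_equal(sm$ncol, 30L)
  expect_true(all(nchar(sm$seqs) == 30L))
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 30L))

  # missing taxon gap-filled with a warning
  alns$g2 <- alns$g2[c("A", "B")]
  expect_warning(sm2 <- concat_supermatrix(alns), "gap-filled: C")
  expect_equal(substr(sm2$seqs[["C"]], 11L, 30L), strrep("-", 20L))

  expect_error(concat_supermatrix(list(g1 = c(A = "AAA", B = "AAAA"))),
               "alignment error in gene 'g1'")
})

test_that("partition spans always tile the columns", {
  set.seed(91)
  for (rep in 1:20) {
    ng <- sample(2:5, 1L)
    alns <- lapply(seq_len(ng), function(g) {
      w <- sample(5:30, 1L)
      setNames(vapply(1:4, function(i) random_dna(w), character(1)),
               paste0("t", 1:4))
    })
    names(alns) <- paste0("g", seq_len(ng))
    sm <- concat_supermatrix(alns)
    expect_equal(sm$partitions$start,
                 c(1L, head(sm$partitions$end, -1L) + 1L))
    expect_equal(sm$partitions$end[ng], sm$ncol)
  }
})

test_that("p-distances match direct column counting", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  set.seed(92)
  for (rep in 1:100) {
    w <- sample(10:60, 1L)
    seqs <- setNames(vapply(1:3, function(i) {
      s <- strsplit(random_dna(w), "")[[1]]
      s[runif(w) < 0.15] <- "-"
      paste(s, collapse = "")
    }, character(1)), c("x", "y", "z"))
    d <- tryCatch(p_distance_matrix(seqs), error = function(e) NULL)
    if (is.null(d)) next  # a pair with no comparable columns
    for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
      a <- strsplit(seqs[[pair[1L]]], "")[[1]]
      b <- strsplit(seqs[[pair[2L]]], "")[[1]]
      use <- a != "-" & b != "-"
      expect_equal(d[pair[1L], pair[2L]], sum(a[use] != b[use]) / sum(use))
    }
  }
  expect_error(p_distance_matrix(c(a = "A---", b = "-CCC")),
               "no comparable columns")
})

test_that("Poisson correction applies -log(1 - p)", {
  d0 <- p_distance_matrix(c(a = "AAAA", b = "AATT"))
  d1 <- p_distance_matrix(c(a = "AAAA", b = "AATT"), correction = "poisson")
  expect_equal(d1["a", "b"], -log(1 - d0["a", "b"]))
})

test_that("NJ recovers a known additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):5,(C:3,D:4)); path-sum distances are additive
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 9
  d["A", "D"] <- d["D", "A"] <- 10
  d["B", "C"] <- d["C", "B"] <- 10
  d["B", "D"] <- d["D", "B"] <- 11
  d["C", "D"] <- d["D", "C"] <- 7
  t <- neighbor_joining(d)
  expect_s3_class(t, "phylo")
  expect_true(is_monophyletic(root_with_outgroup(t, "D"), c("A", "B")))
  # all pairwise path lengths reproduced
  expect_equal(ape::cophenetic.phylo(t)[rownames(d), colnames(d)], d)
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t <- neighbor_joining(d)
  bl <- setNames(t$edge.length[match(1:3, t$edge[, 2L])], t$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0, 2, 3))
})

test_that("NJ is consistent on additive matrices and agrees with ape", {
  set.seed(93)
  for (rep in 1:25) {
    n <- sample(4:10, 1L)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    d <- path_sum_distances(tr)
    mine <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), mine), 0)
    # independent implementation oracle
    expect_equal(phangorn::RF.dist(ape::nj(d), mine), 0)
  }
})

test_that("NJ matches hierarchical-clustering truth on ultrametric data", {
  set.seed(94)
  tr <- ape::rcoal(8)  # ultrametric
  d <- path_sum_distances(tr)
  mine <- neighbor_joining(d)
  hc <- hclust(as.dist(d), method = "average")
  upgma <- ape::as.phylo(hc)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(upgma), mine)), 0)
})

test_that("asymmetric input is rejected", {
  d <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(d), "symmetric")
})

test_that("outgroup rooting is midpoint-on-pendant-edge and idempotent", {
  t <- read_newick("((A:1,B:2):0.5,(C:3,D:4):0.25);")
  rt <- root_with_outgroup(t, "D")
  expect_true(ape::is.rooted(rt))
  # D is sister to all others
  expect_true(is_monophyletic(rt, c("A", "B", "C")))
  # leaf-to-leaf path lengths preserved
  expect_equal(ape::cophenetic.phylo(rt)[t$tip.label, t$tip.label],
               ape::cophenetic.phylo(t)[t$tip.label, t$tip.label])
  rt2 <- root_with_outgroup(rt, "D")
  expect_equal(as.numeric(ape::dist.topo(rt, rt2)), 0)
  expect_error(root_with_outgroup(t, "Z"), "unknown taxon")
})

test_that("monophyly queries agree with brute-force clade enumeration", {
  t <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(t, c("A", "B")))
  expect_false(is_monophyletic(t, c("A", "C")))
  expect_error(is_monophyletic(t, c("A", "Q")), "unknown taxa")
  set.seed(95)
  for (rep in 1:20) {
    tr <- ape::rtree(10)
    clades <- all_clades(tr)
    for (q in 1:5) {
      qset <- sort(sample(tr$tip.label, sample(2:9, 1L)))
      truth <- any(vapply(clades, identical, logical(1), qset))
      expect_equal(is_monophyletic(tr, qset), truth)
    }
  }
})

test_that("Newick round trips preserve topology and branch lengths", {
  txt <- "((A:1,B:2):0.5,C:3);"
  t <- read_newick(txt)
  expect_equal(write_newick(t), txt)
  t2 <- read_newick("((sp_one:1.5,sp_two:2):1,out_group:4);")
  expect_setequal(t2$tip.label, c("sp_one", "sp_two", "out_group"))
  expect_error(read_newick("((A:1,B:2:0.5;"), "unbalanced")
  set.seed(96)
  for (rep in 1:20) {
    tr <- ape::rtree(sample(4:12, 1L))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})
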