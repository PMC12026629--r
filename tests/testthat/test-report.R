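test_that("unknown configuration keys are rejected", {
  expect_error(run_config(inptu = "x"), "unknown config keys")
  cfg <- run_config(seed = 3L)
  expect_equal(cfg$code, 5L)
  expect_equal(cfg$correction, "none")
})

test_that("characterization writes the five-report bundle", {
  sim <- sim_fixture(1L)
  out <- withr::local_tempdir()
  res <- suppressMessages(
    run_characterize(run_config(input = sim$genome, out_dir = out)))
  expect_true(all(file.exists(res$paths)))
  expect_setequal(basename(res$paths),
                  c("gene_table.tsv", "composition.tsv", "codon_usage.tsv",
                    "arrangement.tsv", "trna_structures.tsv"))
  expect_equal(nrow(res$composition), 18L)
  expect_equal(nrow(res$gene_table), 38L)
  expect_equal(nrow(res$codon_usage), 64L)
  expect_length(res$structures, 22L)
  # the nonstandard cox1 start is logged with its stable code
  expect_message(
    run_characterize(run_config(input = sim$genome,
                                out_dir = withr::local_tempdir())),
    "NONSTD_START: cox1")
})

test_that("characterization reruns are byte-identical", {
  sim <- sim_fixture(1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- suppressMessages(
    run_characterize(run_config(input = sim$genome, out_dir = d1)))
  r2 <- suppressMessages(
    run_characterize(run_config(input = sim$genome, out_dir = d2)))
  for (k in seq_along(r1$paths))
    expect_identical(readLines(r1$paths[[k]]), readLines(r2$paths[[k]]))
})

test_that("the genetic-code id changes RSCU families", {
  sim <- sim_fixture(1L)
  out5 <- suppressMessages(run_characterize(
    run_config(input = sim$genome, out_dir = withr::local_tempdir(),
               code = 5L)))
  out2 <- suppressMessages(run_characterize(
    run_config(input = sim$genome, out_dir = withr::local_tempdir(),
               code = 2L)))
  # AGA is Ser under code 5 but a stop under code 2
  aa5 <- out5$codon_usage$aa[out5$codon_usage$codon == "AGA"]
  aa2 <- out2$codon_usage$aa[out2$codon_usage$codon == "AGA"]
  expect_equal(aa5, "S")
  expect_equal(aa2, "*")
  expect_false(identical(out5$codon_usage$rscu, out2$codon_usage$rscu))
})

test_that("the phylogeny run produces a tree, distances and query answers", {
  set.seed(101)
  tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.2))
  tr$tip.label <- c("caridina", "neocaridina", "typhlatya", "outgroup")
  alns <- list(g1 = evolve_alignment(tr, "poisson", 400, seed = 1),
               g2 = evolve_alignment(tr, "poisson", 300, seed = 2))
  dirin <- withr::local_tempdir()
  paths <- file.path(dirin, c("g1.fasta", "g2.fasta"))
  write_fasta(alns$g1, paths[1L]); write_fasta(alns$g2, paths[2L])
  out <- withr::local_tempdir()
  res <- suppressMessages(run_phylo(run_config(
    input = paths, out_dir = out, outgroup = "outgroup",
    queries = list(ingroup = c("caridina", "neocaridina", "typhlatya")))))
  expect_equal(sort(res$tree$tip.label), sort(tr$tip.label))
  expect_true(file.exists(res$paths[["tree"]]))
  expect_true(file.exists(res$paths[["distances"]]))
  expect_true(res$monophyly[["ingroup"]])
  expect_equal(res$supermatrix$ncol, 700L)
  # error paths
  expect_error(suppressMessages(run_phylo(run_config(
    input = paths, out_dir = out, outgroup = "nosuch"))), "outgroup")
  expect_error(suppressMessages(run_phylo(run_config(
    input = list(g1 = alns$g1[1:2]), out_dir = out))), "at least 3 taxa")
})

test_that("the command-line front end runs a characterization", {
  cli <- system.file("cli", "mitochar.R", package = "mitochar")
  expect_true(nzchar(cli))
  sim <- sim_fixture(1L)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, gb)
  out <- withr::local_tempdir()
  status <- system2("Rscript", c(cli, "characterize", "--input", gb,
                                 "--out-dir", out),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "composition.tsv")))
  comp <- read.table(file.path(out, "composition.tsv"), sep = "\t",
                     header = TRUE, check.names = FALSE)
  expect_equal(nrow(comp), 18L)
  # missing input is a usage error with non-zero exit
  status2 <- system2("Rscript", c(cli, "characterize", "--out-dir", out),
                     stdout = FALSE, stderr = FALSE)
  expect_gt(status2, 0L)
})
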