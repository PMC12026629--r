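# Report bundle and run configuration: the programmatic face of the
# command-line front end (inst/cli/mitochar.R is a thin wrapper over these).

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolved run configuration
#'
#' Validates and completes a configuration for [run_characterize()] /
#' [run_phylo()]. Unknown keys are rejected so typos fail loudly; the full
#' resolved configuration is echoed to standard error at run time so every
#' run is reproducible from its log.
#'
#' @param ... configuration keys: `input` (GenBank path or
#'   `annotated_genome`), `out_dir`, `code` (genetic-code id, default 5),
#'   `seed` (default 1), `outgroup`, `correction` (`"none"`/`"poisson"`),
#'   `queries` (named list of taxon sets for monophyly tests),
#'   `fold_config` (a [cloverleaf_config()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(input = NULL, out_dir = ".", code = 5L, seed = 1L,
                   outgroup = NULL, correction = "none", queries = NULL,
                   fold_config = cloverleaf_config())
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

log_config <- function(cfg, what) {
  flat <- vapply(cfg[c("out_dir", "code", "seed", "correction")],
                 function(x) paste(format(x), collapse = ","), character(1))
  message(what, " config: ",
          paste(names(flat), flat, sep = "=", collapse = " "))
}

#' Characterize an annotated mitogenome into a report bundle
#'
#' Runs the full characterization pipeline and writes five tab-separated
#' reports to `out_dir`: the gene arrangement table (`gene_table.tsv`), the
#' per-partition composition and skew table (`composition.tsv`), the codon
#' count/RSCU table (`codon_usage.tsv`), the adjacency census with its
#' spacer/overlap summary (`arrangement.tsv`), and the tRNA structure report
#' with dot-bracket strings and the pair-class census
#' (`trna_structures.tsv`). Warnings are logged to standard error with
#' stable codes (e.g. `NONSTD_START`).
#'
#' @param config a [run_config()] whose `input` is a GenBank flat-file path
#'   or an `annotated_genome` with sequence.
#' @return invisibly, a list with the report paths and the in-memory tables.
#' @export
run_characterize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop("usage error: config$input is required")
  ag <- if (inherits(config$input, "annotated_genome")) config$input else
    read_genbank(config$input)
  log_config(config, "characterize")
  code <- genetic_code(config$code)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir,
                   c("gene_table.tsv", "composition.tsv", "codon_usage.tsv",
                     "arrangement.tsv", "trna_structures.tsv"))
  names(out) <- c("gene_table", "composition", "codon_usage", "arrangement",
                  "trna")

  gt <- write_gene_table(ag, out[["gene_table"]], code)
  nonstd <- gt$gene[!is.na(gt$start_codon) & gt$direction %in% c("+", "-") &
                      !gt$start_codon %in% code$start_codons &
                      gt$gene %in% ag$features$name[ag$features$category == "PCG"]]
  for (g in nonstd)
    message("WARN NONSTD_START: ", g, " starts with ",
            gt$start_codon[gt$gene == g])

  comp <- composition_report_table(partition_report(ag))
  write_tsv(comp, out[["composition"]])

  cu <- codon_usage_table(pooled_codon_counts(ag, code), code)
  cu$rscu <- round(cu$rscu, 2)
  write_tsv(cu, out[["codon_usage"]])

  cen <- adjacency_census(ag)
  smry <- summarize_arrangement(cen)
  arr <- cen
  arr$note <- ifelse(arr$gap > 0, "spacer", ifelse(arr$gap < 0, "overlap", ""))
  write_tsv(arr, out[["arrangement"]])
  message("arrangement: ", smry$n_spacers, " spacers (",
          paste(smry$spacer_range, collapse = "-"), " bp), ",
          smry$n_overlaps, " overlaps (",
          paste(smry$overlap_range, collapse = "-"), " bp)")

  fe <- ag$features
  trna_idx <- which(fe$category == "tRNA")
  structures <- list()
  trna_rows <- list()
  for (i in trna_idx) {
    f <- fe[i, ]
    st <- fold_cloverleaf(extract_sense_sequence(ag$genome, f),
                          anticodon = if (!is.na(f$anticodon)) f$anticodon,
                          config = config$fold_config)
    structures[[f$name]] <- st
    trna_rows[[f$name]] <- data.frame(
      gene = f$name, length = st$length, score = st$score,
      d_arm_absent = detect_missing_arms(st)$d_arm_absent,
      anticodon = st$anticodon, dot_bracket = as_dot_bracket(st),
      stringsAsFactors = FALSE)
  }
  if (length(structures)) {
    trna_tab <- do.call(rbind, c(trna_rows, list(make.row.names = FALSE)))
    write_tsv(trna_tab, out[["trna"]])
    census <- pair_census(structures)
    message("tRNA pair census: ",
            paste(names(census), census, sep = "=", collapse = " "))
  } else {
    write_tsv(data.frame(gene = character()), out[["trna"]])
    census <- NULL
  }
  invisible(list(paths = out, gene_table = gt, composition = comp,
                 codon_usage = cu, arrangement = arr, summary = smry,
                 structures = structures, pair_census = census))
}

#' Distance phylogeny from per-gene alignments
#'
#' Reads per-gene aligned FASTA files, concatenates them into a supermatrix,
#' computes the pairwise p-distance matrix (optionally Poisson-corrected),
#' infers a neighbor-joining tree, roots it on the configured outgroup if
#' given, evaluates any monophyly queries, and writes `tree.nwk` and
#' `distances.tsv` to `out_dir`.
#'
#' @param config a [run_config()] whose `input` is a character vector of
#'   aligned FASTA paths (or a named list of in-memory alignments).
#' @return invisibly, list with `tree` (`phylo`), `distances` (matrix),
#'   `supermatrix`, `monophyly` (named logical, if queried), and the output
#'   paths.
#' @export
run_phylo <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop("usage error: config$input is required")
  alns <- if (is.list(config$input)) config$input else {
    paths <- config$input
    nm <- sub("\\.(fa|fasta|fas)$", "", basename(paths), ignore.case = TRUE)
    setNames(lapply(paths, read_alignment_fasta), nm)
  }
  log_config(config, "phylo")
  sm <- concat_supermatrix(alns)
  if (length(sm$taxa) < 3L)
    stop("inference error: at least 3 taxa required, got ", length(sm$taxa))
  message("supermatrix: ", length(sm$taxa), " taxa, ", sm$ncol, " columns, ",
          nrow(sm$partitions), " partitions")
  d <- p_distance_matrix(sm, correction = config$correction)
  tree <- neighbor_joining(d)
  if (!is.null(config$outgroup)) {
    if (!config$outgroup %in% sm$taxa)
      stop("usage error: outgroup '", config$outgroup, "' not among taxa")
    tree <- root_with_outgroup(tree, config$outgroup)
  }
  mono <- NULL
  if (!is.null(config$queries)) {
    mono <- vapply(config$queries, function(q) is_monophyletic(tree, q),
                   logical(1))
    for (nm in names(mono))
      message("monophyly ", nm, ": ", mono[[nm]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(config$out_dir, "tree.nwk")
  dist_path <- file.path(config$out_dir, "distances.tsv")
  write_newick(tree, tree_path)
  write_tsv(data.frame(taxon = rownames(d), as.data.frame(d),
                       check.names = FALSE), dist_path)
  invisible(list(tree = tree, distances = d, supermatrix = sm,
                 monophyly = mono, paths = c(tree = tree_path,
                                             distances = dist_path)))
}

# Alignment FASTA reader: like read_fasta but permits amino-acid letters
# and gap characters.
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- startsWith(lines, ">")
  if (length(lines) == 0L || !hdr[1L])
    stop("FASTA format error in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                 character(1))
  out <- setNames(rep("", sum(hdr)), ids)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out)))
    stop("FASTA format error in ", path, ": record with no sequence")
  out
}

#' Simulate a genome and write its file bundle
#'
#' Convenience front end over [simulate_genome()]: writes the simulated
#' genome as FASTA and GenBank plus a tab-separated truth-manifest summary
#' (adjacency gaps, codon counts, start/stop codons, tRNA pair census).
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... further arguments to [simulate_genome()].
#' @return invisibly, the [simulate_genome()] result with a `paths` element.
#' @export
run_simulate <- function(out_dir = ".", seed = 1L, ...) {
  sim <- simulate_genome(seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("genome.fasta", "genome.gb",
                                "truth_adjacency.tsv", "truth_codons.tsv",
                                "truth_start_stop.tsv", "truth_census.tsv"))
  names(paths) <- c("fasta", "genbank", "adjacency", "codons", "start_stop",
                    "census")
  write_fasta(setNames(sim$genome$genome$sequence,
                       sprintf("simulated_mitogenome seed=%d", seed)),
              paths[["fasta"]])
  write_genbank(sim$genome, paths[["genbank"]],
                locus_name = "SIMMITO")
  write_tsv(sim$truth$adjacency, paths[["adjacency"]])
  write_tsv(data.frame(codon = names(sim$truth$codon_counts),
                       count = as.integer(sim$truth$codon_counts)),
            paths[["codons"]])
  ss <- do.call(rbind, sim$truth$start_stop)
  write_tsv(data.frame(gene = rownames(ss), start = ss[, "start"],
                       stop = ss[, "stop"]), paths[["start_stop"]])
  write_tsv(data.frame(label = names(sim$truth$pair_census),
                       count = as.integer(sim$truth$pair_census)),
            paths[["census"]])
  sim$paths <- paths
  invisible(sim)
}
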