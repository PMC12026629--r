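#' Extract codons from a protein-coding gene
#'
#' Splits the feature's sense-strand sequence into consecutive triplets. When
#' the length is not a multiple of three, the trailing 1-2 nt are an
#' incomplete stop codon - completed to TAA by post-transcriptional
#' polyadenylation - reported in the parenthesized form `"T(AA)"` or
#' `"TA(A)"` and excluded from the codon list. A complete terminal stop codon
#' is part of the codon list.
#'
#' @param genome a `circular_genome` with sequence.
#' @param pcg a one-row feature of category `"PCG"`.
#' @param code a [genetic_code()] (used for display only; extraction itself
#'   is code-agnostic).
#' @return list with `codons` (RNA-alphabet character vector), `start_codon`
#'   (DNA), `stop_codon` (DNA, possibly parenthesized incomplete form) and
#'   `incomplete_stop` (logical).
#' @examples
#' g <- circular_genome("ATGAAATAA")
#' f <- gene_features("toy", "PCG", "+", 1, 9)
#' extract_codons(g, f)$codons
#' @export
extract_codons <- function(genome, pcg, code = genetic_code(5L)) {
  if (!identical(as.character(pcg$category), "PCG"))
    stop("extract_codons expects a PCG feature")
  seq <- extract_sense_sequence(genome, pcg)
  n <- nchar(seq)
  if (n < 6L) stop("coding sequence too short (", n, " nt)")
  rem <- n %% 3L
  n_cod <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  codons_dna <- substring(seq, starts, starts + 2L)
  start_codon <- codons_dna[1L]
  if (rem == 0L) {
    stop_codon <- codons_dna[n_cod]
    incomplete <- FALSE
  } else {
    partial <- substr(seq, n - rem + 1L, n)
    stop_codon <- paste0(partial, "(", substr("TAA", rem + 1L, 3L), ")")
    incomplete <- TRUE
  }
  list(codons = chartr("T", "U", codons_dna), start_codon = start_codon,
       stop_codon = stop_codon, incomplete_stop = incomplete)
}

#' Pooled codon counts over all protein-coding genes
#'
#' Sums the per-gene codon lists of every PCG of the annotation. Counts are
#' reported over the RNA alphabet; complete terminal stop codons are counted,
#' incomplete stops are not, so an annotation with one T(AA)-terminated gene
#' contributes one fewer stop than it has PCGs.
#'
#' @param ag an `annotated_genome` with sequence.
#' @param code a [genetic_code()].
#' @return named integer vector over the 64 RNA codons (standard UUU..GGG
#'   order), class `codon_count_table`.
#' @export
pooled_codon_counts <- function(ag, code = genetic_code(5L)) {
  stopifnot(inherits(ag, "annotated_genome"))
  pcg <- ag$features[ag$features$category == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0L) stop("annotation contains no PCG features")
  counts <- setNames(integer(64L), rna_codons())
  for (i in seq_len(nrow(pcg))) {
    cod <- extract_codons(ag$genome, pcg[i, ], code)$codons
    cod <- cod[cod %in% names(counts)]  # codons containing N are not counted
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(counts, class = c("codon_count_table", "integer"))
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F, `RSCU(c) = count(c) * |F| / sum(F)`:
#' the observed count relative to the expectation under uniform usage within
#' the family. Stop codons form a regular (two-codon, under table 5) family
#' and receive RSCU values like any other. A family with zero total yields
#' RSCU 0 for all its codons, with a warning.
#'
#' @param counts named count vector over RNA codons (any subset of the 64;
#'   as from [pooled_codon_counts()] or entered by hand).
#' @param code a [genetic_code()].
#' @return named numeric vector of RSCU values over the codons present in
#'   `counts`.
#' @examples
#' leu <- c(UUA = 305, UUG = 55, CUU = 115, CUC = 26, CUA = 62, CUG = 15)
#' round(rscu(leu), 2)[["UUA"]]
#' @export
rscu <- function(counts, code = genetic_code(5L)) {
  codons <- names(counts)
  if (is.null(codons) || !all(codons %in% names(code$codon_aa)))
    stop("counts must be named by valid RNA codons")
  if (anyDuplicated(codons)) stop("duplicate codon keys")
  counts <- as.numeric(counts)
  aa <- code$codon_aa[codons]
  out <- setNames(numeric(length(codons)), codons)
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam_size <- length(code$families[[a]])
    tot <- sum(counts[idx])
    if (tot == 0) {
      warning("synonymous family '", a, "' has zero total count; RSCU set to 0")
      out[idx] <- 0
    } else {
      out[idx] <- counts[idx] * fam_size / tot
    }
  }
  out
}

#' Per-gene start/stop codon table
#'
#' Tabulates the observed start and stop codon of every PCG and summarizes
#' usage: how many genes start with each codon, stop with each complete
#' codon, and how many carry an incomplete stop.
#'
#' @param ag an `annotated_genome` with sequence.
#' @param code a [genetic_code()].
#' @return list with `table` (gene, start_codon, stop_codon,
#'   incomplete_stop), `start_counts`, `stop_counts` (complete stops only)
#'   and `n_incomplete`.
#' @export
start_stop_table <- function(ag, code = genetic_code(5L)) {
  stopifnot(inherits(ag, "annotated_genome"))
  pcg <- ag$features[ag$features$category == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0L) stop("annotation contains no PCG features")
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    cod <- extract_codons(ag$genome, pcg[i, ], code)
    data.frame(gene = pcg$name[i], start_codon = cod$start_codon,
               stop_codon = cod$stop_codon,
               incomplete_stop = cod$incomplete_stop,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  complete <- tab$stop_codon[!tab$incomplete_stop]
  list(table = tab,
       start_counts = table(tab$start_codon),
       stop_counts = table(complete),
       n_incomplete = sum(tab$incomplete_stop))
}

#' Codon usage report in standard table layout
#'
#' Combines counts and RSCU into one data frame over all 64 codons in the
#' standard UUU..GGG order, annotated with the encoded amino acid.
#'
#' @param counts named counts over RNA codons (missing codons count 0).
#' @param code a [genetic_code()].
#' @return data frame with columns `codon`, `aa`, `count`, `rscu`.
#' @export
codon_usage_table <- function(counts, code = genetic_code(5L)) {
  full <- setNames(numeric(64L), rna_codons())
  full[names(counts)] <- as.numeric(counts)
  r <- rscu(full, code)
  data.frame(codon = names(full), aa = unname(code$codon_aa[names(full)]),
             count = unname(full), rscu = unname(r),
             stringsAsFactors = FALSE)
}
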