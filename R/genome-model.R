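#' Circular genome object
#'
#' A minimal container for a circular DNA molecule. Either the sequence, or
#' just a length (for coordinate-only work such as the adjacency census),
#' may be supplied.
#'
#' @param sequence single DNA string over A/C/G/T/N (case-insensitive; U is
#'   normalized to T), or `NULL` for a coordinate-only genome.
#' @param length genome length in bp; required when `sequence` is `NULL`,
#'   otherwise inferred.
#' @return an object of class `circular_genome` with elements `sequence`
#'   (string or `NULL`) and `length`.
#' @examples
#' g <- circular_genome("ACGTACGT")
#' g$length
#' @export
circular_genome <- function(sequence = NULL, length = NULL) {
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    sequence <- normalize_dna(sequence)
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
      stop("sequence contains non-IUPAC characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    }
    if (is.null(length)) length <- nchar(sequence)
    if (length != nchar(sequence)) stop("length does not match sequence")
  } else if (is.null(length)) {
    stop("either sequence or length must be given")
  }
  structure(list(sequence = sequence, length = as.integer(length)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("Circular genome, ", x$length, " bp",
      if (is.null(x$sequence)) " (coordinates only)", "\n", sep = "")
  invisible(x)
}

# Uppercase, U -> T.
normalize_dna <- function(x) chartr("U", "T", toupper(x))

#' Reverse complement of a DNA string
#'
#' @param x single DNA string (A/C/G/T/N).
#' @return the reverse complement, as a string.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build a gene-feature table
#'
#' Features are held as an ordinary data frame; this constructor checks
#' column types and coordinate sanity so downstream code can rely on them.
#'
#' @param name gene names.
#' @param category one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"` per feature.
#' @param strand `"+"` or `"-"` per feature.
#' @param start,end 1-based inclusive coordinates on the plus strand; a
#'   feature that wraps the origin has `start > end`.
#' @param anticodon optional 3-letter DNA anticodon (tRNAs).
#' @param start_codon,stop_codon optional annotated codons (PCGs); stop may
#'   use the incomplete form `"T(AA)"`.
#' @return data frame with one row per feature.
#' @export
gene_features <- function(name, category, strand, start, end,
                          anticodon = NA_character_,
                          start_codon = NA_character_,
                          stop_codon = NA_character_) {
  n <- length(name)
  stopifnot(length(start) == n, length(end) == n)
  category <- rep_len(as.character(category), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(category %in% c("PCG", "tRNA", "rRNA", "CR")))
    stop("unknown feature category")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(name = as.character(name), category = category,
             strand = strand,
             start = as.integer(start), end = as.integer(end),
             anticodon = rep_len(as.character(anticodon), n),
             start_codon = rep_len(as.character(start_codon), n),
             stop_codon = rep_len(as.character(stop_codon), n),
             stringsAsFactors = FALSE)
}

#' Annotated circular genome
#'
#' Binds a [circular_genome()] to an ordered feature table. Features are
#' sorted by plus-strand start position; at most one control-region (CR)
#' feature is permitted.
#'
#' @param genome a `circular_genome`, a raw DNA string, or an integer length.
#' @param features a feature data frame as built by [gene_features()].
#' @return object of class `annotated_genome` with elements `genome` and
#'   `features`.
#' @export
annotated_genome <- function(genome, features) {
  if (is.character(genome)) genome <- circular_genome(genome)
  if (is.numeric(genome)) genome <- circular_genome(length = genome)
  stopifnot(inherits(genome, "circular_genome"), is.data.frame(features))
  if (nrow(features) == 0L) stop("annotation must contain at least one feature")
  if (any(features$start < 1L | features$start > genome$length |
          features$end < 1L | features$end > genome$length))
    stop("feature coordinates outside genome [1, ", genome$length, "]")
  if (sum(features$category == "CR") > 1L)
    stop("at most one control-region feature is permitted")
  o <- order(features$start, features$end, features$name)
  features <- features[o, , drop = FALSE]
  rownames(features) <- NULL
  structure(list(genome = genome, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated circular genome, ", x$genome$length, " bp, ",
      nrow(x$features), " features (",
      paste(names(table(x$features$category)),
            table(x$features$category), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Feature length on a circular genome
#'
#' Length in bp of a 1-based inclusive interval, wrapping the origin when
#' `start > end`.
#'
#' @param start,end coordinates (vectorized).
#' @param genome_length circle length in bp.
#' @return integer vector of lengths.
#' @examples
#' feature_length(12609, 13405, 15581)  # 797
#' @export
feature_length <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L | end < 1L | start > genome_length | end > genome_length))
    stop("coordinates outside genome [1, ", genome_length, "]")
  ifelse(start <= end, end - start + 1L,
         (genome_length - start + 1L) + end)
}

#' Extract the sense-strand sequence of a feature
#'
#' Returns the feature's coding-strand sequence: the plus-strand substring
#' `start..end` (wrapping the origin when `start > end`), reverse-complemented
#' for minus-strand features.
#'
#' @param genome a `circular_genome` with sequence.
#' @param feature a one-row feature data frame or list with `strand`,
#'   `start`, `end`.
#' @return DNA string whose length equals [feature_length()].
#' @export
extract_sense_sequence <- function(genome, feature) {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  s <- as.integer(feature$start); e <- as.integer(feature$end)
  L <- genome$length
  if (s < 1L || e < 1L || s > L || e > L)
    stop("coordinates outside genome [1, ", L, "]")
  seq <- if (s <= e) substr(genome$sequence, s, e) else
    paste0(substr(genome$sequence, s, L), substr(genome$sequence, 1L, e))
  if (identical(as.character(feature$strand), "-")) revcomp(seq) else seq
}

#' Sense sequences for every feature of an annotated genome
#'
#' @param ag an `annotated_genome` with sequence.
#' @return named character vector, one sense sequence per feature, in
#'   plus-strand start order.
#' @export
feature_sequences <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  out <- vapply(seq_len(nrow(ag$features)), function(i)
    extract_sense_sequence(ag$genome, ag$features[i, ]), character(1))
  names(out) <- ag$features$name
  out
}

#' Validate PCG start/stop annotation against the sequence
#'
#' For each protein-coding gene, the annotated start codon is compared with
#' the first sense triplet and the annotated stop with the final (possibly
#' incomplete) triplet. A nonstandard but correctly annotated start (such as
#' the CAA start of cox1 in *C. mariae*) is reported as a warning, not a
#' failure. Strand usage is summarized for the whole annotation.
#'
#' @param ag an `annotated_genome` with sequence.
#' @param code a [genetic_code()]; used for the set of conventional starts.
#' @return list with `pcg` (per-gene data frame: observed/annotated codons,
#'   `status` of PASS/WARN/FAIL and a note), `strand_counts` (features per
#'   strand) and counts `n_warn`, `n_fail`.
#' @export
validate_annotation <- function(ag, code = genetic_code(5L)) {
  stopifnot(inherits(ag, "annotated_genome"))
  fe <- ag$features
  pcg <- fe[fe$category == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    f <- pcg[i, ]
    cod <- extract_codons(ag$genome, f, code)
    status <- "PASS"; note <- ""
    if (!is.na(f$start_codon) && f$start_codon != cod$start_codon) {
      status <- "FAIL"; note <- "annotated start differs from sequence"
    } else if (!cod$start_codon %in% code$start_codons) {
      status <- "WARN"
      note <- paste0("nonstandard start codon ", cod$start_codon)
    }
    if (!is.na(f$stop_codon) && f$stop_codon != cod$stop_codon) {
      status <- "FAIL"
      note <- paste(note, "annotated stop differs from sequence", sep = "; ")
    }
    data.frame(gene = f$name, start_observed = cod$start_codon,
               start_annotated = f$start_codon,
               stop_observed = cod$stop_codon, stop_annotated = f$stop_codon,
               status = status, note = sub("^; ", "", note),
               stringsAsFactors = FALSE)
  })
  pcg_report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  strand_counts <- c(plus = sum(fe$strand == "+"),
                     minus = sum(fe$strand == "-"))
  list(pcg = pcg_report, strand_counts = strand_counts,
       n_warn = sum(pcg_report$status == "WARN"),
       n_fail = sum(pcg_report$status == "FAIL"))
}
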