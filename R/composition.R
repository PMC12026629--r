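#' Strand-skew statistic
#'
#' `skew(x, y) = (x - y) / (x + y)`, the standard compositional asymmetry
#' statistic: AT-skew is `skew(A, T)` and GC-skew is `skew(G, C)`. Counts,
#' fractions or percentages may be supplied (the statistic is scale-free).
#' A zero denominator yields `NaN` rather than an error, so that report
#' tables can carry an undefined-value entry.
#'
#' @param x_count,y_count non-negative counts (or percentages).
#' @return dimensionless value in `[-1, 1]`, or `NaN` when `x + y == 0`.
#' @examples
#' skew(35.5, 33.4)  # mitogenome AT-skew ~ 0.030
#' @export
skew <- function(x_count, y_count) {
  if (any(x_count < 0) || any(y_count < 0)) stop("counts must be non-negative")
  (x_count - y_count) / (x_count + y_count)
}

#' Base composition and skew statistics of a sequence
#'
#' Counts A/C/G/T over the non-N positions of a DNA string and derives
#' percentages, A+T content, AT-skew and GC-skew. Values are returned at
#' full precision; rounding (percentages to 1 decimal, skews to 3) is a
#' display concern, see [composition_report_table()].
#'
#' @param seq DNA string.
#' @param name partition label for the output row.
#' @return one-row data frame (class-tagged `composition_stats`): `partition`,
#'   `size` (bp, N included), `n_A`, `n_C`, `n_G`, `n_T`, `pct_T`, `pct_C`,
#'   `pct_A`, `pct_G`, `at_content`, `at_skew`, `gc_skew`.
#' @export
base_composition <- function(seq, name = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- normalize_dna(seq)
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(seq) - nchar(gsub(b, "", seq, fixed = TRUE)), integer(1))
  n <- sum(counts)
  if (n == 0L) stop("composition undefined: sequence contains no A/C/G/T")
  pct <- 100 * counts / n
  gs <- skew(counts[["G"]], counts[["C"]])
  if (is.nan(gs)) warning("GC-skew undefined (G + C == 0) for '", name, "'")
  as_ <- skew(counts[["A"]], counts[["T"]])
  if (is.nan(as_)) warning("AT-skew undefined (A + T == 0) for '", name, "'")
  out <- data.frame(partition = name, size = nchar(seq),
                    n_A = counts[["A"]], n_C = counts[["C"]],
                    n_G = counts[["G"]], n_T = counts[["T"]],
                    pct_T = pct[["T"]], pct_C = pct[["C"]],
                    pct_A = pct[["A"]], pct_G = pct[["G"]],
                    at_content = pct[["A"]] + pct[["T"]],
                    at_skew = as_, gc_skew = gs,
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_stats", class(out))
  out
}

#' Composition report over the standard mitogenome partitions
#'
#' Emits one composition row per partition, in the order conventional for
#' mitogenome papers: the whole mitogenome (plus strand), the pooled PCGs
#' (sense strands concatenated in start order), each PCG separately (sense
#' strand), the pooled tRNAs, the pooled rRNAs, and the control region
#' (plus strand). Pooled partitions concatenate each feature's full sense
#' sequence, so bases shared by overlapping genes are counted once per gene
#' and pooled sizes equal the sum of feature lengths.
#'
#' @param ag an `annotated_genome` with sequence.
#' @return data frame of [base_composition()] rows.
#' @export
partition_report <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  if (is.null(ag$genome$sequence)) stop("genome carries no sequence")
  fe <- ag$features
  seqs <- feature_sequences(ag)
  rows <- list(base_composition(ag$genome$sequence, "Mitogenome"))
  pool <- function(cat, label) {
    idx <- which(fe$category == cat)
    if (length(idx) == 0L) {
      warning("no features of category ", cat, "; row omitted")
      return(NULL)
    }
    base_composition(paste(seqs[idx], collapse = ""), label)
  }
  rows <- c(rows, list(pool("PCG", "PCGs")))
  for (i in which(fe$category == "PCG"))
    rows <- c(rows, list(base_composition(seqs[i], fe$name[i])))
  rows <- c(rows, list(pool("tRNA", "tRNAs"), pool("rRNA", "rRNAs")))
  cr <- which(fe$category == "CR")
  if (length(cr) == 1L) {
    # control region reported on the deposited plus strand
    cr_seq <- extract_sense_sequence(ag$genome,
      within(fe[cr, ], strand <- "+"))
    rows <- c(rows, list(base_composition(cr_seq, "Control region")))
  } else {
    warning("no control-region feature; row omitted")
  }
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  class(out) <- c("composition_stats", "data.frame")
  out
}

#' Rounded composition table for display
#'
#' Formats a [partition_report()] with the usual rounding: percentages to
#' one decimal, skews to three.
#'
#' @param stats data frame of composition rows.
#' @return data frame with columns `partition`, `size`, `T`, `C`, `A`, `G`,
#'   `A_T`, `AT_skew`, `GC_skew`.
#' @export
composition_report_table <- function(stats) {
  data.frame(partition = stats$partition, size = stats$size,
             T = round(stats$pct_T, 1), C = round(stats$pct_C, 1),
             A = round(stats$pct_A, 1), G = round(stats$pct_G, 1),
             A_T = round(stats$at_content, 1),
             AT_skew = round(stats$at_skew, 3),
             GC_skew = round(stats$gc_skew, 3),
             stringsAsFactors = FALSE, check.names = FALSE)
}
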