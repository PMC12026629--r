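#' Gene table in the style of a mitogenome paper's arrangement table
#'
#' One row per feature in plus-strand start order with direction, location,
#' size, anticodon, start/stop codon and the signed intergenic-nucleotide
#' column. Sizes are recomputed from coordinates (never trusted from the
#' input) and the intergenic column comes from [adjacency_census()], so the
#' last row carries the wrap-around gap. When the genome carries sequence,
#' PCG start/stop codons are read from the sequence via [extract_codons()];
#' otherwise the annotated codons are reported.
#'
#' @param ag an `annotated_genome`.
#' @param path optional path; when given, the table is written as
#'   tab-separated UTF-8 text (minus strand rendered as ASCII `-`).
#' @param code a [genetic_code()] used for codon extraction.
#' @return data frame with columns `gene`, `direction`, `start`, `end`,
#'   `size`, `anticodon`, `start_codon`, `stop_codon`, `intergenic`.
#' @export
write_gene_table <- function(ag, path = NULL, code = genetic_code(5L)) {
  stopifnot(inherits(ag, "annotated_genome"))
  fe <- ag$features
  if (anyDuplicated(fe[, c("name", "start", "end", "strand")]))
    warning("duplicate identical features; all emitted")
  cen <- adjacency_census(ag)
  size <- feature_length(fe$start, fe$end, ag$genome$length)
  start_codon <- fe$start_codon
  stop_codon <- fe$stop_codon
  if (!is.null(ag$genome$sequence)) {
    for (i in which(fe$category == "PCG")) {
      cod <- extract_codons(ag$genome, fe[i, ], code)
      start_codon[i] <- cod$start_codon
      stop_codon[i] <- cod$stop_codon
    }
  }
  out <- data.frame(gene = fe$name, direction = fe$strand,
                    start = fe$start, end = fe$end, size = size,
                    anticodon = fe$anticodon,
                    start_codon = start_codon, stop_codon = stop_codon,
                    intergenic = cen$gap, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8")
  }
  out
}
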