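#' Genetic code with synonymous-codon families
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()]) and
#' derives the partition of the 64 codons into synonymous families, with the
#' stop codons forming one family. The default, table 5, is the invertebrate
#' mitochondrial code, under which AGA/AGG encode serine (an eight-codon Ser
#' family), AUA encodes methionine and UGA tryptophan, leaving UAA/UAG as the
#' two stops.
#'
#' @param table_id NCBI genetic-code table id (default 5).
#' @return object of class `genetic_code`: `table_id`; `codon_aa`, a named
#'   character vector over the 64 RNA codons (stops as `"*"`); `families`,
#'   a list of RNA codon vectors named by amino acid; `start_codons`,
#'   conventional DNA initiation codons for validation purposes.
#' @examples
#' gc5 <- genetic_code(5)
#' lengths(gc5$families)[c("L", "S", "*")]
#' @export
genetic_code <- function(table_id = 5L) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codon_aa <- setNames(unname(tab), chartr("T", "U", names(tab)))
  fams <- split(names(codon_aa), codon_aa)
  structure(list(table_id = as.integer(table_id),
                 codon_aa = codon_aa,
                 families = fams,
                 start_codons = c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG")),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table ", x$table_id, ": ",
      length(x$families) - 1L, " amino-acid families, ",
      length(x$families[["*"]]), " stop codons\n", sep = "")
  invisible(x)
}

# The 64 RNA codons in standard table order (UUU, UUC, UUA, UUG, UCU, ...).
rna_codons <- function() {
  b <- c("U", "C", "A", "G")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}
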