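#' Published mitogenome gene layout of Caridina mariae
#'
#' The gene arrangement of the 15,581 bp mitogenome of the atyid shrimp
#' *Caridina mariae* (GenBank PQ359442): 13 protein-coding genes, 22 tRNAs,
#' 2 rRNAs and the control region, with strand, 1-based inclusive
#' coordinates, anticodons, annotated start/stop codons (incomplete stops in
#' the parenthesized form) and the published signed intergenic-nucleotide
#' column (negative values are overlaps with the next feature; the last
#' row's value is the wrap-around gap back to the first gene). The control
#' region is carried as a distinctly labelled `CR` row on the plus strand.
#'
#' @return data frame with columns `name`, `category`, `strand`, `start`,
#'   `end`, `size`, `anticodon`, `start_codon`, `stop_codon`, `intergenic`.
#' @examples
#' sum(subset(caridina_gene_layout(), category == "PCG")$size)  # 11128
#' @export
caridina_gene_layout <- function() {
  txt <- "
name    category strand start  end    anticodon start_codon stop_codon intergenic
cox1    PCG      +      1      1533   NA        CAA         TAA        2
trnL2   tRNA     +      1536   1599   TAA       NA          NA         1
cox2    PCG      +      1601   2308   NA        ATG         TAA        -20
trnK    tRNA     +      2289   2355   TTT       NA          NA         22
trnD    tRNA     +      2378   2442   GTC       NA          NA         2
atp8    PCG      +      2445   2603   NA        ATT         TAA        -7
atp6    PCG      +      2597   3271   NA        ATG         TAA        -1
cox3    PCG      +      3271   4056   NA        ATG         TAA        3
trnG    tRNA     +      4060   4124   TCC       NA          NA         0
nad3    PCG      +      4125   4478   NA        ATT         TAA        -2
trnA    tRNA     +      4477   4540   TGC       NA          NA         -1
trnR    tRNA     +      4540   4601   TCG       NA          NA         3
trnN    tRNA     +      4605   4671   GTT       NA          NA         0
trnS1   tRNA     +      4672   4738   TCT       NA          NA         0
trnE    tRNA     +      4739   4806   TTC       NA          NA         -2
trnF    tRNA     -      4805   4870   GAA       NA          NA         0
nad5    PCG      -      4871   6562   NA        ATT         TAA        36
trnH    tRNA     -      6599   6662   GTG       NA          NA         0
nad4    PCG      -      6663   8001   NA        ATG         T(AA)      -7
nad4L   PCG      -      7995   8294   NA        ATG         TAA        2
trnT    tRNA     +      8297   8361   TGT       NA          NA         0
trnP    tRNA     -      8362   8427   TGG       NA          NA         17
nad6    PCG      +      8445   8945   NA        ATA         TAA        -1
cob     PCG      +      8945   10081  NA        ATG         TAG        -2
trnS2   tRNA     +      10080  10149  TGA       NA          NA         18
nad1    PCG      -      10168  11106  NA        ATA         TAG        30
trnL1   tRNA     -      11137  11203  TAG       NA          NA         -40
rrnL    rRNA     -      11164  12489  NA        NA          NA         50
trnV    tRNA     -      12540  12606  TAC       NA          NA         2
rrnS    rRNA     -      12609  13405  NA        NA          NA         0
CR      CR       +      13406  14151  NA        NA          NA         0
trnI    tRNA     +      14152  14216  GAT       NA          NA         19
trnQ    tRNA     -      14236  14303  TTG       NA          NA         6
trnM    tRNA     +      14310  14377  CAT       NA          NA         0
nad2    PCG      +      14378  15382  NA        ATT         TAA        -2
trnW    tRNA     +      15381  15450  TCA       NA          NA         -1
trnC    tRNA     -      15450  15513  GCA       NA          NA         0
trnY    tRNA     -      15514  15579  GTA       NA          NA         2"
  df <- read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  df$size <- df$end - df$start + 1L
  df[, c("name", "category", "strand", "start", "end", "size",
         "anticodon", "start_codon", "stop_codon", "intergenic")]
}

#' Genome length implied by the C. mariae layout
#' @return 15581L
#' @export
caridina_genome_length <- function() {
  lay <- caridina_gene_layout()
  sum(lay$size) + sum(lay$intergenic)
}

#' Coordinate-only annotated genome for the C. mariae layout
#'
#' Builds an [annotated_genome()] carrying the published coordinates but no
#' sequence, suitable for coordinate arithmetic (lengths, adjacency census,
#' gene-order signature). Use [simulate_genome()] for a sequence-bearing
#' emulation.
#'
#' @return `annotated_genome` of length 15,581 bp with 38 features.
#' @export
caridina_annotation <- function() {
  lay <- caridina_gene_layout()
  annotated_genome(circular_genome(length = caridina_genome_length()),
                   gene_features(lay$name, lay$category, lay$strand,
                                 lay$start, lay$end, lay$anticodon,
                                 lay$start_codon, lay$stop_codon))
}

#' Published composition table of the C. mariae mitogenome
#'
#' The published per-partition nucleotide composition and strand-skew table
#' (percentages to one decimal, skews to three). Stored verbatim as
#' reference data; note that the published per-gene `size` column is
#' internally inconsistent with the gene layout for some genes (e.g. it
#' lists cob at 354 bp where the layout gives 1137 bp), so computed sizes
#' should always come from [caridina_gene_layout()].
#'
#' @return data frame with columns `partition`, `size`, `T`, `C`, `A`, `G`,
#'   `A_T`, `AT_skew`, `GC_skew`.
#' @export
caridina_composition <- function() {
  txt <- "
partition|size|T|C|A|G|A_T|AT_skew|GC_skew
Mitogenome|15581|33.4|18.9|35.5|12.2|68.9|0.030|-0.214
PCGs|11128|39.6|16.3|27.4|16.6|67.1|-0.182|0.007
cox1|1533|35.5|18.3|28.0|18.2|63.5|-0.118|-0.004
cox2|708|33.1|20.1|32.8|14.1|65.8|-0.004|-0.174
atp8|159|39.6|20.1|33.3|6.9|73.0|-0.086|-0.488
atp6|675|38.1|18.5|28.9|14.5|67.0|-0.137|-0.121
cox3|786|35.9|19.2|29.1|15.8|65.0|-0.104|-0.098
cob|354|40.1|20.1|28.8|11.0|68.9|-0.164|-0.291
nad5|1692|41.5|11.6|26.1|20.7|67.7|-0.228|0.283
nad4|1339|43.6|11.0|24.4|21.0|68.0|-0.282|0.313
nad4l|300|44.3|8.7|26.3|20.7|70.7|-0.255|0.409
nad3|501|40.7|21.6|29.1|8.6|69.9|-0.166|-0.430
nad1|1137|38.5|19.3|26.9|15.3|65.4|-0.177|-0.115
nad6|939|44.9|11.2|25.1|18.7|70.1|-0.283|0.253
nad2|1005|40.4|21.4|27.7|10.5|68.1|-0.187|-0.340
tRNAs|1455|33.5|14.0|34.6|17.9|68.1|0.015|0.125
rRNAs|2123|39.0|9.2|33.9|17.9|72.9|-0.070|0.323
Control region|746|39.7|7.0|47.1|6.3|86.7|0.085|-0.051"
  read.table(text = txt, header = TRUE, sep = "|",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published codon usage of the C. mariae protein-coding genes
#'
#' Codon counts and published RSCU values over all 64 codons (RNA alphabet,
#' standard UUU..GGG order) for the pooled 13 PCGs under the invertebrate
#' mitochondrial code. The two stop codons are included (UAA 10, UAG 2);
#' the incomplete stop of nad4 is not counted.
#'
#' @return data frame with columns `codon`, `aa`, `count`, `rscu_published`.
#' @export
caridina_codon_usage <- function() {
  counts <- c(
    UUU = 258, UUC = 47, UUA = 305, UUG = 55,
    UCU = 115, UCC = 21, UCA = 75, UCG = 10,
    UAU = 104, UAC = 32, UAA = 10, UAG = 2,
    UGU = 37, UGC = 5, UGA = 75, UGG = 23,
    CUU = 115, CUC = 26, CUA = 62, CUG = 15,
    CCU = 70, CCC = 29, CCA = 44, CCG = 9,
    CAU = 51, CAC = 30, CAA = 71, CAG = 10,
    CGU = 19, CGC = 3, CGA = 30, CGG = 9,
    AUU = 271, AUC = 30, AUA = 169, AUG = 31,
    ACU = 102, ACC = 21, ACA = 77, ACG = 7,
    AAU = 76, AAC = 46, AAA = 59, AAG = 17,
    AGU = 20, AGC = 7, AGA = 77, AGG = 25,
    GUU = 100, GUC = 18, GUA = 110, GUG = 28,
    GCU = 152, GCC = 33, GCA = 54, GCG = 10,
    GAU = 53, GAC = 28, GAA = 54, GAG = 17,
    GGU = 54, GGC = 20, GGA = 87, GGG = 89)
  published <- c(
    UUU = 1.69, UUC = 0.31, UUA = 3.17, UUG = 0.57,
    UCU = 2.63, UCC = 0.48, UCA = 1.71, UCG = 0.23,
    UAU = 1.53, UAC = 0.47, UAA = 1.67, UAG = 0.33,
    UGU = 1.76, UGC = 0.24, UGA = 1.53, UGG = 0.47,
    CUU = 1.19, CUC = 0.27, CUA = 0.64, CUG = 0.16,
    CCU = 1.84, CCC = 0.76, CCA = 1.16, CCG = 0.24,
    CAU = 1.26, CAC = 0.74, CAA = 1.75, CAG = 0.25,
    CGU = 1.25, CGC = 0.20, CGA = 1.97, CGG = 0.59,
    AUU = 1.80, AUC = 0.20, AUA = 1.69, AUG = 0.31,
    ACU = 1.97, ACC = 0.41, ACA = 1.49, ACG = 0.14,
    AAU = 1.25, AAC = 0.75, AAA = 1.55, AAG = 0.45,
    AGU = 0.46, AGC = 0.16, AGA = 1.76, AGG = 0.57,
    GUU = 1.56, GUC = 0.28, GUA = 1.72, GUG = 0.44,
    GCU = 2.44, GCC = 0.53, GCA = 0.87, GCG = 0.16,
    GAU = 1.31, GAC = 0.69, GAA = 1.52, GAG = 0.48,
    GGU = 0.86, GGC = 0.32, GGA = 1.39, GGG = 1.42)
  code <- genetic_code(5L)
  codons <- rna_codons()
  data.frame(codon = codons, aa = unname(code$codon_aa[codons]),
             count = unname(counts[codons]),
             rscu_published = unname(published[codons]),
             stringsAsFactors = FALSE)
}
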