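# Seeded simulator of annotated circular mitogenomes with a ground-truth
# manifest. The default emulates the published C. mariae layout: PCGs are
# built codon-by-codon from the published codon-usage profile with planted
# start/stop codons (one incomplete T stop where the layout demands length
# = 1 mod 3), tRNAs are planted cloverleaves (with a configurable mismatch
# plan and a D-armless trnS1), rRNA/CR/spacers are sampled at their target
# compositions. Overlapping features share sequence: signals are planted
# first, then tRNAs, then PCG bodies, then composition-sampled partitions,
# each step respecting every base fixed before it.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Unpaired-region (loop/linker/variable) base frequencies. Restricted to
# A and C: no apposition drawn from {A, C} scores positively (A-A and A-G
# are penalized, A-C and C-C are neutral mismatches), so spurious stems
# cannot form inside planted unpaired regions and the planted placement
# stays the unique score optimum.
LOOP_PROBS <- c(A = 0.8, C = 0.2, G = 0, T = 0)

#' Default per-partition composition targets
#'
#' Base-frequency targets (A/C/G/T fractions on the sense strand) used by
#' [simulate_genome()] for the partitions that are sampled rather than built
#' from codons or stems: rRNAs, the control region, and intergenic spacers
#' (spacers default to control-region-like A+T richness). Derived from the
#' published composition table.
#'
#' @return named list of named numeric vectors summing to 1.
#' @export
default_composition_targets <- function() {
  comp <- caridina_composition()
  tgt <- function(row) {
    v <- unlist(comp[comp$partition == row, c("A", "C", "G", "T")]) / 100
    v / sum(v)
  }
  list(rRNA = tgt("rRNAs"), CR = tgt("Control region"),
       spacer = tgt("Control region"))
}

#' Default planted tRNA mismatch plan
#'
#' Total pair-slot mismatch classes planted across the 22 tRNAs, matching
#' the census reported for the *C. mariae* structures: 31 G-U wobbles plus
#' a handful of CC/UU/CA/UC appositions.
#'
#' @return named integer vector.
#' @export
default_mismatch_plan <- function() {
  c(GU = 31L, CC = 1L, UU = 2L, CA = 2L, UC = 3L)
}

wrap_pos <- function(p, L) ((p - 1L) %% L) + 1L

# plus-strand positions of sense positions k (1-based) of a feature
sense_to_plus <- function(f, k, L) {
  if (f$strand == "+") wrap_pos(f$start + k - 1L, L) else
    wrap_pos(f$end - k + 1L, L)
}

# Plant a cloverleaf tRNA sequence of length len against a template of
# fixed sense bases (DNA chars, NA = free). Returns the sense sequence and
# the realized structure truth.
plant_cloverleaf <- function(len, anticodon = NULL, d_armless = FALSE,
                             mismatches = character(),
                             template = rep(NA_character_, len),
                             config = cloverleaf_config()) {
  geos <- cloverleaf_geometries(len, config)
  geos <- geos[if (d_armless) geos$d == 0L else geos$d > 0L, , drop = FALSE]
  if (nrow(geos) == 0L)
    stop("no plantable cloverleaf geometry for length ", len)
  # Plant the geometry the fold search itself would rank first among equal
  # scores: maximal stems (so folding cannot profitably extend them), then
  # minimal total loop, then leftmost arms. An all-WC plant is then the
  # unique tie-break winner at the global score optimum.
  total_loop <- ifelse(geos$d > 0L, geos$d_loop, 0L) + geos$t_loop
  geos <- geos[order(-geos$d, -geos$t, total_loop, geos$g1, geos$g2), ,
               drop = FALSE]
  anticodon_dna <- if (!is.null(anticodon) && !is.na(anticodon))
    chartr("U", "T", normalize_dna(anticodon)) else NULL

  geo <- NULL; p <- NULL
  for (k in seq_len(nrow(geos))) {
    cand <- geometry_pairs(geos[k, ], len, config)
    if (!is.null(anticodon_dna)) {
      at <- template[cand$anticodon_pos[1L]:cand$anticodon_pos[2L]]
      want <- strsplit(anticodon_dna, "")[[1]]
      if (any(!is.na(at) & at != want)) next
    }
    geo <- geos[k, ]; p <- cand
    break
  }
  if (is.null(geo)) {  # no geometry places the anticodon over free bases
    geo <- geos[1L, ]; p <- geometry_pairs(geo, len, config)
    anticodon_dna <- NULL
  }

  s <- template
  if (!is.null(anticodon_dna)) {
    idx <- p$anticodon_pos[1L]:p$anticodon_pos[2L]
    s[idx] <- strsplit(anticodon_dna, "")[[1]]
  }

  slots <- rbind(p$acceptor, p$d, p$anticodon, p$t)
  want <- rep("WC", nrow(slots))
  free_slot <- is.na(s[slots[, 1L]]) & is.na(s[slots[, 2L]])
  # Mismatches go only into the acceptor and anticodon stems: those slots
  # are positionally pinned (sequence ends, anticodon loop), so a planted
  # non-WC slot cannot be "repaired" by sliding an arm during folding.
  n_acc <- nrow(p$acceptor); n_d <- nrow(p$d)
  pinned <- c(seq_len(n_acc), n_acc + n_d + seq_len(nrow(p$anticodon)))
  pickable <- intersect(pinned, which(free_slot))
  mismatches <- mismatches[seq_len(min(length(mismatches), length(pickable)))]
  if (length(mismatches)) {
    chosen <- if (length(pickable) == 1L) pickable else
      sample(pickable, length(mismatches))
    want[chosen] <- mismatches
  }
  stem_probs <- c(A = 0.22, C = 0.26, G = 0.30, T = 0.22)
  for (r in seq_len(nrow(slots))) {
    i <- slots[r, 1L]; j <- slots[r, 2L]
    lab <- want[r]
    fi <- !is.na(s[i]); fj <- !is.na(s[j])
    if (fi && fj) next
    if (!fi && !fj) {
      if (lab == "WC") {
        s[i] <- sample(DNA_BASES, 1L, prob = stem_probs[DNA_BASES])
        s[j] <- DNA_COMP[[s[i]]]
      } else {
        duo <- switch(lab, GU = c("G", "T"), CC = c("C", "C"),
                      UU = c("T", "T"), CA = c("C", "A"), UC = c("T", "C"))
        if (runif(1) < 0.5) duo <- rev(duo)
        s[i] <- duo[1L]; s[j] <- duo[2L]
      }
    } else {
      x <- if (fi) s[i] else s[j]
      partner <- switch(lab,
        WC = DNA_COMP[[x]],
        GU = switch(x, G = "T", T = "G", DNA_COMP[[x]]),
        CC = if (x == "C") "C" else DNA_COMP[[x]],
        UU = if (x == "T") "T" else DNA_COMP[[x]],
        CA = switch(x, C = "A", A = "C", DNA_COMP[[x]]),
        UC = switch(x, T = "C", C = "T", DNA_COMP[[x]]))
      if (fi) s[j] <- partner else s[i] <- partner
    }
  }
  free <- is.na(s)
  s[free] <- sample(DNA_BASES, sum(free), replace = TRUE,
                    prob = LOOP_PROBS[DNA_BASES])
  labels <- pair_label(s[slots[, 1L]], s[slots[, 2L]])
  list(seq = paste(s, collapse = ""), geometry = as.list(geo),
       pairs = slots, pair_labels = labels, d_armless = d_armless,
       anticodon = if (!is.null(anticodon_dna)) anticodon_dna else
         paste(s[p$anticodon_pos[1L]:p$anticodon_pos[2L]], collapse = ""))
}

#' Simulate an annotated circular mitogenome with known ground truth
#'
#' Builds a sequence-bearing [annotated_genome()] on a given gene layout
#' (default: the published *C. mariae* arrangement, which forces the
#' published structural numbers - 15,581 bp; 11,128 bp of PCGs; 1455 bp of
#' tRNAs; 16 spacers and 12 overlaps - by construction) and records every
#' realized quantity in a truth manifest. The same seed always yields the
#' same genome.
#'
#' @param layout gene layout data frame (see [caridina_gene_layout()]):
#'   columns `name`, `category`, `strand`, and either `start`/`end`
#'   coordinates or `size` plus signed `intergenic` gaps.
#' @param seed integer seed.
#' @param codon_weights sampling weights for PCG body codons, named by RNA
#'   codon (default: the published codon counts). Stop codons are never
#'   sampled.
#' @param composition_targets list with elements `rRNA`, `CR`, `spacer`
#'   (see [default_composition_targets()]).
#' @param mismatch_plan named counts of tRNA stem mismatch classes to plant
#'   (see [default_mismatch_plan()]); distributed randomly across the tRNAs.
#' @param d_armless name of the tRNA planted without a D-arm (`NULL` for
#'   none); default `"trnS1"`.
#' @param code a [genetic_code()].
#' @param fold_config a [cloverleaf_config()].
#' @return list with elements `genome` (an `annotated_genome`) and `truth`,
#'   the manifest: `genome_length`, `seed`, `adjacency` (planted gaps),
#'   `codon_counts` (realized pooled RNA codon counts), `start_stop`
#'   (realized per-PCG codons), `trna` (per-tRNA planted structures),
#'   `pair_census` (realized planted pair-class counts), `d_armless_flags`,
#'   `composition` (realized per-partition base counts and the targets).
#' @export
simulate_genome <- function(layout = caridina_gene_layout(), seed = 1L,
                            codon_weights = NULL,
                            composition_targets = default_composition_targets(),
                            mismatch_plan = default_mismatch_plan(),
                            d_armless = "trnS1",
                            code = genetic_code(5L),
                            fold_config = cloverleaf_config()) {
  set.seed(as.integer(seed))
  lay <- layout
  if (!all(c("start", "end") %in% names(lay))) {
    stopifnot(all(c("size", "intergenic") %in% names(lay)))
    lay$start <- cumsum(c(1L, head(lay$size + lay$intergenic, -1L)))
    lay$end <- lay$start + lay$size - 1L
  }
  if (!"intergenic" %in% names(lay))
    stop("layout must carry the signed intergenic column (gap plan)")
  if (!"size" %in% names(lay)) lay$size <- lay$end - lay$start + 1L
  L <- sum(lay$size) + sum(lay$intergenic)
  if (L < max(lay$end) || L < max(lay$start))
    stop("infeasible layout: gaps and sizes imply genome length ", L,
         " shorter than the coordinate span")
  lay$size <- feature_length(lay$start, lay$end, L)

  s <- rep(NA_character_, L)
  plant <- function(pos, bases, what) {
    clash <- !is.na(s[pos]) & s[pos] != bases
    if (any(clash))
      stop("infeasible layout: conflicting planted bases for ", what,
           " at position ", pos[clash][1L])
    s[pos] <<- bases
  }
  write_sense <- function(f, k, sense_bases) {
    pos <- sense_to_plus(f, k, L)
    bases <- if (f$strand == "-") DNA_COMP[sense_bases] else sense_bases
    free <- is.na(s[pos])
    s[pos[free]] <<- bases[free]
  }
  read_sense <- function(f, k) {
    b <- s[sense_to_plus(f, k, L)]
    if (f$strand == "-") unname(DNA_COMP[b]) else b
  }

  pcgs <- which(lay$category == "PCG")
  trnas <- which(lay$category == "tRNA")

  # --- step 1: plant PCG start and stop codons as hard constraints ---
  for (i in pcgs) {
    f <- lay[i, ]
    sc <- strsplit(f$start_codon, "")[[1]]
    plant(sense_to_plus(f, 1:3, L),
          if (f$strand == "-") DNA_COMP[sc] else sc, paste0(f$name, " start"))
    partial <- sub("\\(.*", "", f$stop_codon)
    stop_chars <- strsplit(partial, "")[[1]]
    k <- (f$size - length(stop_chars) + 1L):f$size
    plant(sense_to_plus(f, k, L),
          if (f$strand == "-") DNA_COMP[stop_chars] else stop_chars,
          paste0(f$name, " stop"))
  }

  # --- step 2: plant tRNA cloverleaves ---
  mm_labels <- rep(names(mismatch_plan), mismatch_plan)
  mm_owner <- if (length(mm_labels) && length(trnas))
    sample(seq_along(trnas), length(mm_labels), replace = TRUE) else integer()
  # a plant is accepted only if folding the planted sequence recovers the
  # planted pair set and D-arm status; base draws are redrawn on the rare
  # coincidental collision (an equally good alternative placement)
  plant_recoverable <- function(pl, anticodon, armless) {
    st <- tryCatch(
      fold_cloverleaf(pl$seq,
                      anticodon = if (!is.na(anticodon)) anticodon,
                      config = fold_config),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(st)) return(FALSE)
    fp <- rbind(st$acceptor_stem,
                if (!is.null(st$d_arm)) st$d_arm$stem_pairs,
                st$anticodon_arm$stem_pairs, st$t_arm$stem_pairs)
    identical(fp[order(fp[, 1L]), , drop = FALSE],
              pl$pairs[order(pl$pairs[, 1L]), , drop = FALSE]) &&
      identical(detect_missing_arms(st)$d_arm_absent, armless)
  }
  trna_truth <- list()
  for (ti in seq_along(trnas)) {
    i <- trnas[ti]
    f <- lay[i, ]
    template <- read_sense(f, seq_len(f$size))
    armless <- identical(f$name, d_armless)
    for (attempt in 1:25) {
      pl <- plant_cloverleaf(f$size, anticodon = f$anticodon,
                             d_armless = armless,
                             mismatches = mm_labels[mm_owner == ti],
                             template = template, config = fold_config)
      if (plant_recoverable(pl, f$anticodon, armless)) break
    }
    write_sense(f, seq_len(f$size), strsplit(pl$seq, "")[[1]])
    pl$seq <- paste(read_sense(f, seq_len(f$size)), collapse = "")
    pl$name <- f$name
    trna_truth[[f$name]] <- pl
  }

  # --- step 3: fill PCG bodies codon-by-codon from the usage profile ---
  if (is.null(codon_weights)) {
    cu <- caridina_codon_usage()
    codon_weights <- setNames(cu$count, cu$codon)
  }
  w_dna <- setNames(as.numeric(codon_weights), chartr("U", "T", names(codon_weights)))
  stops_dna <- chartr("U", "T", code$families[["*"]])
  body_codons <- setdiff(names(w_dna)[w_dna >= 0], stops_dna)
  body_mat <- do.call(rbind, strsplit(body_codons, ""))
  body_w <- w_dna[body_codons]
  for (i in pcgs) {
    f <- lay[i, ]
    n_cod <- f$size %/% 3L
    has_complete_stop <- f$size %% 3L == 0L
    body_idx <- setdiff(seq_len(n_cod), c(1L, if (has_complete_stop) n_cod))
    for (ci in body_idx) {
      k <- (3L * ci - 2L):(3L * ci)
      fixed <- read_sense(f, k)
      freepos <- is.na(fixed)
      if (!any(freepos)) next
      okc <- rep(TRUE, length(body_codons))
      for (m in which(!freepos)) okc <- okc & body_mat[, m] == fixed[m]
      if (!any(okc)) next  # constraints force a stop codon; leave as is
      wsel <- body_w[okc]
      if (sum(wsel) <= 0) wsel <- rep(1, sum(okc))
      pickrow <- which(okc)[sample.int(sum(okc), 1L, prob = wsel)]
      write_sense(f, k, body_mat[pickrow, ])
    }
    # an incomplete-stop gene may have 1-2 trailing nt after its last codon
    # already planted in step 1; nothing further to fill
  }

  # --- step 4: rRNA, CR, spacers by composition-target sampling ---
  sample_bases <- function(n, probs)
    sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES])
  for (i in which(lay$category == "rRNA")) {
    f <- lay[i, ]
    free <- which(is.na(read_sense(f, seq_len(f$size))))
    if (length(free))
      write_sense(f, free, sample_bases(length(free),
                                        composition_targets$rRNA))
  }
  for (i in which(lay$category == "CR")) {
    f <- lay[i, ]
    free <- which(is.na(read_sense(f, seq_len(f$size))))
    if (length(free))
      write_sense(f, free, sample_bases(length(free), composition_targets$CR))
  }
  spacer_pos <- which(is.na(s))
  if (length(spacer_pos))
    s[spacer_pos] <- sample_bases(length(spacer_pos),
                                  composition_targets$spacer)

  genome <- circular_genome(paste(s, collapse = ""))
  ag <- annotated_genome(genome,
                         gene_features(lay$name, lay$category, lay$strand,
                                       lay$start, lay$end, lay$anticodon,
                                       lay$start_codon, lay$stop_codon))

  # --- truth manifest: realized quantities, read back from the sequence ---
  codon_counts <- setNames(integer(64L), rna_codons())
  start_stop <- list()
  for (i in pcgs) {
    f <- lay[i, ]
    sense <- paste(read_sense(f, seq_len(f$size)), collapse = "")
    n_cod <- f$size %/% 3L
    cods <- chartr("T", "U",
                   substring(sense, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod)))
    tab <- table(cods)
    codon_counts[names(tab)] <- codon_counts[names(tab)] + as.integer(tab)
    rem <- f$size %% 3L
    stop_txt <- if (rem == 0L) substr(sense, f$size - 2L, f$size) else
      paste0(substr(sense, f$size - rem + 1L, f$size), "(",
             substr("TAA", rem + 1L, 3L), ")")
    start_stop[[f$name]] <- c(start = substr(sense, 1L, 3L), stop = stop_txt)
  }
  lv <- c("WC", "GU", "CC", "UU", "CA", "UC", "other")
  census <- table(factor(unlist(lapply(trna_truth, `[[`, "pair_labels")),
                         levels = lv))
  comp_count <- function(txt) {
    ch <- strsplit(txt, "")[[1]]
    vapply(DNA_BASES, function(b) sum(ch == b), integer(1))
  }
  comp <- lapply(seq_len(nrow(lay)), function(i)
    comp_count(paste(read_sense(lay[i, ], seq_len(lay$size[i])), collapse = "")))
  names(comp) <- lay$name
  comp$spacers <- if (length(spacer_pos))
    vapply(DNA_BASES, function(b) sum(s[spacer_pos] == b), integer(1)) else
    setNames(integer(4L), DNA_BASES)
  comp$genome <- vapply(DNA_BASES, function(b) sum(s == b), integer(1))

  truth <- list(
    genome_length = L, seed = as.integer(seed),
    adjacency = data.frame(upstream = lay$name,
                           downstream = lay$name[c(2:nrow(lay), 1L)],
                           gap = as.integer(lay$intergenic),
                           stringsAsFactors = FALSE),
    codon_counts = codon_counts,
    start_stop = start_stop,
    trna = trna_truth,
    pair_census = setNames(as.integer(census), lv),
    d_armless_flags = setNames(lay$name[trnas] == if (is.null(d_armless)) ""
                               else d_armless, lay$name[trnas]),
    composition = list(counts = comp, targets = composition_targets))
  list(genome = ag, truth = truth)
}

#' Evolve sequences along a tree
#'
#' Simulates site-independent sequence evolution on a rooted tree with
#' branch lengths, under Jukes-Cantor nucleotides (`"JC"`) or a Poisson
#' amino-acid model (`"poisson"`). The root sequence is drawn from the
#' uniform equilibrium; along an edge of length `b` each site changes with
#' the model's exact transition probability (JC:
#' `p = 3/4 (1 - exp(-4 b / 3))`; Poisson over 20 states:
#' `p = 19/20 (1 - exp(-20 b / 19))`), moving to one of the other states
#' uniformly.
#'
#' @param tree rooted `phylo` tree with non-negative branch lengths.
#' @param model `"JC"` or `"poisson"`.
#' @param length number of columns.
#' @param seed integer seed.
#' @return named character vector of leaf sequences.
#' @export
evolve_alignment <- function(tree, model = c("JC", "poisson"), length,
                             seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(as.integer(seed))
  alpha <- if (model == "JC") DNA_BASES else
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  k <- length(alpha)
  tree <- stats::reorder(tree)  # cladewise: parents precede children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(alpha, length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    p <- (k - 1) / k * (1 - exp(-k * b / (k - 1)))
    x <- seqs[[par]]
    hit <- runif(length) < p
    if (any(hit)) {
      shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
      x[hit] <- alpha[(match(x[hit], alpha) - 1L + shift) %% k + 1L]
    }
    seqs[[child]] <- x
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}
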