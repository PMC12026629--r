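# Constrained cloverleaf folding for mitochondrial tRNAs.
#
# The search space is the classic four-arm cloverleaf skeleton: a 7-slot
# acceptor stem pairing the 5' and 3' ends, then (5'->3') an optional D-arm,
# the anticodon arm (5-pair stem, 7-nt loop), a variable region and the
# T-arm. All admissible arm placements are enumerated and scored slot by
# slot; this is exhaustive, not thermodynamic, and is deliberately
# brute-forceable at tRNA lengths (<= 75 nt).

#' Cloverleaf folding parameters
#'
#' All constants of the constrained cloverleaf search in one place.
#' Arm-geometry ranges are in nucleotides; `pair_scores` gives the per-slot
#' contribution of a Watson-Crick pair, a G-U wobble, one of the censused
#' mismatch classes (`mismatch_labels`), and any other apposition.
#'
#' @param acceptor_pairs acceptor-stem slots (fixed, 7).
#' @param d_stem,d_loop admissible D-stem pair counts and D-loop lengths.
#' @param d_linker admissible unpaired linker lengths replacing an absent
#'   D-arm.
#' @param ac_stem,ac_loop anticodon stem pairs and loop length (the loop is
#'   the canonical 7 nt, anticodon at loop positions 3-5).
#' @param t_stem,t_loop T-arm stem pairs and loop lengths.
#' @param spacer1 unpaired nt between acceptor stem and D-arm.
#' @param spacer2 unpaired nt between D-arm and anticodon arm.
#' @param var_region admissible variable-region lengths.
#' @param pair_scores named numeric: `WC`, `GU`, `mismatch`, `other`.
#' @param mismatch_labels pair classes scored as tolerated mismatches.
#' @param min_score minimum acceptable total score; below it the fold is
#'   flagged as failed (the best partial structure is still returned).
#' @param d_margin score margin by which the best D-armless placement must
#'   beat the best D-bearing one before [detect_missing_arms()] flags the
#'   D-arm as absent.
#' @return list of class `cloverleaf_config`.
#' @export
cloverleaf_config <- function(acceptor_pairs = 7L,
                              d_stem = 3:4, d_loop = 4:12, d_linker = 0:10,
                              ac_stem = 5L, ac_loop = 7L,
                              t_stem = 4:5, t_loop = 4:9,
                              spacer1 = 0:3, spacer2 = 0:3,
                              var_region = 0:12,
                              pair_scores = c(WC = 2, GU = 1,
                                              mismatch = 0, other = -1),
                              mismatch_labels = c("CC", "UU", "CA", "UC"),
                              min_score = 0, d_margin = 0) {
  structure(list(acceptor_pairs = acceptor_pairs, d_stem = d_stem,
                 d_loop = d_loop, d_linker = d_linker, ac_stem = ac_stem,
                 ac_loop = ac_loop, t_stem = t_stem, t_loop = t_loop,
                 spacer1 = spacer1, spacer2 = spacer2,
                 var_region = var_region, pair_scores = pair_scores,
                 mismatch_labels = mismatch_labels, min_score = min_score,
                 d_margin = d_margin),
            class = "cloverleaf_config")
}

#' Classify a base apposition
#'
#' Unordered pair classes: `WC` (AU/GC), `GU` wobble, the censused
#' mismatches `CC`, `UU`, `CA` (A against C) and `UC` (U against C), and
#' `other` for everything else (AA, GG, AG, or anything involving N).
#'
#' @param x,y single RNA/DNA bases (vectorized).
#' @return character vector of labels.
#' @export
pair_label <- function(x, y) {
  key <- paste0(chartr("Tt", "Uu", toupper(x)), chartr("Tt", "Uu", toupper(y)))
  lut <- c(AU = "WC", UA = "WC", GC = "WC", CG = "WC",
           GU = "GU", UG = "GU", CC = "CC", UU = "UU",
           CA = "CA", AC = "CA", UC = "UC", CU = "UC")
  out <- lut[key]
  out[is.na(out)] <- "other"
  unname(out)
}

# Enumerate all admissible arm geometries for a sequence of length L.
# Returns a data frame; d == 0 encodes an absent D-arm with `dspan` linker nt.
cloverleaf_geometries <- function(L, config) {
  core <- 2L * config$acceptor_pairs + 2L * config$ac_stem + config$ac_loop
  d_opts <- rbind(
    expand.grid(d = config$d_stem, d_loop = config$d_loop),
    data.frame(d = 0L, d_loop = config$d_linker))
  g <- expand.grid(g1 = config$spacer1, di = seq_len(nrow(d_opts)),
                   g2 = config$spacer2, t = config$t_stem,
                   t_loop = config$t_loop)
  g$d <- d_opts$d[g$di]; g$d_loop <- d_opts$d_loop[g$di]; g$di <- NULL
  g$dspan <- 2L * g$d + g$d_loop
  g$v <- L - core - g$g1 - g$dspan - g$g2 - 2L * g$t - g$t_loop
  g <- g[g$v >= min(config$var_region) & g$v <= max(config$var_region), ,
         drop = FALSE]
  rownames(g) <- NULL
  g
}

# Pair indices of one geometry on a length-L sequence.
geometry_pairs <- function(geo, L, config) {
  np <- config$acceptor_pairs
  acc <- cbind(seq_len(np), L - seq_len(np) + 1L)
  a <- np + geo$g1 + 1L
  dp <- if (geo$d > 0L)
    cbind(a + seq_len(geo$d) - 1L, a + geo$dspan - seq_len(geo$d)) else
    matrix(integer(), 0L, 2L)
  b <- a + geo$dspan + geo$g2
  ns <- config$ac_stem
  acs <- cbind(b + seq_len(ns) - 1L, b + 2L * ns + config$ac_loop - seq_len(ns))
  c0 <- b + 2L * ns + config$ac_loop + geo$v
  ts <- cbind(c0 + seq_len(geo$t) - 1L, c0 + 2L * geo$t + geo$t_loop - seq_len(geo$t))
  list(acceptor = acc, d = dp, anticodon = acs, t = ts,
       d_loop = if (geo$d > 0L) c(a + geo$d, a + geo$d + geo$d_loop - 1L),
       d_linker = if (geo$d == 0L && geo$dspan > 0L) c(a, a + geo$dspan - 1L),
       ac_loop = c(b + ns, b + ns + config$ac_loop - 1L),
       anticodon_pos = c(b + ns + 2L, b + ns + 4L),
       var_region = if (geo$v > 0L) c(c0 - geo$v, c0 - 1L),
       t_loop = c(c0 + geo$t, c0 + geo$t + geo$t_loop - 1L))
}

#' Fold a tRNA sequence into a constrained cloverleaf
#'
#' Exhaustively enumerates every admissible cloverleaf geometry (including
#' D-armless ones) under the template in [cloverleaf_config()], scores each
#' pair slot (+2 Watson-Crick, +1 G-U wobble, 0 for a tolerated mismatch,
#' -1 otherwise) and returns the best placement. Ties are broken by more
#' Watson-Crick pairs, then smaller total loop length, then the leftmost
#' D-arm. When `anticodon` is given, placements whose 7-nt anticodon loop
#' does not carry it at loop positions 3-5 are rejected. If the best score
#' falls below `config$min_score` the structure is returned with
#' `fold_failed = TRUE` and a warning.
#'
#' @param seq tRNA sequence, 55-75 nt, RNA or DNA alphabet.
#' @param anticodon optional 3-mer (RNA or DNA).
#' @param config a [cloverleaf_config()].
#' @return object of class `cloverleaf`: per-arm pair matrices and loop
#'   spans, `pair_labels` over all slots, `score`, the best scores with and
#'   without a D-arm (`score_d_present`, `score_d_absent`, `NA` when no such
#'   placement is admissible), `geometry`, `anticodon`, `fold_failed`.
#' @export
fold_cloverleaf <- function(seq, anticodon = NULL,
                            config = cloverleaf_config()) {
  seq <- chartr("T", "U", normalize_dna(seq))
  L <- nchar(seq)
  if (L < 55L || L > 75L)
    stop("tRNA sequence length ", L, " outside supported range [55, 75]")
  chars <- strsplit(seq, "")[[1]]
  geos <- cloverleaf_geometries(L, config)
  if (nrow(geos) == 0L) stop("no admissible cloverleaf geometry for length ", L)

  sc <- config$pair_scores
  lab_all <- outer(chars, chars, pair_label)
  smat <- matrix(sc[["other"]], L, L)
  smat[lab_all == "WC"] <- sc[["WC"]]
  smat[lab_all == "GU"] <- sc[["GU"]]
  smat[lab_all %in% config$mismatch_labels] <- sc[["mismatch"]]
  wmat <- lab_all == "WC"

  if (!is.null(anticodon)) {
    anticodon <- chartr("T", "U", normalize_dna(anticodon))
    stopifnot(nchar(anticodon) == 3L)
    ac_start <- config$acceptor_pairs + geos$g1 + geos$dspan + geos$g2 +
      config$ac_stem + 3L
    geos <- geos[substring(seq, ac_start, ac_start + 2L) == anticodon, ,
                 drop = FALSE]
    if (nrow(geos) == 0L)
      stop("no admissible placement carries the anticodon '", anticodon, "'")
  }

  n <- nrow(geos)
  score <- numeric(n); n_wc <- integer(n); ok <- rep(TRUE, n)
  for (k in seq_len(n)) {
    p <- geometry_pairs(geos[k, ], L, config)
    idx <- rbind(p$acceptor, p$d, p$anticodon, p$t)
    score[k] <- sum(smat[idx])
    n_wc[k] <- sum(wmat[idx])
  }

  total_loop <- geos$d_loop * (geos$d > 0L) + config$ac_loop + geos$t_loop
  pick <- function(cand) {
    o <- order(-score[cand], -n_wc[cand], total_loop[cand], geos$g1[cand])
    cand[o][1L]
  }
  best <- pick(which(ok))
  with_d <- which(ok & geos$d > 0L)
  without_d <- which(ok & geos$d == 0L)
  score_d_present <- if (length(with_d)) score[pick(with_d)] else NA_real_
  score_d_absent <- if (length(without_d)) score[pick(without_d)] else NA_real_

  geo <- geos[best, ]
  p <- geometry_pairs(geo, L, config)
  slot_labels <- function(m) if (nrow(m)) pair_label(chars[m[, 1L]], chars[m[, 2L]]) else character()
  labels <- c(acceptor = list(slot_labels(p$acceptor)),
              d = list(slot_labels(p$d)),
              anticodon = list(slot_labels(p$anticodon)),
              t = list(slot_labels(p$t)))
  failed <- score[best] < config$min_score
  if (failed)
    warning("fold failure: best score ", score[best], " below minimum ",
            config$min_score, "; returning best partial structure")
  structure(list(
    sequence = seq, length = L,
    acceptor_stem = p$acceptor,
    d_arm = if (geo$d > 0L) list(stem_pairs = p$d, loop = p$d_loop),
    d_linker = p$d_linker,
    anticodon_arm = list(stem_pairs = p$anticodon, loop = p$ac_loop),
    t_arm = list(stem_pairs = p$t, loop = p$t_loop),
    variable_region = p$var_region,
    anticodon = substr(seq, p$anticodon_pos[1L], p$anticodon_pos[2L]),
    pair_labels = labels,
    score = score[best],
    score_d_present = score_d_present,
    score_d_absent = score_d_absent,
    geometry = as.list(geo),
    fold_failed = failed,
    config = config), class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("Cloverleaf, ", x$length, " nt, score ", x$score,
      if (is.null(x$d_arm)) ", D-armless", ", anticodon ", x$anticodon,
      "\n", sep = "")
  cat(as_dot_bracket(x), "\n")
  invisible(x)
}

#' Missing-arm flags for a folded structure
#'
#' The D-arm is called absent when the best-scoring D-armless placement
#' beats the best D-bearing placement by more than `margin` (default taken
#' from the structure's config, itself defaulting to 0, i.e. a strictly
#' better armless fold).
#'
#' @param structure a `cloverleaf` from [fold_cloverleaf()].
#' @param margin score margin; overrides the config's `d_margin`.
#' @return list with logical `d_arm_absent`.
#' @export
detect_missing_arms <- function(structure, margin = NULL) {
  stopifnot(inherits(structure, "cloverleaf"))
  if (is.null(margin)) margin <- structure$config$d_margin
  pres <- structure$score_d_present
  abs_ <- structure$score_d_absent
  d_absent <- !is.na(abs_) && (is.na(pres) || abs_ > pres + margin)
  list(d_arm_absent = d_absent)
}

#' Pair-class census over a set of structures
#'
#' Sums the per-slot pair labels of every arm of every structure. G-U
#' wobbles are censused as a mismatch class, following the convention of
#' mitogenome papers.
#'
#' @param structures list of `cloverleaf` objects (a single structure is
#'   accepted).
#' @return named integer vector over `WC`, `GU`, `CC`, `UU`, `CA`, `UC`,
#'   `other`; the total equals the number of scored pair slots.
#' @export
pair_census <- function(structures) {
  if (inherits(structures, "cloverleaf")) structures <- list(structures)
  stopifnot(length(structures) >= 1L,
            all(vapply(structures, inherits, logical(1), "cloverleaf")))
  labels <- unlist(lapply(structures, function(s) unlist(s$pair_labels)))
  lv <- c("WC", "GU", "CC", "UU", "CA", "UC", "other")
  out <- table(factor(labels, levels = lv))
  setNames(as.integer(out), lv)
}

#' Dot-bracket rendering of a cloverleaf
#'
#' @param structure a `cloverleaf`.
#' @return single dot-bracket string (nested, one bracket layer).
#' @export
as_dot_bracket <- function(structure) {
  stopifnot(inherits(structure, "cloverleaf"))
  db <- rep(".", structure$length)
  pairs <- rbind(structure$acceptor_stem,
                 if (!is.null(structure$d_arm)) structure$d_arm$stem_pairs,
                 structure$anticodon_arm$stem_pairs,
                 structure$t_arm$stem_pairs)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  paste(db, collapse = "")
}
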