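# Test helpers: independent oracles and small fixture builders. Everything
# here is deliberately plain (nested loops, direct counting) so it shares no
# code path with the package implementation it checks.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# direct per-letter counting, the independent composition oracle
count_base <- function(seq, base) {
  sum(strsplit(seq, "")[[1]] == base)
}

# extract the pair set of a cloverleaf as a sorted two-column matrix
structure_pairs <- function(st) {
  p <- rbind(st$acceptor_stem,
             if (!is.null(st$d_arm)) st$d_arm$stem_pairs,
             st$anticodon_arm$stem_pairs,
             st$t_arm$stem_pairs)
  p[order(p[, 1L]), , drop = FALSE]
}

# Brute-force cloverleaf oracle: plain nested loops over every admissible
# geometry, scoring pair by pair, with the documented tie-break (score,
# then Watson-Crick count, then total loop, then leftmost D-arm, then
# enumeration order). Independent of the package's vectorized search.
brute_force_fold_score <- function(seq, config = cloverleaf_config()) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  sc1 <- function(x, y) {
    xy <- paste0(x, y)
    if (xy %in% c("AU", "UA", "GC", "CG")) return(2)
    if (xy %in% c("GU", "UG")) return(1)
    if (xy %in% c("CC", "UU", "CA", "AC", "UC", "CU")) return(0)
    -1
  }
  wc1 <- function(x, y) paste0(x, y) %in% c("AU", "UA", "GC", "CG")
  best <- NULL
  d_options <- rbind(expand.grid(d = config$d_stem, dl = config$d_loop),
                     data.frame(d = 0L, dl = config$d_linker))
  for (g1 in config$spacer1) for (r in seq_len(nrow(d_options))) {
    d <- d_options$d[r]; dl <- d_options$dl[r]
    dspan <- 2L * d + dl
    for (g2 in config$spacer2) for (tt in config$t_stem)
      for (tl in config$t_loop) {
        v <- L - 14L - g1 - dspan - g2 - 17L - 2L * tt - tl
        if (v < min(config$var_region) || v > max(config$var_region)) next
        score <- 0; nwc <- 0L
        for (i in 1:7) {
          score <- score + sc1(ch[i], ch[L - i + 1L])
          nwc <- nwc + wc1(ch[i], ch[L - i + 1L])
        }
        a <- 8L + g1
        if (d > 0L) for (k in seq_len(d)) {
          score <- score + sc1(ch[a + k - 1L], ch[a + dspan - k])
          nwc <- nwc + wc1(ch[a + k - 1L], ch[a + dspan - k])
        }
        b <- a + dspan + g2
        for (k in 1:5) {
          score <- score + sc1(ch[b + k - 1L], ch[b + 17L - k])
          nwc <- nwc + wc1(ch[b + k - 1L], ch[b + 17L - k])
        }
        c0 <- b + 17L + v
        for (k in seq_len(tt)) {
          score <- score + sc1(ch[c0 + k - 1L], ch[c0 + 2L * tt + tl - k])
          nwc <- nwc + wc1(ch[c0 + k - 1L], ch[c0 + 2L * tt + tl - k])
        }
        loops <- (if (d > 0L) dl else 0L) + 7L + tl
        cand <- list(score = score, nwc = nwc, loops = loops, g1 = g1)
        if (is.null(best) ||
            score > best$score ||
            (score == best$score && nwc > best$nwc) ||
            (score == best$score && nwc == best$nwc && loops < best$loops) ||
            (score == best$score && nwc == best$nwc && loops == best$loops &&
             g1 < best$g1))
          best <- cand
      }
  }
  best
}

# Hand-built perfect cloverleaf with a chosen geometry; stems are written
# explicitly (5' string and its reverse complement), loops are all-A.
handmade_cloverleaf <- function(acc = "GGCGGCA", d5 = "GCUC", dl = 8,
                               g1 = 2, g2 = 1, ac5 = "CUGGC",
                               anticodon = "UGC", v = 4, t5 = "GGUCC",
                               tl = 7, d_armless = FALSE) {
  rc <- function(x) {
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  loop <- function(n) strrep("A", n)
  ac_loop <- paste0("AA", anticodon, "AA")
  d_part <- if (d_armless) loop(5) else paste0(d5, loop(dl), rc(d5))
  paste0(acc, loop(g1), d_part, loop(g2),
         ac5, ac_loop, rc(ac5), loop(v),
         t5, loop(tl), rc(t5), rc(acc))
}

# additive distance matrix from a phylo tree by leaf-to-leaf path sums
path_sum_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# all clades of a rooted tree by brute-force descendant enumeration
all_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply((ntip + 1L):(ntip + tree$Nnode), function(nd) {
    sort(tree$tip.label[unlist(ape::prop.part(tree)[[nd - ntip]])])
  })
}

# simulated caridina-layout genome, cached per test run for speed
sim_fixture <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache) || cache$truth$seed != seed)
      cache <<- simulate_genome(seed = seed)
    cache
  }
})
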