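#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa are the union over genes; a taxon missing from a gene is gap-filled
#' for that partition (with a warning). Partition column spans are recorded
#' so downstream code can tell which columns came from which gene.
#'
#' @param per_gene_alignments named list: gene -> named character vector of
#'   equal-length aligned sequences (nucleotide or amino acid, `-` gaps).
#' @return object of class `supermatrix`: `taxa`, `seqs` (named character
#'   vector of concatenated rows), `partitions` (data frame `gene`, `start`,
#'   `end`), `ncol`.
#' @export
concat_supermatrix <- function(per_gene_alignments) {
  stopifnot(is.list(per_gene_alignments), length(per_gene_alignments) >= 1L,
            !is.null(names(per_gene_alignments)))
  for (g in names(per_gene_alignments)) {
    aln <- per_gene_alignments[[g]]
    if (is.null(names(aln)) || length(unique(nchar(aln))) != 1L)
      stop("alignment error in gene '", g,
           "': sequences must be named and of equal length")
  }
  taxa <- unique(unlist(lapply(per_gene_alignments, names)))
  parts <- list(); col <- 0L
  rows <- setNames(rep("", length(taxa)), taxa)
  for (g in names(per_gene_alignments)) {
    aln <- per_gene_alignments[[g]]
    w <- nchar(aln[[1L]])
    missing <- setdiff(taxa, names(aln))
    if (length(missing))
      warning("gene '", g, "': taxa gap-filled: ",
              paste(missing, collapse = ", "))
    block <- setNames(rep(strrep("-", w), length(taxa)), taxa)
    block[names(aln)] <- aln
    rows <- paste0(rows, block)
    parts[[g]] <- data.frame(gene = g, start = col + 1L, end = col + w,
                             stringsAsFactors = FALSE)
    col <- col + w
  }
  names(rows) <- taxa
  structure(list(taxa = taxa, seqs = rows,
                 partitions = do.call(rbind, c(parts, list(make.row.names = FALSE))),
                 ncol = col),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix: ", length(x$taxa), " taxa x ", x$ncol, " columns, ",
      nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

#' Pairwise p-distance matrix with pairwise gap deletion
#'
#' `d(i, j)` is the proportion of mismatching columns among columns where
#' neither row has a gap (`-`, `?` or `.`). Optionally Poisson-corrected
#' (`-log(1 - p)`), the simple multiple-hit correction for amino-acid data.
#'
#' @param sm a `supermatrix` (or named character vector of equal-length
#'   sequences).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(sm, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  seqs <- if (inherits(sm, "supermatrix")) sm$seqs else sm
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            length(unique(nchar(seqs))) == 1L)
  n <- length(seqs)
  if (n < 2L) stop("at least 2 taxa required")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  isgap <- m %in% c("-", "?", ".")
  dim(isgap) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- !isgap[i, ] & !isgap[j, ]
    nc <- sum(use)
    if (nc == 0L)
      stop("undefined distance: no comparable columns between '",
           names(seqs)[i], "' and '", names(seqs)[j], "'")
    p <- sum(m[i, use] != m[j, use]) / nc
    if (correction == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p = 1")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the standard Q-criterion. At each step
#' the pair minimizing Q is joined; ties are broken by the smallest (i, j)
#' index pair in the current matrix order. Negative branch-length estimates
#' are clamped to zero and the clamped deficit reported via a message. The
#' result is an unrooted `ape::phylo` tree, so all of ape's tooling applies
#' downstream.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return unrooted tree of class `phylo`.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # nodes are newick fragments; heights carried implicitly by branch lengths
  frag <- labels
  clamped <- 0
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    # smallest (i, j), i < j, among minima
    minq <- min(q)
    hits <- which(q - minq <= 1e-12 * max(1, abs(minq)), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    bi <- 0.5 * d[i, j] + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { clamped <- clamped - bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped - bj; bj <- 0 }
    newd <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":", fmt(bj), ")")
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    n <- n - 1L
  }
  # final three-point resolution
  b1 <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  b2 <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  b3 <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  b <- c(b1, b2, b3)
  if (any(b < 0)) { clamped <- clamped + sum(-b[b < 0]); b[b < 0] <- 0 }
  if (clamped > 0)
    message("neighbor_joining: clamped negative branch lengths, total deficit ",
            signif(clamped, 6))
  nwk <- paste0("(", frag[1], ":", fmt(b[1]), ",", frag[2], ":", fmt(b[2]),
                ",", frag[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so the
#' outgroup becomes the sister of everything else and all leaf-to-leaf path
#' lengths are preserved.
#'
#' @param t a `phylo` tree.
#' @param outgroup leaf name.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(t, outgroup) {
  stopifnot(inherits(t, "phylo"))
  if (!outgroup %in% t$tip.label) stop("unknown taxon: ", outgroup)
  tip <- which(t$tip.label == outgroup)
  pend <- which(t$edge[, 2L] == tip)
  blen <- t$edge.length[pend]
  rt <- ape::root(t, outgroup = outgroup, resolve.root = TRUE)
  # split the pendant edge evenly between outgroup and ingroup root edges
  root_node <- ape::Ntip(rt) + 1L
  kids <- which(rt$edge[, 1L] == root_node)
  og_edge <- kids[rt$edge[kids, 2L] == which(rt$tip.label == outgroup)]
  in_edge <- setdiff(kids, og_edge)
  extra <- rt$edge.length[og_edge] - blen / 2
  rt$edge.length[og_edge] <- blen / 2
  rt$edge.length[in_edge] <- rt$edge.length[in_edge] + extra
  rt
}

#' Exact monophyly query
#'
#' TRUE iff some node of the rooted tree has exactly the query set as its
#' leaf descendants. Delegates to [ape::is.monophyletic()].
#'
#' @param t rooted `phylo` tree.
#' @param taxa character vector of leaf names.
#' @return logical.
#' @export
is_monophyletic <- function(t, taxa) {
  stopifnot(inherits(t, "phylo"))
  unknown <- setdiff(taxa, t$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  ape::is.monophyletic(t, taxa)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that accept
#' either a file path or literal Newick text, check parse success, and write
#' branch lengths at 10 significant digits so round-trips preserve topology
#' and lengths.
#'
#' @param x path to a Newick file, or a Newick string (for `read_newick`).
#' @return `read_newick`: a `phylo` tree.
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')')")
  t <- tryCatch(ape::read.tree(text = txt),
                error = function(e) stop("Newick parse error: ",
                                         conditionMessage(e)))
  if (is.null(t)) stop("Newick parse error: unparseable input")
  t
}

#' @rdname read_newick
#' @param t a `phylo` tree.
#' @param path output path, or `NULL` to return the Newick string.
#' @return `write_newick`: the Newick string, invisibly when written to file.
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  txt <- ape::write.tree(t, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
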