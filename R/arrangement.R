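#' Circular adjacency census of an annotation
#'
#' For each consecutive pair of features in plus-strand start order -
#' including the wrap-around pair from the last feature back to the first -
#' computes the signed gap `next.start - prev.end - 1` under circular
#' arithmetic: positive gaps are intergenic spacers, negative gaps are
#' overlaps, zero means abutting. The wrap-around gap is attributed to the
#' last feature's record, matching the convention of printed gene tables.
#'
#' @param ag an `annotated_genome` (sequence not required).
#' @return data frame with columns `upstream`, `downstream`, `gap` (signed
#'   bp), one row per adjacency, forming a single cycle over the features.
#' @export
adjacency_census <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  fe <- ag$features
  L <- ag$genome$length
  if (nrow(fe) == 1L) {  # degenerate closed circle: one self-adjacency
    gap <- if (fe$start > fe$end) fe$start - fe$end - 1L else
      (fe$start + L) - fe$end - 1L
    return(data.frame(upstream = fe$name, downstream = fe$name,
                      gap = as.integer(gap), stringsAsFactors = FALSE))
  }
  if (anyDuplicated(fe[, c("start", "end")]))
    warning("features with identical coordinates; order is (start, end, name)")
  n <- nrow(fe)
  nxt <- c(2:n, 1L)
  gap <- fe$start[nxt] - fe$end - 1L
  # wrap-around pair: measured through the origin
  gap[n] <- (fe$start[1L] + L) - fe$end[n] - 1L
  # features that themselves wrap (start > end) end at `end` on the far side
  wraps <- fe$start > fe$end
  if (any(wraps)) {
    for (i in which(wraps)) {
      j <- nxt[i]
      gap[i] <- fe$start[j] - fe$end[i] - 1L
      if (i == n) gap[i] <- fe$start[1L] - fe$end[n] - 1L
    }
  }
  data.frame(upstream = fe$name, downstream = fe$name[nxt],
             gap = as.integer(gap), stringsAsFactors = FALSE)
}

#' Summary of spacers and overlaps
#'
#' @param records data frame from [adjacency_census()].
#' @return list: `n_spacers`, `spacer_range` (min/max positive gap),
#'   `largest_spacer` (upstream/downstream pair), `n_overlaps`,
#'   `overlap_range` (min/max absolute overlap), `largest_overlap`.
#' @export
summarize_arrangement <- function(records) {
  stopifnot(all(c("upstream", "downstream", "gap") %in% names(records)))
  sp <- records[records$gap > 0L, , drop = FALSE]
  ov <- records[records$gap < 0L, , drop = FALSE]
  rng <- function(x) if (length(x)) range(x) else c(NA_integer_, NA_integer_)
  pair <- function(df, i) if (nrow(df)) unlist(df[i, c("upstream", "downstream")]) else NULL
  list(n_spacers = nrow(sp), spacer_range = rng(sp$gap),
       largest_spacer = pair(sp, which.max(sp$gap)),
       n_overlaps = nrow(ov), overlap_range = rng(abs(ov$gap)),
       largest_overlap = pair(ov, which.max(-ov$gap)))
}

#' Canonical gene-order signature
#'
#' A strand-signed, rotation-invariant rendering of the gene order: gene
#' names in plus-strand start order, minus-strand genes prefixed `"-"`,
#' rotated to start at `cox1` (or at the lexicographically minimal rotation
#' when `cox1` is absent). Duplicate names are suffixed `.2`, `.3`, ... in
#' order of occurrence.
#'
#' @param ag an `annotated_genome`.
#' @return single space-separated string.
#' @export
gene_order_signature <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  fe <- ag$features
  nm <- fe$name
  dup <- ave(seq_along(nm), nm, FUN = seq_along)
  nm[dup > 1L] <- paste0(nm[dup > 1L], ".", dup[dup > 1L])
  signed <- ifelse(fe$strand == "-", paste0("-", nm), nm)
  n <- length(signed)
  rot <- function(k) signed[c(k:n, if (k > 1L) 1:(k - 1L))]
  anchor <- which(nm == "cox1")
  if (length(anchor) >= 1L) {
    out <- rot(anchor[1L])
  } else {
    cands <- vapply(1:n, function(k) paste(rot(k), collapse = " "), character(1))
    out <- rot(which.min(rank(cands, ties.method = "first")))
  }
  paste(out, collapse = " ")
}
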