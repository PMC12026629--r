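#' Read a FASTA file
#'
#' Light FASTA reader with strict diagnostics: malformed headers, sequence
#' lines before any header, and empty records are reported with the
#' offending line number. Sequences are uppercased and U is normalized to T;
#' only A/C/G/T/N (and U) are accepted.
#'
#' @param path path to a FASTA file.
#' @return named character vector of DNA sequences, in file order; names are
#'   the full header lines without the leading `>`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("FASTA format error: empty file ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L])
    stop("FASTA format error at line ", idx[1L], ": sequence before header")
  ids <- sub("^>", "", lines[hdr])
  if (any(!nzchar(trimws(ids)))) {
    bad <- idx[hdr][!nzchar(trimws(ids))][1L]
    stop("FASTA format error at line ", bad, ": empty header")
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""),
                 character(1))
  out <- setNames(rep("", sum(hdr)), ids)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    bad <- idx[hdr][!nzchar(out)][1L]
    stop("FASTA format error at line ", bad, ": record has no sequence")
  }
  out <- vapply(out, normalize_dna, character(1))
  alien <- gsub("[ACGTN]", "", out)
  if (any(nzchar(alien))) {
    i <- which(nzchar(alien))[1L]
    stop("FASTA format error in record '", names(out)[i],
         "': invalid characters '",
         paste(unique(strsplit(alien[i], "")[[1]]), collapse = ""), "'")
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
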