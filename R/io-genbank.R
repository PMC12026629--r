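# Minimal GenBank flat-file support: enough to carry an annotated circular
# mitogenome (CDS/tRNA/rRNA/misc_feature, complement() and join() locations,
# /gene //product //note //transl_table qualifiers, ORIGIN block). Not a
# general GenBank parser.

parse_gb_location <- function(loc, line_no) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
    first <- as.integer(sub("\\.\\..*$", "", parts[1L]))
    last <- as.integer(sub("^.*\\.\\.", "", parts[length(parts)]))
    return(list(start = first, end = last, strand = strand))
  }
  if (!grepl("^\\d+\\.\\.\\d+$", loc) && !grepl("^\\d+$", loc))
    stop("GenBank format error at line ", line_no,
         ": unsupported location '", loc, "'")
  se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(se) == 1L) se <- c(se, se)
  list(start = se[1L], end = se[2L], strand = strand)
}

#' Read a GenBank flat file as an annotated genome
#'
#' Parses the FEATURES and ORIGIN sections of a GenBank flat file into an
#' [annotated_genome()]. CDS features become PCGs, `tRNA`/`rRNA` keep their
#' category, and `misc_feature`/`D-loop` features become the control region.
#' `complement(...)` locations set the minus strand and `join(...)` across
#' the origin yields a wrap-aware feature (`start > end`). Anticodons are
#' taken from `/note` or `/product` qualifiers of the form `anticodon:NNN`;
#' `/transl_table` is captured on the returned object.
#'
#' @param path path to a GenBank flat file.
#' @return an `annotated_genome`; element `transl_table` carries the
#'   translation-table id (NA when absent).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L)
    stop("GenBank format error: missing ORIGIN section in ", path)
  if (length(fstart) == 0L)
    stop("GenBank format error: missing FEATURES section in ", path)
  fstart <- fstart[1L]; ostart <- ostart[1L]

  # --- sequence ---
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart][1L] else length(lines) + 1L
  seq_lines <- lines[seq.int(ostart + 1L, oend - 1L)]
  sequence <- normalize_dna(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop("GenBank format error: empty ORIGIN section in ", path)

  # --- features ---
  feat_lines <- seq.int(fstart + 1L, ostart - 1L)
  keys <- character(); quals <- list(); locs <- list(); lnos <- integer()
  cur_qual <- NULL
  for (i in feat_lines) {
    ln <- lines[i]
    if (grepl("^     \\S", ln)) {            # new feature line
      key <- sub("^\\s*(\\S+)\\s.*$", "\\1", ln)
      loc <- trimws(sub("^\\s*\\S+\\s+", "", ln))
      keys <- c(keys, key); locs <- c(locs, loc); lnos <- c(lnos, i)
      quals[[length(keys)]] <- character()
      cur_qual <- NULL
    } else if (grepl("^\\s+/", ln) && length(keys)) {
      quals[[length(keys)]] <- c(quals[[length(keys)]], trimws(ln))
      cur_qual <- length(quals[[length(keys)]])
    } else if (!is.null(cur_qual) && length(keys)) {  # continuation line
      k <- length(keys)
      quals[[k]][cur_qual] <- paste(quals[[k]][cur_qual], trimws(ln))
    }
  }

  qual_value <- function(q, name) {
    hit <- grep(paste0("^/", name, "[=$]?"), q, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    v <- sub(paste0("^/", name, "=?"), "", hit[1L])
    gsub('^"|"$', "", v)
  }

  transl_table <- NA_integer_
  rows <- list()
  for (k in seq_along(keys)) {
    key <- keys[k]
    if (key %in% c("source", "gene")) {
      tt <- qual_value(quals[[k]], "transl_table")
      if (!is.na(tt)) transl_table <- as.integer(tt)
      next
    }
    category <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       misc_feature = "CR", "D-loop" = "CR", NA_character_)
    if (is.na(category)) next
    loc <- parse_gb_location(locs[[k]], lnos[k])
    if (max(loc$start, loc$end) > nchar(sequence))
      stop("GenBank coordinate error at line ", lnos[k], ": feature ",
           locs[[k]], " beyond sequence length ", nchar(sequence))
    q <- quals[[k]]
    tt <- qual_value(q, "transl_table")
    if (!is.na(tt)) transl_table <- as.integer(tt)
    name <- qual_value(q, "gene")
    if (is.na(name)) name <- qual_value(q, "product")
    if (is.na(name)) name <- paste0(key, "_", k)
    anticodon <- NA_character_
    for (src in c(qual_value(q, "note"), qual_value(q, "product"))) {
      if (!is.na(src) && grepl("anticodon[:= ]*[ACGTUacgtu]{3}", src)) {
        anticodon <- toupper(sub(".*anticodon[:= ]*([ACGTUacgtu]{3}).*",
                                 "\\1", src))
        break
      }
    }
    rows[[length(rows) + 1L]] <-
      gene_features(normalize_gene_name(name), category, loc$strand,
                    loc$start, loc$end, anticodon)
  }
  if (length(rows) == 0L) stop("GenBank format error: no usable features")
  ag <- annotated_genome(circular_genome(sequence),
                         do.call(rbind, rows))
  ag$transl_table <- transl_table
  ag
}

#' Write an annotated genome as a minimal GenBank flat file
#'
#' Emits LOCUS, FEATURES (CDS/tRNA/rRNA/misc_feature with `complement()`
#' and origin-spanning `join()` locations, `/gene` and anticodon `/note`
#' qualifiers) and ORIGIN, sufficient for [read_genbank()] to round-trip
#' every feature's name, strand and coordinates.
#'
#' @param ag an `annotated_genome` with sequence.
#' @param path output path.
#' @param locus_name name for the LOCUS line.
#' @param transl_table translation-table id written on CDS features.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(ag, path, locus_name = "mitogenome",
                          transl_table = 5L) {
  stopifnot(inherits(ag, "annotated_genome"))
  if (is.null(ag$genome$sequence)) stop("genome carries no sequence")
  L <- ag$genome$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular INV",
                     locus_name, L), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  fe <- ag$features
  for (i in seq_len(nrow(fe))) {
    f <- fe[i, ]
    key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "misc_feature")
    span <- if (f$start <= f$end) sprintf("%d..%d", f$start, f$end) else
      sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
    if (f$strand == "-") span <- sprintf("complement(%s)", span)
    writeLines(sprintf("     %-15s %s", key, span), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (f$category == "CR")
      writeLines('                     /note="control region"', con)
    if (f$category == "PCG")
      writeLines(sprintf("                     /transl_table=%d",
                         transl_table), con)
    if (!is.na(f$anticodon))
      writeLines(sprintf('                     /note="anticodon:%s"',
                         f$anticodon), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(ag$genome$sequence)
  pos <- seq.int(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Normalize gene-name aliases
#'
#' Maps the common alternative spellings of mitochondrial gene names onto
#' the canonical short forms used throughout the package (`cox1` for COI,
#' `cob` for cytb, `rrnL` for 16S, `rrnS` for 12S, and case variants).
#'
#' @param x character vector of gene names.
#' @return canonical names.
#' @export
normalize_gene_name <- function(x) {
  map <- c(coi = "cox1", coii = "cox2", coiii = "cox3",
           co1 = "cox1", co2 = "cox2", co3 = "cox3",
           cytb = "cob", cytB = "cob", cob = "cob",
           "16s" = "rrnL", "16s rrna" = "rrnL", "rrn16" = "rrnL",
           "12s" = "rrnS", "12s rrna" = "rrnS", "rrn12" = "rrnS",
           "d-loop" = "CR", "control region" = "CR")
  out <- as.character(x)
  key <- tolower(out)
  hit <- key %in% names(map)
  out[hit] <- map[key[hit]]
  key <- tolower(out)
  std <- grepl("^(cox[123]|atp[68]|nad[1-6]|cob)$", key)
  out[std] <- key[std]
  out[key == "nad4l"] <- "nad4L"
  out[key == "rrnl"] <- "rrnL"
  out[key == "rrns"] <- "rrnS"
  trn <- grepl("^trn[a-z][12]?$", key)
  out[trn] <- paste0("trn", toupper(substr(key[trn], 4L, 4L)),
                     substr(key[trn], 5L, 5L))
  unname(out)
}
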