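#' Read and write FASTA
#'
#' Thin wrappers over Biostrings for raw (unannotated) sequences.
#'
#' @param x A named character vector of sequences, or a (named) list of
#'   `stst_dna` objects.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x)) {
    x <- vapply(x, function(el) {
      if (inherits(el, "stst_dna")) el$residues else as.character(el)
    }, character(1))
  }
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write an annotated molecule as a GenBank flat file
#'
#' A minimal GenBank writer/reader pair for the package's own annotated
#' molecules (vectors and assembly products): LOCUS topology, `misc_feature`
#' entries with `/label` qualifiers (origin-spanning features on circular
#' molecules are written as `join(...)`), and the ORIGIN sequence block.
#' `read_genbank()` round-trips files written by `write_genbank()`.
#'
#' @param x An `stst_dna`.
#' @param path File path.
#' @param name LOCUS name (defaults to the molecule id).
#' @export
write_genbank <- function(x, path, name = NULL) {
  stopifnot(inherits(x, "stst_dna"))
  name <- name %||% x$id %||% "molecule"
  len <- nchar(x$residues)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
            name, len, x$topology),
    "DEFINITION  synthetic construct.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len)
  )
  if (nrow(x$features)) {
    for (i in seq_len(nrow(x$features))) {
      f <- x$features[i, ]
      loc <- if (f$end <= len) {
        sprintf("%d..%d", f$start + 1L, f$end)
      } else {
        sprintf("join(%d..%d,1..%d)", f$start + 1L, len, f$end - len)
      }
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines,
                 sprintf("     misc_feature    %s", loc),
                 sprintf("                     /label=\"%s\"", f$label))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(x$residues)
  for (at in seq(1L, len, by = 60L)) {
    chunk <- substr(s, at, min(at + 59L, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", at, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genbank
#' @return `read_genbank()` returns an `stst_dna`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  topology <- if (grepl("circular", locus)) "circular" else "linear"
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  origin_at <- which(grepl("^ORIGIN", lines))[1]
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^acgtACGT]", "", paste(seq_lines, collapse = "")))

  feat_rows <- list()
  i <- which(grepl("^FEATURES", lines))[1] + 1L
  while (i < origin_at) {
    ln <- lines[i]
    if (grepl("^\\s{5}misc_feature\\s+", ln)) {
      loc <- trimws(sub("^\\s{5}misc_feature\\s+", "", ln))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^join\\(", loc)) {
        inner <- sub("^join\\((.*)\\)$", "\\1", loc)
        parts <- strsplit(inner, ",")[[1]]
        r1 <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
        r2 <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
        start <- r1[1] - 1L
        end <- nchar(residues) + r2[2]
      } else {
        r <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        start <- r[1] - 1L
        end <- r[2]
      }
      label <- NA_character_
      if (grepl("/label=", lines[i + 1L])) {
        label <- sub('.*?/label="(.*)".*', "\\1", lines[i + 1L])
        i <- i + 1L
      }
      feat_rows[[length(feat_rows) + 1L]] <- tibble::tibble(
        label = label, start = start, end = end, strand = strand)
    }
    i <- i + 1L
  }
  dna(residues, topology = topology,
      features = if (length(feat_rows)) dplyr::bind_rows(feat_rows) else NULL,
      id = name)
}
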