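#' DNA sequence objects
#'
#' `dna()` builds a strict double-stranded DNA sequence object: an A/C/G/T
#' top strand, a topology (`"linear"` or `"circular"`) and an optional feature
#' table. Coordinates are 0-based, half-open throughout the package; features
#' on circular molecules may wrap past the origin (`end` up to
#' `start + length`).
#'
#' @param residues Character scalar over the strict alphabet `A`, `C`, `G`,
#'   `T`. Ambiguity codes are rejected.
#' @param topology `"linear"` or `"circular"`.
#' @param features Optional tibble/data frame with columns `label`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`); 0-based half-open coordinates.
#' @param id Optional molecule identifier used in provenance records.
#' @return An object of class `stst_dna` with fields `residues`, `topology`,
#'   `features` and `id`.
#' @examples
#' dna("ATGTAA")
#' dna("GCTCTTCA", topology = "circular")
#' @export
dna <- function(residues, topology = c("linear", "circular"), features = NULL,
                id = NULL) {
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    rlang::abort("`residues` must be a single string.", class = "stst_alphabet_error")
  }
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    rlang::abort("`residues` must be non-empty.", class = "stst_alphabet_error")
  }
  if (stringi::stri_detect_regex(residues, "[^ACGT]")) {
    bad <- unique(strsplit(gsub("[ACGT]", "", residues), "")[[1]])
    rlang::abort(
      paste0("Non-ACGT character(s) in sequence: ", paste(bad, collapse = ", "),
             ". Ambiguity codes are not supported."),
      class = "stst_alphabet_error"
    )
  }
  len <- nchar(residues)
  features <- validate_features(features, len, topology)
  structure(
    list(residues = residues, topology = topology, features = features, id = id),
    class = "stst_dna"
  )
}

validate_features <- function(features, len, topology) {
  if (is.null(features) || (is.data.frame(features) && nrow(features) == 0L)) {
    return(tibble::tibble(label = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  features <- tibble::as_tibble(features)
  needed <- c("label", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    rlang::abort(paste0("Feature table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  features <- features[needed]
  wrap <- if (topology == "circular") len else 0L
  ok <- features$start >= 0 & features$start < len &
    features$end > features$start & features$end <= len + wrap &
    features$strand %in% c("+", "-")
  if (!all(ok)) {
    rlang::abort(paste0("Feature coordinates out of bounds for ",
                        topology, " molecule of length ", len, "."))
  }
  features
}

#' @export
print.stst_dna <- function(x, ...) {
  cat(sprintf("<stst_dna> %s, %d bp%s\n", x$topology, nchar(x$residues),
              if (!is.null(x$id)) paste0(", id: ", x$id) else ""))
  res <- x$residues
  shown <- if (nchar(res) > 60) paste0(substr(res, 1, 57), "...") else res
  cat(" ", shown, "\n")
  if (nrow(x$features)) {
    cat(sprintf("  %d feature(s)\n", nrow(x$features)))
  }
  invisible(x)
}

#' @export
length.stst_dna <- function(x) nchar(x$residues)

as_dna <- function(x, topology = "linear", id = NULL) {
  if (inherits(x, "stst_dna")) return(x)
  dna(x, topology = topology, id = id)
}

# 0-based half-open substring with modular wrap on circular molecules.
wrap_sub <- function(s, start0, width, len = nchar(s)) {
  start0 <- start0 %% len
  if (width <= 0) return("")
  if (start0 + width <= len) {
    substr(s, start0 + 1L, start0 + width)
  } else {
    paste0(substr(s, start0 + 1L, len),
           substr(s, 1L, width - (len - start0)))
  }
}

revcomp_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", stringi::stri_reverse(x))
}

#' Reverse complement
#'
#' Involution on the strict ACGT alphabet; length and topology are preserved.
#' Features are remapped to the opposite strand and mirrored coordinates.
#'
#' @param x An `stst_dna` object or a character vector of ACGT strings.
#' @return The reverse complement, of the same type as the input.
#' @examples
#' reverse_complement("ATG")   # "CAT"
#' reverse_complement(dna("TAA"))
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) {
  if (any(stringi::stri_detect_regex(x, "[^ACGTacgt]"))) {
    rlang::abort("Non-ACGT character in input.", class = "stst_alphabet_error")
  }
  revcomp_chr(x)
}

#' @export
reverse_complement.stst_dna <- function(x) {
  len <- nchar(x$residues)
  feats <- x$features
  if (nrow(feats)) {
    new_start <- len - feats$end
    new_end <- len - feats$start
    # wrapped circular features map to wrapped features anchored in-bounds
    shift <- ifelse(new_start < 0, len, 0L)
    feats <- tibble::tibble(
      label = feats$label,
      start = as.integer(new_start + shift),
      end = as.integer(new_end + shift),
      strand = ifelse(feats$strand == "+", "-", "+")
    )
  }
  dna(revcomp_chr(x$residues), topology = x$topology, features = feats, id = x$id)
}

# Lexicographically smallest rotation of a circular top strand; used to give
# every assembly product a single canonical representation.
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  doubled <- c(chars, chars)
  cand <- which(chars == min(chars))  # 1-based rotation starts
  k <- 0L
  while (length(cand) > 1L && k < n) {
    ch <- doubled[cand + k]
    cand <- cand[ch == min(ch)]
    k <- k + 1L
  }
  start <- cand[1L]
  paste0(substr(s, start, n), substr(s, 1, start - 1L))
}

#' Canonicalize a circular molecule
#'
#' Rotates a circular `stst_dna` to its lexicographically smallest top-strand
#' rotation, so that identical circular products compare equal as strings.
#' Features are dropped unless remappable; linear input is returned unchanged.
#'
#' @param x An `stst_dna`.
#' @return An `stst_dna` in canonical rotation.
#' @export
canonicalize <- function(x) {
  stopifnot(inherits(x, "stst_dna"))
  if (x$topology != "circular") return(x)
  s <- canonical_rotation(x$residues)
  if (identical(s, x$residues)) return(x)
  len <- nchar(s)
  # offset of the rotation: position in old coords that became 0
  off <- stringi::stri_locate_first_fixed(paste0(x$residues, x$residues), s)[1, 1] - 1L
  feats <- x$features
  if (nrow(feats)) {
    start <- (feats$start - off) %% len
    width <- feats$end - feats$start
    feats$start <- as.integer(start)
    feats$end <- as.integer(start + width)
  }
  dna(s, topology = "circular", features = feats, id = x$id)
}
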