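#' Scan a molecule for type IIS recognition sites
#'
#' Reports every occurrence of the enzyme's recognition sequence on either
#' strand. On circular molecules, occurrences spanning the origin are found.
#' Positions are 0-based starts of the recognition sequence read 5'->3' on the
#' reported strand.
#'
#' @param x An `stst_dna` (or ACGT string, taken as linear).
#' @param enz Enzyme name or `stst_enzyme`.
#' @return A tibble with columns `position` (0-based) and `strand`
#'   (`"top"`/`"bottom"`), sorted by top-strand location; zero rows when the
#'   site is absent.
#' @examples
#' scan_sites(dna("AAAAGCTCTTCTATGCCCC"), "SapI")
#' @export
scan_sites <- function(x, enz) {
  x <- as_dna(x)
  enz <- enzyme(enz)
  hits <- scan_top_coords(x, enz)
  len <- nchar(x$residues)
  L <- nchar(enz$recognition)
  pos <- ifelse(hits$strand == "top", hits$top_start,
                (len - (hits$top_start + L)) %% max(len, 1L))
  tibble::tibble(position = as.integer(pos), strand = hits$strand)
}

# Internal scan in top-strand coordinates: `top_start` is the 0-based start of
# the recognition sequence (for bottom-strand hits, of its reverse complement)
# on the top strand. Circular molecules are scanned across the origin.
scan_top_coords <- function(x, enz) {
  s <- x$residues
  len <- nchar(s)
  L <- nchar(enz$recognition)
  search_space <- if (x$topology == "circular" && len > 1) {
    paste0(s, substr(s, 1L, min(L - 1L, len)))
  } else {
    s
  }
  find <- function(pattern) {
    m <- stringi::stri_locate_all_fixed(search_space, pattern,
                                        overlap = TRUE)[[1]]
    starts <- m[, 1]
    starts <- starts[!is.na(starts)] - 1L   # to 0-based
    starts[starts < len]                    # dedupe wrap copies
  }
  top <- find(enz$recognition)
  bottom <- find(revcomp_chr(enz$recognition))
  out <- tibble::tibble(
    top_start = as.integer(c(top, bottom)),
    strand = rep(c("top", "bottom"), c(length(top), length(bottom)))
  )
  out[order(out$top_start, out$strand), ]
}
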