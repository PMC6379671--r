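#' Cohesive ends and DNA fragments
#'
#' A cohesive end is a 5' single-stranded protrusion left by a type IIS cut:
#' `protrusion` is its 5'->3' sequence, `strand` records whether the
#' protruding strand is the top or the bottom strand, and `site_label` holds
#' the fusion-site name of the junction when known. Blunt ends carry an empty
#' protrusion. In this package's bookkeeping every fragment's *left* sticky
#' end protrudes on the top strand and every *right* sticky end on the bottom
#' strand, the geometry produced by 5'-overhang enzymes.
#'
#' @param protrusion 5'->3' sequence of the extension (`""` for blunt).
#' @param strand `"top"` or `"bottom"`.
#' @param site_label Optional fusion-site name.
#' @return An object of class `stst_end`.
#' @export
cohesive_end <- function(protrusion = "", strand = c("top", "bottom"),
                         site_label = NA_character_) {
  strand <- match.arg(strand)
  structure(list(protrusion = toupper(protrusion), strand = strand,
                 site_label = site_label),
            class = "stst_end")
}

blunt_end <- function(strand = "top") cohesive_end("", strand)

is_blunt <- function(e) !nzchar(e$protrusion)

#' @export
print.stst_end <- function(x, ...) {
  cat(if (is_blunt(x)) "<stst_end> blunt\n" else
    sprintf("<stst_end> 5'-%s (%s strand)%s\n", x$protrusion, x$strand,
            if (!is.na(x$site_label)) paste0(" [", x$site_label, "]") else ""))
  invisible(x)
}

new_fragment <- function(top, left, right, provenance = list(), uncut = FALSE) {
  structure(list(
    duplex = dna(top, topology = if (uncut) "circular" else "linear"),
    left_end = left, right_end = right,
    provenance = provenance, uncut = uncut
  ), class = "stst_fragment")
}

#' @export
print.stst_fragment <- function(x, ...) {
  if (isTRUE(x$uncut)) {
    cat(sprintf("<stst_fragment> uncut circular molecule, %d bp\n",
                nchar(x$duplex$residues)))
    return(invisible(x))
  }
  lab <- function(e) if (is_blunt(e)) "blunt" else
    sprintf("%s(%s)", e$protrusion, substr(e$strand, 1, 1))
  cat(sprintf("<stst_fragment> %d nt top strand, ends %s | %s  [%s]\n",
              nchar(x$duplex$residues), lab(x$left_end), lab(x$right_end),
              x$provenance$id %||% "?"))
  invisible(x)
}

fragment_length <- function(f) nchar(f$duplex$residues)

#' Complete digestion with a type IIS enzyme
#'
#' Simulates complete digestion at every recognition site on both strands.
#' Each cut removes the phosphodiester bonds at the enzyme's offsets, leaving
#' 5' protrusions; each internal junction's overhang bases appear on exactly
#' one fragment's top strand (the downstream fragment), so top-strand lengths
#' sum to the input length. Circular input with k sites yields k fragments,
#' linear input yields k+1 (terminal fragments blunt-ended). Cut windows that
#' would fall off a linear molecule are skipped with a warning. Fragments are
#' returned in order of top-strand position.
#'
#' @param x An `stst_dna`.
#' @param enz Enzyme name or `stst_enzyme`.
#' @param id Molecule id recorded in fragment provenance (defaults to `x$id`).
#' @return A list of `stst_fragment`. A circular molecule with no sites is
#'   returned as a single fragment flagged `uncut`.
#' @examples
#' digest(dna("AAAAGCTCTTCTATGCCCC"), "SapI")
#' @export
digest <- function(x, enz, id = NULL) {
  x <- as_dna(x)
  enz <- enzyme(enz)
  id <- id %||% x$id %||% "molecule"
  s <- x$residues
  len <- nchar(s)
  L <- nchar(enz$recognition)
  ov <- enz$overhang_length
  hits <- scan_top_coords(x, enz)

  # cut coordinates on the top strand: top strand severed at ct, bottom at cb;
  # the 5' protrusion is top-strand [ct, cb)
  ct <- integer(0)
  if (nrow(hits)) {
    ct_top <- hits$top_start[hits$strand == "top"] + L + enz$cut_offset_top
    ct_bot <- hits$top_start[hits$strand == "bottom"] - enz$cut_offset_bottom
    if (x$topology == "circular") {
      ct <- c(ct_top, ct_bot) %% len
    } else {
      keep_top <- ct_top >= 0 & (ct_top + ov) <= len
      keep_bot <- ct_bot >= 0 & (ct_bot + ov) <= len
      if (any(!keep_top) || any(!keep_bot)) {
        rlang::warn(paste0(enz$name,
          " site(s) with cut windows off the end of the linear molecule were skipped."))
      }
      ct <- c(ct_top[keep_top], ct_bot[keep_bot])
    }
  }
  ct <- sort(unique(as.integer(ct)))

  if (length(ct) == 0L) {
    if (x$topology == "circular") {
      frag <- new_fragment(s, NULL, NULL, provenance = list(id = id, start = 0L,
                                                            width = len),
                           uncut = TRUE)
      return(list(frag))
    }
    return(list(new_fragment(s, blunt_end("top"), blunt_end("bottom"),
                             provenance = list(id = id, start = 0L, width = len))))
  }

  prot_at <- function(pos) wrap_sub(s, pos, ov, len)

  if (x$topology == "circular") {
    k <- length(ct)
    nxt <- c(ct[-1], ct[1])
    frags <- vector("list", k)
    for (i in seq_len(k)) {
      width <- (nxt[i] - ct[i]) %% len
      if (width == 0L) width <- len
      frags[[i]] <- new_fragment(
        wrap_sub(s, ct[i], width, len),
        cohesive_end(prot_at(ct[i]), "top"),
        cohesive_end(revcomp_chr(prot_at(nxt[i])), "bottom"),
        provenance = list(id = id, start = ct[i], width = width)
      )
    }
    return(frags)
  }

  bounds <- c(0L, ct, len)
  k <- length(ct)
  frags <- vector("list", k + 1L)
  for (i in seq_len(k + 1L)) {
    start <- bounds[i]
    end <- bounds[i + 1L]
    left <- if (i == 1L) blunt_end("top") else
      cohesive_end(prot_at(bounds[i]), "top")
    right <- if (i == k + 1L) blunt_end("bottom") else
      cohesive_end(revcomp_chr(prot_at(bounds[i + 1L])), "bottom")
    frags[[i]] <- new_fragment(substr(s, start + 1L, end), left, right,
                               provenance = list(id = id, start = start,
                                                 width = end - start))
  }
  frags
}

#' Can two cohesive ends anneal?
#'
#' TRUE iff the protrusions are exact reverse complements and protrude on
#' complementary strands, the condition for the two single-stranded extensions
#' to base-pair in antiparallel orientation. Blunt-blunt ligation is outside
#' the one-pot model and returns FALSE.
#'
#' @param a,b `stst_end` objects.
#' @return Logical scalar.
#' @examples
#' ends_compatible(cohesive_end("ATG", "top"), cohesive_end("CAT", "bottom"))
#' @export
ends_compatible <- function(a, b) {
  stopifnot(inherits(a, "stst_end"), inherits(b, "stst_end"))
  if (is_blunt(a) || is_blunt(b)) return(FALSE)
  if (nchar(a$protrusion) != nchar(b$protrusion)) return(FALSE)
  a$strand != b$strand && a$protrusion == revcomp_chr(b$protrusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
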