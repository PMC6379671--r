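#' The fusion-site registry
#'
#' All named fusion sites of the assembly framework. Level 1 junctions are
#' 3 bp: alpha = CAG (vector-promoter), beta = CCA (promoter-UTR/RBS, placed
#' at the transcription start site when known), gamma = ATG (the start codon),
#' delta = TAA (the stop codon), epsilon = GGA (terminator-vector). Level 2
#' sites are 4 bp (A GGAG, B AATG, C AGGT, D GCTT, E CGCT, Z TACT), Level 3
#' sites are 4 bp (1 TGCC, 2 ACTA, 3 TTAC, 4 CGAG). F and R are the Level 0
#' storage acceptor sites; their published sequences are supplementary-only,
#' so the package ships documented synthetic stand-ins (F = GCAA, R = TGGC)
#' chosen not to collide with any other site or its reverse complement.
#'
#' @return An immutable tibble with columns `label`, `sequence`, `length`,
#'   `level`, `role` and `synthetic` (TRUE only for the F/R stand-ins).
#' @examples
#' fusion_sites()
#' fusion_site("gamma")  # "ATG"
#' @export
fusion_sites <- function() {
  tibble::tibble(
    label = c("alpha", "beta", "gamma", "delta", "epsilon",
              "A", "B", "C", "D", "E", "Z",
              "1", "2", "3", "4",
              "F", "R"),
    sequence = c("CAG", "CCA", "ATG", "TAA", "GGA",
                 "GGAG", "AATG", "AGGT", "GCTT", "CGCT", "TACT",
                 "TGCC", "ACTA", "TTAC", "CGAG",
                 "GCAA", "TGGC"),
    length = c(rep(3L, 5), rep(4L, 6), rep(4L, 4), rep(4L, 2)),
    level = c(rep(1L, 5), rep(2L, 6), rep(3L, 4), rep(0L, 2)),
    role = c("vector-promoter junction",
             "promoter-UTR/RBS junction (TSS)",
             "UTR/RBS-CDS junction (start codon)",
             "CDS-terminator junction (stop codon)",
             "terminator-vector junction",
             "Level 2 acceptor / first unit", "unit-unit junction",
             "unit-unit junction", "unit-unit junction", "unit-unit junction",
             "Level 2 acceptor / last unit",
             "Level 3 acceptor / first block", "block-block junction",
             "Level 3 acceptor (2-block) / block-block junction",
             "Level 3 acceptor / last block (3-block)",
             "Level 0 storage acceptor, left", "Level 0 storage acceptor, right"),
    synthetic = c(rep(FALSE, 15), TRUE, TRUE)
  )
}

#' @rdname fusion_sites
#' @param label A fusion-site label, e.g. `"gamma"`, `"Z"`, `"2"`.
#' @export
fusion_site <- function(label) {
  tab <- fusion_sites()
  i <- match(as.character(label), tab$label)
  if (is.na(i)) {
    rlang::abort(paste0("Unknown fusion site '", label, "'."))
  }
  tab$sequence[i]
}

site_label_of <- function(sequence) {
  tab <- fusion_sites()
  tab$label[match(sequence, tab$sequence)]
}

#' Audit a set of overhangs for ligation fidelity
#'
#' In a one-pot reaction every junction must anneal only to its cognate
#' partner, so the active overhang set must contain no duplicates, no
#' palindromes (self-cohesive ends), no pairs that are each other's reverse
#' complement, and ideally no near-identical pairs. This audit brute-forces
#' all ordered pairs, including each sequence against every reverse
#' complement, and reports anything at or below the Hamming threshold.
#'
#' @param sites Character vector of overhang sequences (all the same length),
#'   or a tibble with a `sequence` column.
#' @param hamming_warn Report `near_collisions` for pairs at Hamming distance
#'   between 1 and this value (0 disables near-collision reporting; exact
#'   matches are always reported as duplicates/rc collisions).
#' @return An object of class `stst_fidelity`: a list of tibbles
#'   (`duplicates`, `palindromes`, `rc_collisions`, `near_collisions`) plus a
#'   logical `pass` that is TRUE iff the three exact-match findings are empty.
#'   Near-collisions are advisory (e.g. the Level 1 set has alpha = CAG one
#'   mismatch away from the reverse complement of gamma = ATG, a consequence
#'   of using natural start/stop codons as fusion sites) and do not fail the
#'   audit; they flag junction pairs worth watching in reactions that pool
#'   many ends.
#' @examples
#' audit_overhang_set(c("CAG", "CCA", "ATG", "TAA", "GGA"))
#' audit_overhang_set(c("GGAG", "GATC"))  # GATC is palindromic
#' @export
audit_overhang_set <- function(sites, hamming_warn = 0L) {
  if (is.data.frame(sites)) sites <- sites$sequence
  sites <- toupper(as.character(sites))
  if (length(sites) < 1L) rlang::abort("Empty overhang set.")
  if (length(unique(nchar(sites))) != 1L) {
    rlang::abort("Overhang set mixes lengths; a one-pot reaction uses a single enzyme and a single overhang length.",
                 class = "stst_mixed_lengths")
  }
  rc <- revcomp_chr(sites)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }

  dup <- tibble::tibble(sequence = unique(sites[duplicated(sites)]))
  pal <- tibble::tibble(sequence = unique(sites[sites == rc]))

  rc_pairs <- tibble::tibble(a = character(), b = character())
  near <- tibble::tibble(a = character(), b = character(),
                         comparison = character(), distance = integer())
  n <- length(sites)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (sites[i] == rc[j]) {
          rc_pairs <- tibble::add_row(rc_pairs, a = sites[i], b = sites[j])
        }
        if (hamming_warn >= 1L) {
          d_plain <- hamming(sites[i], sites[j])
          if (d_plain >= 1L && d_plain <= hamming_warn) {
            near <- tibble::add_row(near, a = sites[i], b = sites[j],
                                    comparison = "plain", distance = d_plain)
          }
          d_rc <- hamming(sites[i], rc[j])
          if (d_rc >= 1L && d_rc <= hamming_warn) {
            near <- tibble::add_row(near, a = sites[i], b = sites[j],
                                    comparison = "reverse-complement",
                                    distance = d_rc)
          }
        }
      }
    }
  }
  structure(
    list(duplicates = dup, palindromes = pal, rc_collisions = rc_pairs,
         near_collisions = near,
         pass = nrow(dup) + nrow(pal) + nrow(rc_pairs) == 0L),
    class = "stst_fidelity"
  )
}

#' @export
print.stst_fidelity <- function(x, ...) {
  cat(sprintf("<overhang fidelity audit> %s\n",
              if (x$pass) "PASS (no findings)" else "FINDINGS"))
  for (nm in c("duplicates", "palindromes", "rc_collisions", "near_collisions")) {
    if (nrow(x[[nm]])) {
      cat(" ", nm, ":\n", sep = "")
      print(x[[nm]])
    }
  }
  invisible(x)
}
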