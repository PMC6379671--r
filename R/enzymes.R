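#' Type IIS enzymes shipped with the package
#'
#' The three enzymes that drive the assembly hierarchy, encoded as data in a
#' single editable table. Cut offsets follow the standard N.N(top/bottom)
#' notation: SapI = GCTCTTC(1/4) leaves 3 nt 5' overhangs, BsaI = GGTCTC(1/5)
#' and BbsI = GAAGAC(2/6) leave 4 nt 5' overhangs. SapI drives Level 1
#' (expression-unit) assembly, BsaI drives Level 0 storage cloning and
#' Level 2, BbsI drives Level 3.
#'
#' @return A tibble with columns `name`, `recognition`, `cut_offset_top`,
#'   `cut_offset_bottom`, `overhang_length`.
#' @examples
#' type_iis_enzymes()
#' @export
type_iis_enzymes <- function() {
  tibble::tibble(
    name = c("SapI", "BsaI", "BbsI"),
    recognition = c("GCTCTTC", "GGTCTC", "GAAGAC"),
    cut_offset_top = c(1L, 1L, 2L),
    cut_offset_bottom = c(4L, 5L, 6L),
    overhang_length = c(3L, 4L, 4L)
  )
}

#' Look up a type IIS enzyme by name
#'
#' @param name `"SapI"`, `"BsaI"` or `"BbsI"`, or an enzyme object (returned
#'   unchanged).
#' @return A one-row list of class `stst_enzyme`.
#' @examples
#' enzyme("SapI")
#' @export
enzyme <- function(name) {
  if (inherits(name, "stst_enzyme")) return(name)
  tab <- type_iis_enzymes()
  i <- match(name, tab$name)
  if (is.na(i)) {
    rlang::abort(paste0("Unknown enzyme '", name, "'. Shipped enzymes: ",
                        paste(tab$name, collapse = ", ")))
  }
  e <- as.list(tab[i, ])
  # geometry invariants: asymmetric recognition, 5' protrusions of length 3-4
  stopifnot(e$recognition != revcomp_chr(e$recognition),
            e$overhang_length == e$cut_offset_bottom - e$cut_offset_top,
            e$overhang_length %in% c(3L, 4L))
  structure(e, class = "stst_enzyme")
}

#' @export
print.stst_enzyme <- function(x, ...) {
  cat(sprintf("<stst_enzyme> %s %s(%d/%d), %d nt 5' overhang\n",
              x$name, x$recognition, x$cut_offset_top, x$cut_offset_bottom,
              x$overhang_length))
  invisible(x)
}
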