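#' Combinatorial positions of a design
#'
#' One row per slot that can vary: a slot holding a mixture of k parts
#' contributes k options; fixed slots contribute 1; spacer slots (internal
#' operon positions) are not positions at all.
#'
#' @param design An `stst_design`.
#' @return A tibble with columns `unit`, `slot`, `k`.
#' @export
design_positions <- function(design) {
  stopifnot(inherits(design, "stst_design"))
  u <- design$units
  purrr::map_dfr(seq_len(nrow(u)), function(i) {
    purrr::map_dfr(c("promoter", "rbs", "cds", "terminator"), function(sl) {
      val <- u[[sl]][[i]]
      if (is_spacer_slot(val)) return(NULL)
      tibble::tibble(unit = i, slot = sl, k = length(val))
    })
  })
}

#' Size of a combinatorial design space
#'
#' The exact product of option counts over all combinatorial positions.
#' Promoter slots replaced by spacers contribute no position; fixed slots
#' contribute a factor of 1. For example, five monocistronic units with
#' 6-part promoter and RBS mixtures give 6^10 = 60,466,176 variants.
#'
#' @param design An `stst_design`.
#' @return A double (exact for all realistic designs).
#' @seealso [format_library_size()] for the 3-significant-figure scientific
#'   rendering.
#' @export
design_space_size <- function(design) {
  pos <- design_positions(design)
  if (nrow(pos) == 0L) return(1)
  prod(pos$k)
}

#' @rdname design_space_size
#' @param size A library size.
#' @export
format_library_size <- function(size) {
  if (size < 1000) return(format(size, big.mark = ","))
  e <- floor(log10(size))
  m <- signif(size / 10^e, 3)
  sprintf("%s x 10^%d", format(m), e)
}

#' Expected library coverage under finite sampling
#'
#' Standard occupancy expectation for n uniform draws (clones) from a design
#' space of S equally likely variants: the expected number of distinct
#' variants is S (1 - (1 - 1/S)^n), evaluated in floating point via `log1p`
#' for numerical stability at large S. Coverage is many-fold at Level 1
#' (spaces of 6^2 = 36 against thousands of transformants) and typically
#' partial at Levels 2-3; each transformation is treated as the only
#' bottleneck.
#'
#' @param S Design-space size (>= 1).
#' @param n Number of draws (>= 0); vectorized.
#' @return A tibble of class `stst_coverage` with columns `space_size`,
#'   `draws`, `expected_distinct`, `coverage_fraction`.
#' @examples
#' expected_coverage(36, c(10, 100, 1000))
#' @export
expected_coverage <- function(S, n) {
  stopifnot(S >= 1, all(n >= 0))
  expected <- S * (1 - exp(n * log1p(-1 / S)))
  if (S == 1) expected <- ifelse(n > 0, 1, 0)
  out <- tibble::tibble(space_size = S, draws = n,
                        expected_distinct = expected,
                        coverage_fraction = expected / S)
  class(out) <- c("stst_coverage", class(out))
  out
}

#' Sample concrete variants from a combinatorial design
#'
#' Draws n variants of the design, choosing uniformly and independently at
#' each combinatorial position (the equimolar-mixture premise; optional
#' per-option weights model biased mixtures), with replacement across
#' variants. Deterministic per seed; every returned design is concrete and
#' can be planned and simulated directly.
#'
#' @param design An `stst_design` with mixture slots.
#' @param n Number of variants to draw (>= 1).
#' @param seed Integer seed.
#' @param weights Optional named list mapping `"unit<i>:<slot>"` to a weight
#'   vector over that slot's options.
#' @return A list of n concrete `stst_design` objects.
#' @export
sample_variants <- function(design, n, seed = 1L, weights = NULL) {
  stopifnot(inherits(design, "stst_design"), n >= 1)
  u <- design$units
  slots <- c("promoter", "rbs", "cds", "terminator")
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(v) {
      u2 <- u
      for (i in seq_len(nrow(u))) {
        for (sl in slots) {
          val <- u[[sl]][[i]]
          if (is_spacer_slot(val) || length(val) == 1L) next
          w <- weights[[paste0("unit", i, ":", sl)]]
          pick <- if (is.null(w)) sample(val, 1L) else
            sample(val, 1L, prob = w)
          u2[[sl]][[i]] <- pick
        }
      }
      out <- design
      out$units <- u2
      out
    })
  })
}

#' Summarize a design's library arithmetic
#'
#' @param design An `stst_design`.
#' @return A one-row tibble: number of units, combinatorial positions, exact
#'   size and scientific rendering.
#' @export
library_size_summary <- function(design) {
  S <- design_space_size(design)
  pos <- design_positions(design)
  tibble::tibble(
    n_units = nrow(design$units),
    n_positions = sum(pos$k > 1),
    size = S,
    size_scientific = format_library_size(S)
  )
}
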