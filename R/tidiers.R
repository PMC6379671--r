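#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assembly plan into its reaction table
#'
#' @param x An `stst_plan`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: `reaction_id`, `level`,
#'   `vector`, `n_inserts`, `insert_summary`.
#' @method tidy stst_plan
#' @export
tidy.stst_plan <- function(x, ...) {
  r <- x$reactions
  tibble::tibble(
    reaction_id = r$reaction_id,
    level = r$level,
    vector = r$vector,
    n_inserts = vapply(r$inserts, length, integer(1)),
    insert_summary = vapply(r$inserts, function(ins) {
      paste(vapply(ins, function(slot) {
        if (isTRUE(slot$spacer)) paste0(slot$slot, ":spacer")
        else if (identical(slot$slot, "product")) slot$source
        else paste0(slot$slot, ":",
                    if (length(slot$source) > 1)
                      paste0("mix(", length(slot$source), ")")
                    else slot$source)
      }, character(1)), collapse = " + ")
    }, character(1))
  )
}

#' @rdname tidy.stst_plan
#' @method glance stst_plan
#' @export
glance.stst_plan <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$design$units),
    n_groups = length(x$groups),
    n_reactions = nrow(x$reactions),
    destination_level = max(x$reactions$level),
    destination_vector = x$reactions$vector[x$reactions$reaction_id == x$final],
    n_level0_parts = x$n_level0_parts,
    design_space = design_space_size(x$design)
  )
}

#' Tidy a fidelity audit into a long findings table
#'
#' @param x An `stst_fidelity`.
#' @param ... Unused.
#' @method tidy stst_fidelity
#' @export
tidy.stst_fidelity <- function(x, ...) {
  out <- dplyr::bind_rows(
    if (nrow(x$duplicates))
      tibble::tibble(finding = "duplicate", a = x$duplicates$sequence,
                     b = x$duplicates$sequence, distance = 0L),
    if (nrow(x$palindromes))
      tibble::tibble(finding = "palindrome", a = x$palindromes$sequence,
                     b = revcomp_chr(x$palindromes$sequence), distance = 0L),
    if (nrow(x$rc_collisions))
      tibble::tibble(finding = "rc_collision", a = x$rc_collisions$a,
                     b = x$rc_collisions$b, distance = 0L),
    if (nrow(x$near_collisions))
      tibble::tibble(finding = paste0("near_", x$near_collisions$comparison),
                     a = x$near_collisions$a, b = x$near_collisions$b,
                     distance = x$near_collisions$distance)
  )
  if (nrow(out) == 0L) {
    out <- tibble::tibble(finding = character(), a = character(),
                          b = character(), distance = integer())
  }
  out
}

#' Plot an assembly plan as a level diagram
#'
#' One tile per reaction, arranged by level, labelled with the vector used.
#'
#' @param object An `stst_plan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stst_plan
#' @export
autoplot.stst_plan <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::mutate(d, x = stats::ave(seq_len(nrow(d)), d$level,
                                       FUN = seq_along))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$level)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$level)),
                       colour = "grey20", width = 0.9, height = 0.8,
                       show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$reaction_id, "\n", .data$vector)), size = 3) +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = paste("Level", 1:3)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Hierarchical assembly plan") +
    ggplot2::theme_minimal()
}

#' Plot expected coverage against the number of clones screened
#'
#' @param object An `stst_coverage` tibble from [expected_coverage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stst_coverage
#' @export
autoplot.stst_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$draws,
                                       y = .data$coverage_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "transformant clones (draws)",
                  y = "expected fraction of design space",
                  title = sprintf("Coverage of a design space of %s variants",
                                  format_library_size(object$space_size[1]))) +
    ggplot2::theme_minimal()
}

#' Plot the classification spectrum of enumerated products
#'
#' @param products Output of [one_pot_products()].
#' @return A ggplot object.
#' @export
plot_products <- function(products) {
  d <- dplyr::count(products, .data$classification, .data$stable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$classification, y = .data$n,
                                  fill = .data$stable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "circular products",
                  title = "One-pot product spectrum") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
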