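sense_codons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_clean_raw <- function(len, kind, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    raw <- if (kind == "cds") {
      n_codons <- len %/% 3L - 2L
      paste0("ATG", paste(sample(sense_codons(), n_codons, replace = TRUE),
                          collapse = ""), "TAA")
    } else {
      random_acgt(len)
    }
    if (nrow(forbidden_site_hits(raw)) > 0L) next
    d <- tryCatch(domesticate(raw, kind, "probe"), error = function(e) NULL)
    if (!is.null(d)) return(raw)
  }
  rlang::abort("Could not draw a clean fixture sequence; try another seed.")
}

#' Generate the synthetic fixture set
#'
#' Builds a complete, self-contained stand-in for the experimental reagent
#' sets, deterministic per seed: six promoters, six RBSs, four terminators,
#' eight carotenoid-pathway CDS analogues (dxs, crtE, crtB, crtI, idi, lcyB,
#' crtZ, crtW; random sense-codon strings of 300-1500 nt beginning ATG and
#' ending TAA) plus an eyfp reporter analogue, 16 spacer linkers, and concrete
#' sequences for all 15 core vectors. Every part is validation-clean, free of
#' SapI/BsaI/BbsI sites, domesticated and stored in the Level 0 vector by
#' simulated one-pot cloning, so the whole toolkit is testable without any
#' downloaded sequence.
#'
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return An object of class `stst_fixtures`: named lists `parts`
#'   (`stst_part`), `inserts` (domesticated linear molecules), `plasmids`
#'   (Level 0 storage plasmids), `primer_tails`, plus `linkers`, `vectors`,
#'   `vector_table` and `seed`.
#' @examples
#' \donttest{
#' fx <- generate_fixtures(seed = 42)
#' names(fx$plasmids)
#' }
#' @export
generate_fixtures <- function(seed = 42L) {
  sub <- withr::with_seed(seed, sample.int(2^31 - 2L, 4L))

  specs <- withr::with_seed(sub[1], {
    cds_names <- c("dxs", "crtE", "crtB", "crtI", "idi", "lcyB", "crtZ",
                   "crtW", "eyfp")
    tibble::tibble(
      name = c(paste0("P", 1:6), paste0("R", 1:6), paste0("T", 1:4),
               cds_names),
      kind = c(rep("promoter", 6), rep("utr_rbs", 6), rep("terminator", 4),
               rep("cds", 9)),
      len = c(rep(35L, 6), rep(25L, 6), rep(60L, 4),
              3L * sample(100:500, 9, replace = TRUE))
    )
  })

  raws <- withr::with_seed(sub[2], {
    purrr::map(seq_len(nrow(specs)), function(i) {
      random_clean_raw(specs$len[i], specs$kind[i])
    })
  })

  vectors <- purrr::map(core_vectors()$name, synthesize_vector, seed = sub[3])
  names(vectors) <- core_vectors()$name
  linkers <- make_spacer_linkers(n = 16L, seed = sub[4])

  doms <- purrr::map(seq_len(nrow(specs)), function(i) {
    domesticate(raws[[i]], specs$kind[i], specs$name[i])
  })
  names(doms) <- specs$name
  parts <- purrr::map(doms, "part")
  inserts <- purrr::map(doms, "insert")
  tails <- purrr::map(doms, "primer_tails")
  plasmids <- purrr::imap(inserts, function(ins, nm) {
    simulate_storage_cloning(ins, vectors$pStA0, id = paste0("pStA0_", nm))
  })

  structure(list(seed = seed, parts = parts, inserts = inserts,
                 plasmids = plasmids, primer_tails = tails,
                 linkers = linkers, vectors = vectors,
                 vector_table = core_vectors()),
            class = "stst_fixtures")
}

#' @export
print.stst_fixtures <- function(x, ...) {
  kinds <- table(vapply(x$parts, function(p) p$kind, character(1)))
  cat(sprintf("<stst_fixtures> seed %d: %s; %d spacer cores; %d vectors\n",
              x$seed,
              paste(names(kinds), as.integer(kinds), collapse = ", "),
              length(unique(x$linkers$core)), length(x$vectors)))
  invisible(x)
}

#' The five carotenoid library designs (plus a single-unit control)
#'
#' The shipped library configurations, expressed against the fixture part
#' names: a five-unit monocistronic beta-carotene library (6^10 variants, one
#' Level 2 destination), the same five CDSs as a single operon (6^6), a
#' three-unit-operon + two-monocistronic hybrid (6^8, Level 2), a
#' four-unit-operon + one-monocistronic hybrid routed to Level 3 (6^7), the
#' eight-CDS astaxanthin hybrid (four-unit operon + monocistronic unit +
#' three-unit operon, 6^11, Level 3), and a single expression unit with
#' promoter and RBS mixtures (6^2 = 36, the per-unit Level 1 design space).
#'
#' @return A named list of `stst_design` objects: `mono5`, `operon5`,
#'   `hybrid_3op_2mono`, `hybrid_4op_1mono`, `asta_hybrid`, `single_unit`.
#' @export
carotenoid_designs <- function() {
  P <- paste0("P", 1:6)
  R <- paste0("R", 1:6)
  bcar <- c("dxs", "crtE", "crtB", "crtI", "lcyB")

  mono5 <- design_spec(purrr::map(seq_along(bcar), function(i) {
    unit_spec(bcar[i], cds = bcar[i], promoter = P, rbs = R,
              terminator = c("T1", "T2", "T3", "T4", "T1")[i])
  }))

  operon5 <- design_spec(
    c(list(unit_spec(bcar[1], cds = bcar[1], promoter = P, rbs = R)),
      purrr::map(2:4, function(i) unit_spec(bcar[i], cds = bcar[i], rbs = R)),
      list(unit_spec(bcar[5], cds = bcar[5], rbs = R, terminator = "T1"))),
    operon = rep(1L, 5))

  hybrid_3op_2mono <- design_spec(
    list(unit_spec("dxs", cds = "dxs", promoter = P, rbs = R),
         unit_spec("crtE", cds = "crtE", rbs = R),
         unit_spec("crtB", cds = "crtB", rbs = R, terminator = "T1"),
         unit_spec("crtI", cds = "crtI", promoter = P, rbs = R,
                   terminator = "T2"),
         unit_spec("lcyB", cds = "lcyB", promoter = P, rbs = R,
                   terminator = "T3")),
    operon = c(1L, 1L, 1L, NA, NA),
    destination_vector = "pStA234")

  hybrid_4op_1mono <- design_spec(
    list(unit_spec("dxs", cds = "dxs", promoter = P, rbs = R),
         unit_spec("crtE", cds = "crtE", rbs = R),
         unit_spec("crtB", cds = "crtB", rbs = R),
         unit_spec("crtI", cds = "crtI", rbs = R, terminator = "T1"),
         unit_spec("lcyB", cds = "lcyB", promoter = P, rbs = R,
                   terminator = "T2")),
    operon = c(1L, 1L, 1L, 1L, NA),
    destination_level = 3)

  asta_hybrid <- design_spec(
    list(unit_spec("dxs", cds = "dxs", promoter = P, rbs = R),
         unit_spec("crtE", cds = "crtE", rbs = R),
         unit_spec("crtB", cds = "crtB", rbs = R),
         unit_spec("crtI", cds = "crtI", rbs = R, terminator = "T1"),
         unit_spec("idi", cds = "idi", promoter = P, rbs = R,
                   terminator = "T2"),
         unit_spec("lcyB", cds = "lcyB", promoter = P, rbs = R),
         unit_spec("crtZ", cds = "crtZ", rbs = R),
         unit_spec("crtW", cds = "crtW", rbs = R, terminator = "T3")),
    operon = c(1L, 1L, 1L, 1L, NA, 2L, 2L, 2L))

  single_unit <- design_spec(
    list(unit_spec("eyfp", cds = "eyfp", promoter = P, rbs = R,
                   terminator = "T1")),
    destination_level = 1)

  list(mono5 = mono5, operon5 = operon5,
       hybrid_3op_2mono = hybrid_3op_2mono,
       hybrid_4op_1mono = hybrid_4op_1mono,
       asta_hybrid = asta_hybrid, single_unit = single_unit)
}
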