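part_kinds <- c("promoter", "utr_rbs", "cds", "terminator",
                "spacer_promoter_side", "spacer_terminator_side",
                "expression_unit", "multiunit_block")

# fixed kind -> flank mapping for basic (Level 0) parts
kind_flanks <- function(kind) {
  switch(kind,
    promoter = c("alpha", "beta"),
    utr_rbs = c("beta", "gamma"),
    cds = c("gamma", "delta"),
    terminator = c("delta", "epsilon"),
    spacer_promoter_side = c("alpha", "beta"),
    spacer_terminator_side = c("delta", "epsilon"),
    rlang::abort(paste0("No fixed flank mapping for kind '", kind,
                        "'; supply `flanks` explicitly."))
  )
}

#' Typed, validated genetic parts
#'
#' A part record couples a core sequence with its type and flanking fusion
#' sites. The core *includes* both fusion-site sequences: a promoter core runs
#' alpha(CAG)...beta(CCA), a UTR/RBS core beta...gamma, a CDS core is the
#' coding sequence itself (its start codon is the gamma site and its stop
#' codon the delta site), and a terminator core runs delta...epsilon. Level
#' 1/2 products used as parts at the next level (`expression_unit`,
#' `multiunit_block`) take explicit flank labels from the A-Z / 1-4 sets.
#'
#' @param name Part identifier.
#' @param kind One of `r paste0('"', part_kinds, '"', collapse = ", ")`.
#' @param core Core sequence (string or `stst_dna`), including both flanks.
#' @param flanks Length-2 character vector of fusion-site labels; defaults to
#'   the fixed mapping for basic kinds.
#' @param level Assembly level the part enters (0 for basic parts).
#' @return An object of class `stst_part`.
#' @examples
#' part_record("eyfp", "cds", paste0("ATG", strrep("GCT", 8), "TAA"))
#' @export
part_record <- function(name, kind, core, flanks = NULL, level = 0L) {
  kind <- match.arg(kind, part_kinds)
  if (is.null(flanks)) flanks <- kind_flanks(kind)
  stopifnot(length(flanks) == 2L)
  core <- if (inherits(core, "stst_dna")) core$residues else toupper(core)
  structure(list(name = name, kind = kind, core = core,
                 flanks = as.character(flanks), level = as.integer(level)),
            class = "stst_part")
}

#' @export
print.stst_part <- function(x, ...) {
  cat(sprintf("<stst_part> %s (%s, level %d), %d bp core, flanks %s/%s\n",
              x$name, x$kind, x$level, nchar(x$core),
              x$flanks[1], x$flanks[2]))
  invisible(x)
}

# every recognition occurrence (either strand) of the three assembly enzymes
forbidden_site_hits <- function(seq_chr) {
  purrr::map_dfr(c("SapI", "BsaI", "BbsI"), function(nm) {
    hits <- scan_sites(dna(seq_chr), nm)
    if (nrow(hits)) tibble::tibble(enzyme = nm, position = hits$position,
                                   strand = hits$strand)
    else tibble::tibble(enzyme = character(), position = integer(),
                        strand = character())
  })
}

#' Validate a part record
#'
#' Checks the part invariants and returns violations as data, never as
#' exceptions: wrong flanking fusion sites (`WRONG_FLANK`, or
#' `BAD_START_CODON`/`BAD_STOP_CODON` for CDS parts, whose flanks are their
#' own start and stop codons), internal recognition sites of any assembly
#' enzyme on either strand (`INTERNAL_SITE:<enzyme>`, these are reserved for
#' assembly), and — for CDS parts only — a reading-frame length check
#' (`CDS_FRAME`, emitted as a warning-severity finding, not an error).
#'
#' @param part An `stst_part`.
#' @return A tibble with columns `code`, `severity` (`"error"`/`"warning"`),
#'   `detail`, `position` (0-based, NA where not positional), in deterministic
#'   order; zero rows iff the part is clean.
#' @export
validate_part <- function(part) {
  stopifnot(inherits(part, "stst_part"))
  v <- tibble::tibble(code = character(), severity = character(),
                      detail = character(), position = integer())
  add <- function(code, severity, detail, position = NA_integer_) {
    tibble::add_row(v, code = code, severity = severity, detail = detail,
                    position = as.integer(position))
  }
  core <- part$core
  left <- fusion_site(part$flanks[1])
  right <- fusion_site(part$flanks[2])

  if (part$kind == "cds") {
    if (substr(core, 1, 3) != "ATG") {
      v <- add("BAD_START_CODON", "error",
               paste0("CDS must begin with the start codon ATG (gamma site); found '",
                      substr(core, 1, 3), "'"), 0L)
    }
    if (substr(core, nchar(core) - 2, nchar(core)) != "TAA") {
      v <- add("BAD_STOP_CODON", "error",
               paste0("CDS must end with the stop codon TAA (delta site); found '",
                      substr(core, nchar(core) - 2, nchar(core)), "'"),
               nchar(core) - 3L)
    }
  } else {
    if (substr(core, 1, nchar(left)) != left) {
      v <- add("WRONG_FLANK", "error",
               paste0("core must begin with ", part$flanks[1], " (", left, ")"), 0L)
    }
    if (substr(core, nchar(core) - nchar(right) + 1, nchar(core)) != right) {
      v <- add("WRONG_FLANK", "error",
               paste0("core must end with ", part$flanks[2], " (", right, ")"),
               nchar(core) - nchar(right))
    }
  }

  hits <- forbidden_site_hits(core)
  if (nrow(hits)) {
    hits <- hits[order(match(hits$enzyme, c("SapI", "BsaI", "BbsI")),
                       hits$position), ]
    for (i in seq_len(nrow(hits))) {
      v <- add(paste0("INTERNAL_SITE:", hits$enzyme[i]), "error",
               paste0(hits$enzyme[i], " recognition site on ", hits$strand[i],
                      " strand"), hits$position[i])
    }
  }

  if (part$kind == "cds" && nchar(core) %% 3L != 0L) {
    v <- add("CDS_FRAME", "warning",
             paste0("CDS length ", nchar(core), " is not a multiple of 3"))
  }
  v
}

# ---- domestication -------------------------------------------------------

# Storage prefix/suffix grammar (synthetic stand-in defaults, see fusion_sites
# docs): outside, inward-facing BsaI sites with F/R storage donor sites;
# inside, inward-facing SapI sites each separated from the part's fusion site
# by a 1 nt spacer (A).
domestication_flanks <- function(kind) {
  flanks <- kind_flanks(kind)
  left_site <- if (kind == "cds") "" else fusion_site(flanks[1])
  right_site <- if (kind == "cds") "" else fusion_site(flanks[2])
  list(
    prefix = paste0("GGTCTC", "A", fusion_site("F"), "GCTCTTC", "A", left_site),
    suffix = paste0(right_site, "A", "GAAGAGC", fusion_site("R"), "A", "GAGACC"),
    flanks = flanks
  )
}

#' Domesticate a raw sequence into the Level 0 storage format
#'
#' Wraps a raw part sequence in the standard prefix/suffix so that (i) the
#' inward-facing BsaI sites with F/R storage donor fusion sites allow one-pot
#' cloning into the Level 0 vector, and (ii) the inward-facing SapI sites,
#' each separated from the fusion site by a 1 bp spacer, later excise the part
#' with the cohesive ends of its type. For CDS parts the raw sequence must
#' already begin ATG and end TAA (those codons *are* the fusion sites); for
#' the other kinds the type's fusion-site sequences are added around the raw
#' sequence. The prefix and the reverse complement of the suffix double as PCR
#' primer tails.
#'
#' @param raw Raw part sequence (string or `stst_dna`), free of SapI, BsaI and
#'   BbsI sites on both strands.
#' @param kind `"promoter"`, `"utr_rbs"`, `"cds"` or `"terminator"`.
#' @param name Part name recorded on the resulting part record.
#' @return A list with `insert` (linear `stst_dna` ready for storage cloning),
#'   `part` (the `stst_part` the insert encodes) and `primer_tails`
#'   (named character vector `forward`/`reverse`).
#' @examples
#' d <- domesticate(paste0("ATG", strrep("GAA", 30), "TAA"), "cds", "demo")
#' nchar(d$insert$residues)
#' @export
domesticate <- function(raw, kind, name = "part") {
  kind <- match.arg(kind, c("promoter", "utr_rbs", "cds", "terminator"))
  raw <- if (inherits(raw, "stst_dna")) raw$residues else toupper(raw)

  hits <- forbidden_site_hits(raw)
  if (nrow(hits)) {
    rlang::abort(
      paste0("Raw sequence contains forbidden recognition site(s): ",
             paste(sprintf("%s@%d(%s)", hits$enzyme, hits$position,
                           hits$strand), collapse = ", "),
             ". These sites are reserved for assembly and must be removed ",
             "(e.g. by synonymous recoding) before domestication."),
      class = "stst_domestication_error", hits = hits
    )
  }
  if (kind == "cds") {
    if (substr(raw, 1, 3) != "ATG" ||
        substr(raw, nchar(raw) - 2, nchar(raw)) != "TAA") {
      rlang::abort("A CDS must begin with ATG and end with TAA; its start and stop codons are its fusion sites.",
                   class = "stst_domestication_error")
    }
  }

  g <- domestication_flanks(kind)
  insert_chr <- paste0(g$prefix, raw, g$suffix)
  core <- if (kind == "cds") raw else
    paste0(fusion_site(g$flanks[1]), raw, fusion_site(g$flanks[2]))

  # junction safety: the assembled insert must carry exactly the intended
  # sites (2 SapI, 2 BsaI, 0 BbsI) and nothing created across junctions
  counts <- table(factor(forbidden_site_hits(insert_chr)$enzyme,
                         levels = c("SapI", "BsaI", "BbsI")))
  if (!(counts[["SapI"]] == 2L && counts[["BsaI"]] == 2L &&
        counts[["BbsI"]] == 0L)) {
    rlang::abort(paste0(
      "Domestication created an unintended recognition site across a ",
      "prefix/suffix junction (found SapI=", counts[["SapI"]], ", BsaI=",
      counts[["BsaI"]], ", BbsI=", counts[["BbsI"]],
      "); adjust the raw sequence ends."),
      class = "stst_domestication_error")
  }

  list(
    insert = dna(insert_chr, topology = "linear", id = paste0(name, "_insert")),
    part = part_record(name, kind, core),
    primer_tails = c(forward = g$prefix, reverse = revcomp_chr(g$suffix))
  )
}

# ---- spacer linkers ------------------------------------------------------

#' Generate spacer linkers for operon configurations
#'
#' Operons are built by substituting short neutral spacers for internal
#' promoters and terminators at Level 1. Each 12 bp spacer core yields two
#' annealed-oligo linkers: a promoter-side linker with alpha/beta cohesive
#' ends and a terminator-side linker with delta/epsilon cohesive ends. Cores
#' are drawn deterministically from `seed` under the constraints: no SapI,
#' BsaI or BbsI site on either strand, including across the junctions with
#' the flanking fusion sites; no ATG on the top strand between a
#' promoter-side linker's alpha and beta sites (spurious start codons ahead
#' of the RBS are avoided); and pairwise Hamming distance >= 4 between cores
#' (the package's operationalization of orthogonality).
#'
#' @param n Number of spacer cores (default 16, the shipped set size).
#' @param seed Integer seed; identical `(n, seed)` give identical output.
#' @param max_tries Bounded rejection-sampling budget per accepted core.
#' @return A tibble with one row per linker (2n rows): `spacer`, `core`,
#'   `side` (`"promoter_side"`/`"terminator_side"`), `oligo_top`,
#'   `oligo_bottom`.
#' @examples
#' make_spacer_linkers(n = 2, seed = 1)
#' @export
make_spacer_linkers <- function(n = 16L, seed = 1L, max_tries = 5000L) {
  if (n < 1L) rlang::abort("`n` must be >= 1.")
  alpha <- fusion_site("alpha"); beta <- fusion_site("beta")
  delta <- fusion_site("delta"); epsilon <- fusion_site("epsilon")

  ok_core <- function(core, accepted) {
    ctx_p <- paste0(alpha, core, beta)
    ctx_t <- paste0(delta, core, epsilon)
    if (nrow(forbidden_site_hits(ctx_p)) || nrow(forbidden_site_hits(ctx_t))) {
      return(FALSE)
    }
    if (grepl("ATG", ctx_p, fixed = TRUE)) return(FALSE)
    if (length(accepted)) {
      d <- vapply(accepted, function(a) {
        sum(strsplit(a, "")[[1]] != strsplit(core, "")[[1]])
      }, integer(1))
      if (any(d < 4L)) return(FALSE)
    }
    TRUE
  }

  cores <- withr::with_seed(seed, {
    acc <- character(0)
    tries <- 0L
    while (length(acc) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        rlang::abort(paste0("Could not satisfy spacer constraints after ",
                            max_tries, " draws; try a different seed."),
                     class = "stst_spacer_error")
      }
      cand <- paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
                    collapse = "")
      if (ok_core(cand, acc)) acc <- c(acc, cand)
    }
    acc
  })

  purrr::map_dfr(seq_along(cores), function(i) {
    core_i <- cores[i]
    tops <- c(paste0(alpha, core_i), paste0(delta, core_i))
    bottoms <- c(revcomp_chr(paste0(core_i, beta)),
                 revcomp_chr(paste0(core_i, epsilon)))
    tibble::tibble(
      spacer = sprintf("spacer%02d", i),
      core = core_i,
      side = c("promoter_side", "terminator_side"),
      oligo_top = tops,
      oligo_bottom = bottoms
    )
  })
}

#' Realize a spacer linker as a cohesive-ended fragment
#'
#' The annealed-oligo duplex enters a Level 1 reaction directly, without
#' digestion: its protrusions already are the fusion-site sequences.
#'
#' @param core 12 bp spacer core sequence.
#' @param side `"promoter_side"` (alpha/beta ends) or `"terminator_side"`
#'   (delta/epsilon ends).
#' @param name Identifier used in provenance.
#' @return An `stst_fragment`.
#' @export
spacer_fragment <- function(core, side = c("promoter_side", "terminator_side"),
                            name = "spacer") {
  side <- match.arg(side)
  left_lab <- if (side == "promoter_side") "alpha" else "delta"
  right_lab <- if (side == "promoter_side") "beta" else "epsilon"
  left <- fusion_site(left_lab)
  right <- fusion_site(right_lab)
  new_fragment(
    paste0(left, toupper(core)),
    cohesive_end(left, "top", left_lab),
    cohesive_end(revcomp_chr(right), "bottom", right_lab),
    provenance = list(id = paste0(name, ":", side), start = 0L,
                      width = nchar(core) + nchar(left))
  )
}
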