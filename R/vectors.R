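#' The fifteen core vectors
#'
#' The registry of core storage and assembly vectors as abstract templates:
#' one Level 0 storage vector (pStA0, BsaI acceptor with F/R storage sites,
#' high-copy pMB1 replicon for convenient part preparation), nine Level 1
#' vectors (SapI acceptors alpha/epsilon; BsaI donor pairs AB, BC, CD, DE and
#' the Z-vector series AZ, BZ, CZ, DZ, EZ), three Level 2 vectors (BsaI
#' acceptors A/Z; BbsI donor pairs 1-2, 2-3, 3-4) and two Level 3 destination
#' vectors (BbsI acceptors 1/3 and 1/4; no donor sites). Levels 1-3 use the
#' low-copy p15A replicon to limit the burden of assembled expression units,
#' and consecutive levels cycle antibiotic markers (AmpR, TetR, KanR, CamR)
#' so carried-over plasmid from the previous level cannot be selected.
#'
#' Vector names encode the level and the donor pair (Level 3: the acceptor
#' pair). The Level 1 names follow that scheme; the per-vector marker mapping
#' is a documented package default satisfying the marker-cycling constraint.
#'
#' @return A tibble with one row per vector: `name`, `level`,
#'   `acceptor_enzyme`, `acceptor_left`, `acceptor_right`, `donor_enzyme`,
#'   `donor_left`, `donor_right`, `marker`, `replicon`.
#' @examples
#' core_vectors()
#' @export
core_vectors <- function() {
  l1_donors <- c("AB", "BC", "CD", "DE", "AZ", "BZ", "CZ", "DZ", "EZ")
  l1 <- tibble::tibble(
    name = paste0("pStA1", l1_donors),
    level = 1L,
    acceptor_enzyme = "SapI", acceptor_left = "alpha",
    acceptor_right = "epsilon",
    donor_enzyme = "BsaI",
    donor_left = substr(l1_donors, 1, 1),
    donor_right = substr(l1_donors, 2, 2),
    marker = "TetR", replicon = "p15A_low"
  )
  l2 <- tibble::tibble(
    name = c("pStA212", "pStA223", "pStA234"),
    level = 2L,
    acceptor_enzyme = "BsaI", acceptor_left = "A", acceptor_right = "Z",
    donor_enzyme = "BbsI",
    donor_left = c("1", "2", "3"), donor_right = c("2", "3", "4"),
    marker = "KanR", replicon = "p15A_low"
  )
  l3 <- tibble::tibble(
    name = c("pStA313", "pStA314"),
    level = 3L,
    acceptor_enzyme = "BbsI", acceptor_left = "1",
    acceptor_right = c("3", "4"),
    donor_enzyme = NA_character_, donor_left = NA_character_,
    donor_right = NA_character_,
    marker = "CamR", replicon = "p15A_low"
  )
  l0 <- tibble::tibble(
    name = "pStA0", level = 0L,
    acceptor_enzyme = "BsaI", acceptor_left = "F", acceptor_right = "R",
    donor_enzyme = NA_character_, donor_left = NA_character_,
    donor_right = NA_character_,
    marker = "AmpR", replicon = "pMB1_high"
  )
  dplyr::bind_rows(l0, l1, l2, l3)
}

vector_spec <- function(name) {
  tab <- core_vectors()
  i <- match(name, tab$name)
  if (is.na(i)) {
    rlang::abort(paste0("Unknown core vector '", name, "'."))
  }
  as.list(tab[i, ])
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthesize a concrete vector sequence
#'
#' Realizes a core vector template as a concrete circular molecule: the
#' assembly cassette (a lacZalpha stuffer flanked by the acceptor fusion
#' sites, with outward-facing recognition sites inside the stuffer so that
#' assembly removes them; donor fusion sites with inward-facing recognition
#' sites outside the acceptors; the whole cassette insulated by T0 and T1
#' terminator placeholders) plus randomized neutral marker and replicon
#' placeholder segments. The sequence is a synthetic stand-in for the
#' deposited vectors — functionally faithful cassette grammar, placeholder
#' everything else — and is deterministic per `(name, seed)`. The result is
#' guaranteed free of SapI/BsaI/BbsI recognition outside the cassette.
#'
#' @param name Core vector name (see [core_vectors()]).
#' @param seed Integer seed.
#' @return A circular, fully feature-annotated `stst_dna` whose `id` is the
#'   vector name.
#' @examples
#' v <- synthesize_vector("pStA1AZ", seed = 7)
#' nrow(scan_sites(v, "SapI"))  # the 2 outward acceptor sites
#' @export
synthesize_vector <- function(name, seed = 1L) {
  spec <- vector_spec(name)
  acc <- enzyme(spec$acceptor_enzyme)
  don <- if (!is.na(spec$donor_enzyme)) enzyme(spec$donor_enzyme) else NULL
  acc_l <- fusion_site(spec$acceptor_left)
  acc_r <- fusion_site(spec$acceptor_right)
  pad_a <- function(e) strrep("A", e$cut_offset_top)

  build <- function() {
    segs <- list()
    feat <- list()
    push <- function(seq, label = NULL, strand = "+") {
      start <- sum(vapply(segs, nchar, integer(1)))
      segs[[length(segs) + 1L]] <<- seq
      if (!is.null(label)) {
        feat[[length(feat) + 1L]] <<- tibble::tibble(
          label = label, start = start, end = start + nchar(seq),
          strand = strand)
      }
    }

    push(random_acgt(sample(800:1100, 1)), paste0("marker_", spec$marker))
    push(random_acgt(20))
    push(random_acgt(sample(600:900, 1)), paste0("replicon_", spec$replicon))
    push(random_acgt(20))
    push(random_acgt(100), "terminator_T0")
    push(random_acgt(10))
    if (!is.null(don)) {
      push(don$recognition, paste0("recognition_", don$name))
      push(pad_a(don))
      push(fusion_site(spec$donor_left), "donor_left_site")
      push(random_acgt(10))
    }
    push(acc_l, "acceptor_left_site")
    push(pad_a(acc))
    push(revcomp_chr(acc$recognition), paste0("recognition_", acc$name),
         strand = "-")
    push(random_acgt(300), "stuffer_lacZalpha")
    push(acc$recognition, paste0("recognition_", acc$name))
    push(pad_a(acc))
    push(acc_r, "acceptor_right_site")
    if (!is.null(don)) {
      push(random_acgt(10))
      push(fusion_site(spec$donor_right), "donor_right_site")
      push(pad_a(don))
      push(revcomp_chr(don$recognition), paste0("recognition_", don$name),
           strand = "-")
    }
    push(random_acgt(10))
    push(random_acgt(100), "terminator_T1")
    push(random_acgt(20))
    dna(paste0(unlist(segs), collapse = ""), topology = "circular",
        features = dplyr::bind_rows(feat), id = name)
  }

  expected <- c(SapI = 0L, BsaI = 0L, BbsI = 0L)
  expected[acc$name] <- 2L
  if (!is.null(don)) expected[don$name] <- 2L

  withr::with_seed(seed, {
    for (attempt in 1:50) {
      v <- build()
      counts <- table(factor(forbidden_site_hits(v$residues)$enzyme,
                             levels = names(expected)))
      if (all(as.integer(counts) == as.integer(expected[names(counts)]))) {
        return(v)
      }
    }
    rlang::abort("Vector synthesis failed to satisfy site constraints after 50 attempts; try another seed.")
  })
}

#' Validate a user-supplied destination backbone
#'
#' Checks that a would-be Level 2 or Level 3 destination vector carries a
#' correct assembly cassette: exactly one acceptor-site pair with
#' outward-facing recognition sites (so the stuffer, not the backbone,
#' carries them), the right acceptor fusion sites (A/Z at Level 2; 1/3 or 1/4
#' at Level 3), and no stray SapI/BsaI/BbsI sites elsewhere. Violations are
#' returned as data.
#'
#' @param backbone Circular `stst_dna`.
#' @param level 2 or 3.
#' @return A tibble with columns `code`, `detail`, `position`; zero rows iff
#'   the backbone validates.
#' @export
validate_destination <- function(backbone, level) {
  stopifnot(level %in% c(2L, 3L))
  backbone <- as_dna(backbone, topology = "circular")
  acc <- enzyme(if (level == 2L) "BsaI" else "BbsI")
  expected_acceptors <- if (level == 2L) {
    list(c("GGAG", "TACT"))
  } else {
    list(c("TGCC", "TTAC"), c("TGCC", "CGAG"))
  }

  v <- tibble::tibble(code = character(), detail = character(),
                      position = integer())
  add <- function(code, detail, position = NA_integer_) {
    tibble::add_row(v, code = code, detail = detail,
                    position = as.integer(position))
  }

  hits <- forbidden_site_hits(backbone$residues)
  allowed <- c(SapI = 0L, BsaI = 0L, BbsI = 0L)
  allowed[acc$name] <- 2L
  donor_enzyme <- if (level == 2L) "BbsI" else NA_character_
  for (nm in names(allowed)) {
    cnt <- sum(hits$enzyme == nm)
    ok <- cnt == allowed[[nm]] ||
      (!is.na(donor_enzyme) && nm == donor_enzyme && cnt %in% c(0L, 2L))
    if (!ok) {
      pos <- hits$position[hits$enzyme == nm]
      v <- add(paste0("STRAY_SITE:", nm),
               paste0("found ", cnt, " ", nm, " site(s), expected ",
                      allowed[[nm]],
                      if (!is.na(donor_enzyme) && nm == donor_enzyme)
                        " (or 2 donor sites)" else ""),
               if (length(pos)) pos[length(pos)] else NA_integer_)
    }
  }

  frags <- digest(backbone, acc)
  if (length(frags) != 2L || isTRUE(frags[[1]]$uncut)) {
    v <- add("NO_CASSETTE",
             paste0(acc$name, " digestion yields ", length(frags),
                    " fragment(s), expected 2 (stuffer + backbone)"))
    return(v)
  }
  n_rec <- vapply(frags, function(f) {
    nrow(scan_sites(f$duplex, acc))
  }, integer(1))
  if (sum(n_rec == 0L) != 1L) {
    v <- add("BAD_CASSETTE_ORIENTATION",
             "recognition sites must face outward from inside the stuffer so exactly one fragment (the backbone) is site-free")
    return(v)
  }
  bb <- frags[[which(n_rec == 0L)]]
  found <- c(revcomp_chr(bb$right_end$protrusion), bb$left_end$protrusion)
  ok <- any(vapply(expected_acceptors, function(e) identical(found, e),
                   logical(1)))
  if (!ok) {
    lab <- site_label_of(found)
    v <- add("WRONG_ACCEPTOR",
             paste0("acceptor sites read (", found[1],
                    ifelse(is.na(lab[1]), "", paste0(" [", lab[1], "]")),
                    ", ", found[2],
                    ifelse(is.na(lab[2]), "", paste0(" [", lab[2], "]")),
                    "); Level ", level, " expects ",
                    paste(vapply(expected_acceptors, paste, "",
                                 collapse = "/"), collapse = " or ")))
  }
  v
}
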