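level_enzyme <- function(level) {
  switch(as.character(level),
         "0" = "BsaI", "1" = "SapI", "2" = "BsaI", "3" = "BbsI",
         rlang::abort("`level` must be 0, 1, 2 or 3."))
}

#' Specify a one-pot restriction-ligation reaction
#'
#' A reaction pairs a destination vector with an ordered list of inserts and
#' the single active type IIS enzyme of that assembly level (SapI at Level 1,
#' BsaI for Level 0 storage cloning and Level 2, BbsI at Level 3). Each insert
#' position may hold a circular storage plasmid, a linear (e.g. freshly
#' domesticated) molecule, a pre-annealed spacer linker fragment, or an
#' unnamed list of such molecules — an equimolar *mixture* occupying one
#' position in a combinatorial assembly.
#'
#' @param destination Circular `stst_dna` destination vector.
#' @param inserts Named list of inserts in design order.
#' @param level Assembly level (0-3).
#' @param enzyme Optional enzyme override; must match the level.
#' @return An object of class `stst_reaction`.
#' @export
reaction_spec <- function(destination, inserts, level, enzyme = NULL) {
  if (!inherits(destination, "stst_dna") || destination$topology != "circular") {
    rlang::abort("`destination` must be a circular stst_dna.")
  }
  if (!is.list(inserts) || length(inserts) == 0L) {
    rlang::abort("`inserts` must be a non-empty list.",
                 class = "stst_reaction_error")
  }
  expected <- level_enzyme(level)
  enz <- enzyme %||% expected
  enz <- if (inherits(enz, "stst_enzyme")) enz$name else enz
  if (!identical(enz, expected)) {
    rlang::abort(paste0("Enzyme ", enz, " does not match level ", level,
                        " (expects ", expected, ")."),
                 class = "stst_reaction_error")
  }
  if (is.null(names(inserts))) {
    names(inserts) <- paste0("insert", seq_along(inserts))
  }
  structure(list(destination = destination, inserts = inserts,
                 level = as.integer(level), enzyme = enzyme(expected)),
            class = "stst_reaction")
}

#' @export
print.stst_reaction <- function(x, ...) {
  cat(sprintf("<stst_reaction> Level %d (%s): %s + %d insert position(s)\n",
              x$level, x$enzyme$name, x$destination$id %||% "destination",
              length(x$inserts)))
  invisible(x)
}

# Digest every reagent and index the fragment pool. A molecule's "payload" is
# its unique fragment free of active-enzyme recognition sites (the fragment
# that can end up in a stable product); donor backbones and stuffers retain
# their sites. Spacer linkers enter pre-cut.
pool_fragments <- function(rx) {
  enz <- rx$enzyme
  frags <- list()
  meta <- list()
  push_molecule <- function(mol, role, position, variant, pos_name) {
    if (inherits(mol, "stst_fragment")) {
      fs <- list(mol)
    } else if (inherits(mol, "stst_dna")) {
      fs <- digest(mol, enz, id = mol$id %||% pos_name)
      if (length(fs) == 1L && isTRUE(fs[[1]]$uncut)) {
        rlang::abort(paste0("Reagent '", mol$id %||% pos_name, "' has no ",
                            enz$name, " site; it cannot participate in this reaction."),
                     class = "stst_reaction_error")
      }
    } else {
      rlang::abort("Inserts must be stst_dna, stst_fragment, or lists of these.")
    }
    n_rec <- vapply(fs, function(f) nrow(scan_sites(f$duplex, enz)), integer(1))
    payload <- n_rec == 0L &
      !vapply(fs, function(f) is_blunt(f$left_end) || is_blunt(f$right_end),
              logical(1))
    if (sum(payload) != 1L) {
      rlang::abort(paste0("Reagent '", fs[[1]]$provenance$id,
                          "' must yield exactly one site-free cohesive fragment (found ",
                          sum(payload), ")."),
                   class = "stst_reaction_error")
    }
    mol_key <- paste0(role, ":", position, ":", variant)
    for (i in seq_along(fs)) {
      frags[[length(frags) + 1L]] <<- fs[[i]]
      meta[[length(meta) + 1L]] <<- tibble::tibble(
        role = role, position = position, variant = variant,
        molecule = mol_key, molecule_id = fs[[i]]$provenance$id,
        payload = payload[i], n_recognition = n_rec[i])
    }
  }

  push_molecule(rx$destination, "destination", 0L, 1L, "destination")
  for (p in seq_along(rx$inserts)) {
    el <- rx$inserts[[p]]
    variants <- if (is.list(el) && !inherits(el, c("stst_dna", "stst_fragment")))
      el else list(el)
    for (vv in seq_along(variants)) {
      push_molecule(variants[[vv]], "insert", p, vv, names(rx$inserts)[p])
    }
  }
  meta <- dplyr::bind_rows(meta)
  meta$idx <- seq_len(nrow(meta))
  list(frags = frags, meta = meta)
}

# Enumerate distinct simple directed cycles (each fragment used at most once,
# the configurable copy bound of the model) in deterministic order: cycles are
# discovered from their lowest-index node, neighbours ascending.
enumerate_cycles <- function(adj, max_cycles = Inf) {
  n <- length(adj)
  cycles <- list()
  truncated <- FALSE
  visited <- logical(n)
  for (s in seq_len(n)) {
    path <- integer(0)
    dfs <- function(v) {
      if (truncated) return()
      path[length(path) + 1L] <<- v
      visited[v] <<- TRUE
      for (w in adj[[v]]) {
        if (truncated) break
        if (w == s) {
          if (length(cycles) >= max_cycles) {
            truncated <<- TRUE
          } else {
            cycles[[length(cycles) + 1L]] <<- path
          }
        } else if (w > s && !visited[w]) {
          dfs(w)
        }
      }
      visited[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(s)
    if (truncated) break
  }
  list(cycles = cycles, truncated = truncated)
}

#' Enumerate the circular products of a one-pot reaction
#'
#' Digests every reagent with the reaction's enzyme, joins fragments whose
#' cohesive ends can anneal, and enumerates the distinct simple circular
#' ligation products — the combinatorial model of a one-pot reaction, in which
#' products that retain no recognition site are terminal ("stable") while
#' re-ligations that regenerate a site are re-cut. Relative yields are not
#' modelled. Each product's top-strand length equals the sum of its fragments'
#' top-strand lengths with every junction overhang counted exactly once.
#'
#' @param rx An `stst_reaction`.
#' @param max_products Enumeration cap; exceeding it sets the `truncated`
#'   attribute.
#' @param classify Attach classifications (see [classify_products()]).
#' @param error_on_no_product Abort with a junction diagnostic when no stable
#'   backbone-containing circle exists (default TRUE).
#' @return A tibble with one row per product: `product_id`, `sequence`
#'   (list of canonical circular `stst_dna`), `length`, `n_fragments`,
#'   `stable`, `classification`, `composition` (list of per-fragment
#'   provenance tibbles). Attribute `truncated` reports a hit enumeration cap.
#' @export
one_pot_products <- function(rx, max_products = 500L, classify = TRUE,
                             error_on_no_product = TRUE) {
  stopifnot(inherits(rx, "stst_reaction"))
  pool <- pool_fragments(rx)
  frags <- pool$frags
  n <- length(frags)
  adj <- lapply(seq_len(n), function(u) {
    which(vapply(seq_len(n), function(v) {
      ends_compatible(frags[[u]]$right_end, frags[[v]]$left_end)
    }, logical(1)))
  })
  enum <- enumerate_cycles(adj, max_cycles = max_products)

  rows <- purrr::map(enum$cycles, function(path) {
    tops <- vapply(frags[path], function(f) f$duplex$residues, character(1))
    feats <- list()
    at <- 0L
    for (i in seq_along(path)) {
      feats[[i]] <- tibble::tibble(
        label = paste0("fragment_", pool$meta$molecule_id[path[i]]),
        start = at, end = at + nchar(tops[i]), strand = "+")
      at <- at + nchar(tops[i])
    }
    circ <- canonicalize(dna(paste0(tops, collapse = ""),
                             topology = "circular",
                             features = dplyr::bind_rows(feats)))
    comp <- pool$meta[path, c("idx", "role", "position", "variant",
                              "molecule", "molecule_id", "payload")]
    tibble::tibble(
      sequence = list(circ),
      length = nchar(circ$residues),
      n_fragments = length(path),
      stable = nrow(scan_sites(circ, rx$enzyme)) == 0L,
      composition = list(comp)
    )
  })
  products <- dplyr::bind_rows(rows)
  if (nrow(products) == 0L) {
    products <- tibble::tibble(sequence = list(), length = integer(),
                               n_fragments = integer(), stable = logical(),
                               composition = list())
  }
  # dedupe identical circles (same canonical sequence and fragment multiset)
  if (nrow(products)) {
    key <- vapply(seq_len(nrow(products)), function(i) {
      paste(products$length[i],
            paste(sort(products$composition[[i]]$idx), collapse = ","),
            products$sequence[[i]]$residues)
    }, character(1))
    products <- products[!duplicated(key), ]
    products$product_id <- sprintf("product%03d", seq_len(nrow(products)))
    products <- products[c("product_id", "sequence", "length", "n_fragments",
                           "stable", "composition")]
  }
  attr(products, "truncated") <- enum$truncated
  attr(products, "reaction") <- rx
  if (classify) products <- classify_products(products, rx, pool = pool)
  if (error_on_no_product) {
    ok <- nrow(products) > 0 && any(
      products$stable &
        vapply(products$composition, function(co) {
          any(co$role == "destination" & co$payload)
        }, logical(1)))
    if (!ok) abort_no_product(pool, rx)
  }
  products
}

abort_no_product <- function(pool, rx) {
  meta <- pool$meta
  payloads <- which(meta$payload & meta$role == "insert")
  payloads <- payloads[order(meta$position[payloads], meta$variant[payloads])]
  backbone <- which(meta$payload & meta$role == "destination")
  cur <- pool$frags[[backbone]]$right_end
  placed <- integer(0)
  stall <- NULL
  repeat {
    need <- revcomp_chr(cur$protrusion)
    cand <- payloads[!(payloads %in% placed) & vapply(payloads, function(i) {
      pool$frags[[i]]$left_end$protrusion == need
    }, logical(1))]
    if (length(cand) == 0L) { stall <- need; break }
    placed <- c(placed, cand[1])
    cur <- pool$frags[[cand[1]]]$right_end
    if (length(placed) == length(payloads)) { stall <- revcomp_chr(cur$protrusion); break }
  }
  unplaced <- setdiff(payloads, placed)
  next_site <- if (length(unplaced)) {
    pool$frags[[unplaced[1]]]$left_end$protrusion
  } else {
    pool$frags[[backbone]]$left_end$protrusion
  }
  lab <- function(s) {
    l <- site_label_of(s)
    if (is.na(l)) s else l
  }
  rlang::abort(
    paste0("NO_PRODUCT: no stable backbone-containing circle. Assembly ",
           "stalls at fusion site '", lab(stall), "': no fragment supplies ",
           "a matching end (gap between ", lab(stall), " and ",
           lab(next_site), ")."),
    class = "stst_no_product", stall_site = stall
  )
}

#' Classify enumerated assembly products
#'
#' `intended`: stable, contains the destination backbone and exactly one
#' payload per insert position, in design order. `relig_donor`: an unstable
#' reconstruction of one of the input plasmids (the re-ligation that
#' regenerates the recognition sites and is re-cut). `misassembly`: stable but
#' with the wrong composition. `background`: everything else.
#'
#' @param products Output of [one_pot_products()].
#' @param rx The reaction.
#' @param pool Internal fragment pool (recomputed if missing).
#' @return `products` with a `classification` column.
#' @export
classify_products <- function(products, rx, pool = NULL) {
  if (nrow(products) == 0L) {
    products$classification <- character(0)
    return(products)
  }
  pool <- pool %||% pool_fragments(rx)
  mol_sizes <- table(pool$meta$molecule)
  n_pos <- length(rx$inserts)

  products$classification <- vapply(seq_len(nrow(products)), function(i) {
    comp <- products$composition[[i]]
    stable <- products$stable[i]
    if (stable) {
      bb <- which(comp$role == "destination" & comp$payload)
      intended <- length(bb) == 1L && nrow(comp) == n_pos + 1L &&
        all(comp$payload)
      if (intended) {
        ord <- c(comp$position[bb:nrow(comp)],
                 if (bb > 1L) comp$position[1:(bb - 1L)])
        intended <- identical(as.integer(ord), as.integer(0:n_pos))
      }
      if (intended) "intended" else "misassembly"
    } else {
      mols <- unique(comp$molecule)
      if (length(mols) == 1L && nrow(comp) == mol_sizes[[mols]]) {
        "relig_donor"
      } else {
        "background"
      }
    }
  }, character(1))
  products
}

#' Audit the overhangs active in a reaction
#'
#' Collects the fusion-site overhang of every junction the reaction can form
#' — one per cohesive junction: each fragment's left-end (top-strand) reading,
#' with mixture variants at the same position collapsed — and audits the set
#' with [audit_overhang_set()] at Hamming threshold 1, flagging duplicates,
#' palindromes, reverse-complement collisions and near-collisions that would
#' permit mis-assembly.
#'
#' @param rx An `stst_reaction`.
#' @param hamming_warn Near-collision threshold (default 1).
#' @return An `stst_fidelity` object.
#' @export
fidelity_report <- function(rx, hamming_warn = 1L) {
  pool <- pool_fragments(rx)
  meta <- pool$meta
  labels <- character(0)
  for (key in unique(meta$molecule[meta$payload])) {
    idxs <- meta$idx[meta$molecule == key & meta$payload]
    labels <- c(labels, unique(vapply(pool$frags[idxs], function(f) {
      f$left_end$protrusion
    }, character(1))))
  }
  audit_overhang_set(labels, hamming_warn = hamming_warn)
}

#' Simulate storage cloning of a domesticated insert into the Level 0 vector
#'
#' One-pot BsaI restriction-ligation of a domesticated linear insert into
#' pStA0: the F/R storage donor sites direct the insert into the backbone in
#' place of the lacZalpha stuffer. The stored part keeps its inner SapI sites
#' (used later for Level 1 excision) and has lost its outer BsaI sites.
#'
#' @param insert Linear `stst_dna` carrying the BsaI/F...R storage grammar
#'   (from [domesticate()]).
#' @param pstA0 Circular `stst_dna` Level 0 vector (from
#'   [synthesize_vector()] or a user sequence).
#' @param id Molecule id for the resulting storage plasmid.
#' @return The canonical circular `stst_dna` Level 0 plasmid.
#' @export
simulate_storage_cloning <- function(insert, pstA0, id = NULL) {
  rx <- reaction_spec(pstA0, stats::setNames(list(insert),
                                             insert$id %||% "insert"),
                      level = 0L)
  products <- one_pot_products(rx)
  hit <- which(products$classification == "intended")
  out <- products$sequence[[hit[1]]]
  out$id <- id %||% paste0("pStA0_", insert$id %||% "part")
  out
}
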