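SPACER <- "<spacer>"

#' Specify one expression unit
#'
#' An expression unit is promoter + UTR/RBS + CDS + terminator. The promoter
#' and RBS (and terminator) slots accept a single part name or a character
#' vector of part names — a *mixture*, one combinatorial position. Units that
#' sit inside an operon omit the promoter (non-first members) and/or the
#' terminator (non-last members); the planner substitutes 12 bp spacer
#' linkers there.
#'
#' @param name Unit name.
#' @param cds CDS part name (always a single part).
#' @param promoter,rbs,terminator Part name(s); `promoter`/`terminator` may be
#'   `NULL` only for internal operon positions.
#' @return A list describing the unit.
#' @export
unit_spec <- function(name, cds, promoter = NULL, rbs, terminator = NULL) {
  stopifnot(length(cds) == 1L)
  list(name = name, promoter = promoter, rbs = rbs, cds = cds,
       terminator = terminator)
}

#' Specify a multi-unit design
#'
#' Collects 1-15 expression units, an optional operon grouping and a
#' destination choice into a validated design. Within an operon, every unit
#' but the first gets a spacer in place of its promoter and every unit but
#' the last gets a spacer in place of its terminator, so one promoter drives
#' the whole operon.
#'
#' @param units List of [unit_spec()] entries, in construct order.
#' @param operon Optional integer vector (length = number of units): units
#'   sharing a non-NA value form one operon; values must label consecutive
#'   runs. `NA` marks monocistronic units. Default: all monocistronic.
#' @param destination_level `"auto"` (Level 2 for up to 5 units, Level 3
#'   above), or 1, 2 or 3. Level 1 is allowed only for single-unit designs
#'   (the Level 1 vector is an intermediate in the full hierarchy).
#' @param destination_vector Optional core-vector name overriding the default
#'   destination.
#' @return An object of class `stst_design`.
#' @examples
#' design_spec(list(
#'   unit_spec("u1", cds = "crtE", promoter = paste0("P", 1:6),
#'             rbs = paste0("R", 1:6), terminator = "T1")
#' ))
#' @export
design_spec <- function(units, operon = NULL,
                        destination_level = "auto",
                        destination_vector = NULL) {
  n <- length(units)
  if (n < 1L || n > 15L) {
    rlang::abort(paste0("A design holds 1-15 expression units; got ", n, "."),
                 class = "stst_capacity_error")
  }
  operon <- operon %||% rep(NA_integer_, n)
  if (length(operon) != n) rlang::abort("`operon` must have one entry per unit.")
  # operon ids must label consecutive runs
  runs <- rle(ifelse(is.na(operon), -seq_along(operon), operon))$values
  if (anyDuplicated(runs[runs > 0])) {
    rlang::abort("Operon ids must mark consecutive units.",
                 class = "stst_design_error")
  }

  first_of <- !duplicated(operon) | is.na(operon)
  last_of <- rev(!duplicated(rev(operon))) | is.na(operon)

  rows <- purrr::map(seq_len(n), function(i) {
    u <- units[[i]]
    promoter <- u$promoter
    terminator <- u$terminator
    if (first_of[i]) {
      if (is.null(promoter)) {
        rlang::abort(paste0("Unit ", i, " starts a transcript and needs a promoter."),
                     class = "stst_design_error")
      }
    } else {
      if (!is.null(promoter)) {
        rlang::abort(paste0("Unit ", i, " is an internal operon member; it takes a spacer, not a promoter."),
                     class = "stst_design_error")
      }
      promoter <- SPACER
    }
    if (last_of[i]) {
      if (is.null(terminator)) {
        rlang::abort(paste0("Unit ", i, " ends a transcript and needs a terminator."),
                     class = "stst_design_error")
      }
    } else {
      if (!is.null(terminator)) {
        rlang::abort(paste0("Unit ", i, " is an internal operon member; it takes a spacer, not a terminator."),
                     class = "stst_design_error")
      }
      terminator <- SPACER
    }
    tibble::tibble(
      unit = i,
      name = u$name %||% paste0("unit", i),
      promoter = list(promoter), rbs = list(u$rbs), cds = list(u$cds),
      terminator = list(terminator), operon = operon[i]
    )
  })
  units_tbl <- dplyr::bind_rows(rows)

  destination_level <- as.character(destination_level)
  if (!destination_level %in% c("auto", "1", "2", "3")) {
    rlang::abort("`destination_level` must be 'auto', 1, 2 or 3.")
  }
  if (destination_level == "1" && n != 1L) {
    rlang::abort("A Level 1 destination holds a single expression unit.",
                 class = "stst_design_error")
  }
  structure(list(units = units_tbl, destination_level = destination_level,
                 destination_vector = destination_vector),
            class = "stst_design")
}

#' @export
print.stst_design <- function(x, ...) {
  n <- nrow(x$units)
  ops <- unique(x$units$operon[!is.na(x$units$operon)])
  cat(sprintf("<stst_design> %d unit(s), %d operon(s), destination level %s\n",
              n, length(ops), x$destination_level))
  invisible(x)
}

is_spacer_slot <- function(x) identical(x, SPACER)

#' Choose Level 1 vectors for one Level 2 group
#'
#' For n units assembled together at Level 2, the donor pairs run
#' (A,B), (B,C), ... with the *last* unit's vector replaced by the Z-vector
#' alternative whose right donor site is Z — so every Level 2 assembly lands
#' in the same A/Z acceptor pair and one destination vector per context
#' suffices. A single unit uses pStA1AZ.
#'
#' @param n Number of units in the group (1-5).
#' @return Character vector of Level 1 vector names.
#' @examples
#' choose_level1_vectors(3)  # pStA1AB pStA1BC pStA1CZ
#' @export
choose_level1_vectors <- function(n) {
  if (n < 1L || n > 5L) {
    rlang::abort(paste0("A Level 2 assembly holds 1-5 Level 1 units; got ",
                        n, "."),
                 class = "stst_capacity_error")
  }
  lefts <- c("A", "B", "C", "D", "E")[seq_len(n)]
  rights <- c(lefts[-1], "Z")[seq_len(n)]
  rights[n] <- "Z"
  paste0("pStA1", lefts, rights)
}

# Partition units into Level 2 groups. Default rule: an operon always forms
# its own group (a split operon would leave a promoter-less unit stranded,
# and merging an operon with neighbours is a design choice, not a default);
# runs of monocistronic units are chunked greedily to 5. If that needs more
# than 3 groups, adjacent atoms are merged greedily as a fallback.
group_units <- function(design) {
  u <- design$units
  n <- nrow(u)
  run_id <- ifelse(is.na(u$operon), -seq_len(n), u$operon)
  r <- rle(run_id)
  atoms <- list()
  at <- 1L
  for (i in seq_along(r$values)) {
    idx <- seq(at, at + r$lengths[i] - 1L)
    at <- at + r$lengths[i]
    if (r$values[i] > 0) {
      if (length(idx) > 5L) {
        rlang::abort(paste0("Operon of ", length(idx),
                            " units exceeds the 5-unit Level 2 capacity; regroup the design."),
                     class = "stst_capacity_error")
      }
      atoms[[length(atoms) + 1L]] <- list(idx = idx, operon = TRUE)
    } else {
      for (j in idx) atoms[[length(atoms) + 1L]] <- list(idx = j, operon = FALSE)
    }
  }

  primary <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur)) primary[[length(primary) + 1L]] <<- cur
    cur <<- integer(0)
  }
  for (a in atoms) {
    if (a$operon) {
      flush()
      primary[[length(primary) + 1L]] <- a$idx
    } else if (length(cur) < 5L) {
      cur <- c(cur, a$idx)
    } else {
      flush()
      cur <- a$idx
    }
  }
  flush()

  if (length(primary) > 3L) {
    # fallback: greedy merge of adjacent atoms, still never splitting an operon
    merged <- list()
    cur <- integer(0)
    for (a in atoms) {
      if (length(cur) + length(a$idx) <= 5L) {
        cur <- c(cur, a$idx)
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- a$idx
      }
    }
    if (length(cur)) merged[[length(merged) + 1L]] <- cur
    primary <- merged
  }
  if (length(primary) > 3L) {
    rlang::abort(paste0("Design needs ", length(primary),
                        " Level 2 groups; the hierarchy supports at most 3 ",
                        "(15 units). Regroup operons or split the design."),
                 class = "stst_capacity_error")
  }
  primary
}

#' Plan a hierarchical assembly
#'
#' Expands a design into the complete reaction plan: one Level 1 reaction per
#' unit with Z-vector substitution for the last unit of each group; for up to
#' 5 units a single Level 2 destination reaction (acceptors A/Z); for 6-15
#' units (or an explicit Level 3 destination) the Level 2 groups are routed
#' to pStA212/pStA223/pStA234 in order and collected in pStA313 (2 groups) or
#' pStA314 (3 groups). Grouping keeps every operon intact in a single Level 2
#' reaction.
#'
#' @param design An [design_spec()] object.
#' @return An object of class `stst_plan` with a `reactions` tibble
#'   (`reaction_id`, `level`, `vector`, `inserts` list-column), the group
#'   structure, and the Level 0 part count.
#' @export
plan_assembly <- function(design) {
  stopifnot(inherits(design, "stst_design"))
  u <- design$units
  n <- nrow(u)

  if (design$destination_level == "1") {
    vec <- design$destination_vector %||% "pStA1AZ"
    reactions <- tibble::tibble(
      reaction_id = "L1_u01", level = 1L, vector = vec,
      inserts = list(unit_inserts(u[1, ])))
    return(new_plan(design, list(1L), reactions, final = "L1_u01"))
  }

  force_l3 <- design$destination_level == "3"
  if (design$destination_level == "2" && n > 5L) {
    rlang::abort("More than 5 units cannot land in a single Level 2 reaction; use destination level 3 (or 'auto').",
                 class = "stst_capacity_error")
  }
  if (n <= 5L && !force_l3) {
    groups <- list(seq_len(n))
  } else {
    groups <- group_units(design)
  }
  if (force_l3 && length(groups) < 2L) {
    rlang::abort("A Level 3 destination collects 2-3 Level 2 blocks; this design forms only one.",
                 class = "stst_design_error")
  }

  reactions <- list()
  l2_ids <- character(0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    vecs <- choose_level1_vectors(length(idx))
    l1_ids <- sprintf("L1_u%02d", idx)
    for (k in seq_along(idx)) {
      reactions[[length(reactions) + 1L]] <- tibble::tibble(
        reaction_id = l1_ids[k], level = 1L, vector = vecs[k],
        inserts = list(unit_inserts(u[idx[k], ])))
    }
    if (length(groups) == 1L) {
      vec2 <- design$destination_vector %||% "pStA212"
    } else {
      vec2 <- c("pStA212", "pStA223", "pStA234")[g]
    }
    l2_id <- sprintf("L2_g%d", g)
    l2_ids <- c(l2_ids, l2_id)
    reactions[[length(reactions) + 1L]] <- tibble::tibble(
      reaction_id = l2_id, level = 2L, vector = vec2,
      inserts = list(purrr::map(l1_ids, ~list(slot = "product", source = .x))))
  }

  if (length(groups) == 1L) {
    final <- l2_ids
  } else {
    vec3 <- design$destination_vector %||%
      if (length(groups) == 2L) "pStA313" else "pStA314"
    reactions[[length(reactions) + 1L]] <- tibble::tibble(
      reaction_id = "L3", level = 3L, vector = vec3,
      inserts = list(purrr::map(l2_ids, ~list(slot = "product", source = .x))))
    final <- "L3"
  }
  new_plan(design, groups, dplyr::bind_rows(reactions), final = final)
}

unit_inserts <- function(urow) {
  slots <- c("promoter", "rbs", "cds", "terminator")
  purrr::map(slots, function(sl) {
    val <- urow[[sl]][[1]]
    list(slot = sl,
         source = val,
         spacer = is_spacer_slot(val))
  })
}

new_plan <- function(design, groups, reactions, final) {
  u <- design$units
  n_parts <- sum(vapply(seq_len(nrow(u)), function(i) {
    sum(!vapply(c("promoter", "rbs", "cds", "terminator"), function(sl) {
      is_spacer_slot(u[[sl]][[i]])
    }, logical(1)))
  }, integer(1)))
  structure(list(design = design, groups = groups, reactions = reactions,
                 final = final, n_level0_parts = n_parts),
            class = "stst_plan")
}

#' @export
print.stst_plan <- function(x, ...) {
  lv <- table(factor(x$reactions$level, levels = 1:3))
  cat(sprintf(paste0("<stst_plan> %d unit(s) in %d group(s): %d Level 1, ",
                     "%d Level 2, %d Level 3 reaction(s); %d Level 0 part ",
                     "position(s); final product: %s (%s)\n"),
              nrow(x$design$units), length(x$groups), lv[1], lv[2], lv[3],
              x$n_level0_parts, x$final,
              x$reactions$vector[x$reactions$reaction_id == x$final]))
  invisible(x)
}

#' Render the bench recipe for a reaction
#'
#' Default amounts follow the standard one-pot protocol: 20 fmol destination
#' vector, 40 fmol of each insert (a 2:1 insert:vector molar ratio), 400 units
#' of T4 DNA ligase and 10 units of the level's restriction endonuclease in
#' 20 ul, thermocycled for 30 two-step cycles of 37 degrees C for 5 min then
#' 16 degrees C for 5 min, with a final 65 degrees C 20 min denaturation. All
#' fields can be overridden.
#'
#' @param rx An `stst_reaction`, or an enzyme name plus `n_inserts`.
#' @param n_inserts Number of insert positions (derived from `rx` if given).
#' @param ... Field overrides (`vector_fmol`, `insert_fmol`, `ligase_units`,
#'   `enzyme_units`, `volume_ul`, `cycles`, ...).
#' @return An object of class `stst_recipe`; `format()` renders protocol text.
#' @examples
#' make_recipe("SapI", n_inserts = 4)
#' @export
make_recipe <- function(rx, n_inserts = NULL, ...) {
  if (inherits(rx, "stst_reaction")) {
    enz_name <- rx$enzyme$name
    n_inserts <- n_inserts %||% length(rx$inserts)
  } else {
    enz_name <- enzyme(rx)$name
    n_inserts <- n_inserts %||% 1L
  }
  rec <- list(
    enzyme = enz_name, n_inserts = n_inserts,
    vector_fmol = 20, insert_fmol = 40,
    ligase_units = 400, enzyme_units = 10, volume_ul = 20,
    cycles = 30, cycle_step1 = "37 C for 5 min", cycle_step2 = "16 C for 5 min",
    final_step = "65 C for 20 min"
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(rec))
  if (length(bad)) rlang::abort(paste0("Unknown recipe field(s): ",
                                       paste(bad, collapse = ", ")))
  rec[names(overrides)] <- overrides
  structure(rec, class = "stst_recipe")
}

#' @export
format.stst_recipe <- function(x, ...) {
  paste0(
    "One-pot restriction-ligation (", x$enzyme, ")\n",
    sprintf("  %g fmol destination vector plasmid DNA\n", x$vector_fmol),
    sprintf("  %g fmol of each insert (%d insert position(s); insert:vector molar ratio %g:1)\n",
            x$insert_fmol, x$n_inserts, x$insert_fmol / x$vector_fmol),
    "  T4 DNA ligase buffer\n",
    sprintf("  %g units T4 DNA ligase\n", x$ligase_units),
    sprintf("  %g units %s\n", x$enzyme_units, x$enzyme),
    sprintf("  total reaction volume %g ul\n", x$volume_ul),
    sprintf("Thermocycle: %d two-step cycles of %s then %s, then %s.",
            x$cycles, x$cycle_step1, x$cycle_step2, x$final_step)
  )
}

#' @export
print.stst_recipe <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Execute an assembly plan in silico
#'
#' Runs the plan's reactions in dependency order against a concrete part
#' library, carrying each reaction's intended product forward as an insert
#' for the next level (pooling between levels is modelled as perfect). The
#' design must be concrete — one part per slot; sample a combinatorial design
#' with [sample_variants()] first.
#'
#' @param plan An `stst_plan`.
#' @param library A fixture set from [generate_fixtures()], or any list with
#'   `plasmids` (named circular `stst_dna` Level 0 storage plasmids),
#'   `linkers` (tibble from [make_spacer_linkers()]) and `vectors` (named
#'   circular `stst_dna`).
#' @return An object of class `stst_simulation`: `final` (the destination
#'   product, CDS-annotated), `products` (named list of every intermediate),
#'   and a `log` tibble.
#' @export
simulate_plan <- function(plan, library) {
  stopifnot(inherits(plan, "stst_plan"))
  u <- plan$design$units
  concrete <- all(vapply(seq_len(nrow(u)), function(i) {
    all(vapply(c("promoter", "rbs", "cds", "terminator"), function(sl) {
      length(u[[sl]][[i]]) == 1L
    }, logical(1)))
  }, logical(1)))
  if (!concrete) {
    rlang::abort("Design has mixture slots; draw concrete variants with sample_variants() before simulating.",
                 class = "stst_design_error")
  }

  linkers <- library$linkers
  cores <- unique(linkers$core)
  spacer_counter <- 0L
  next_spacer <- function(side) {
    # a fresh spacer core per spacer position, cycling through the set
    spacer_counter <<- spacer_counter + 1L
    core <- cores[(spacer_counter - 1L) %% length(cores) + 1L]
    row <- linkers[linkers$side == side & linkers$core == core, ][1, ]
    spacer_fragment(row$core, side = side, name = row$spacer)
  }
  get_plasmid <- function(name) {
    pl <- library$plasmids[[name]]
    if (is.null(pl)) rlang::abort(paste0("Part '", name, "' has no storage plasmid in the library."))
    pl
  }
  get_vector <- function(name) {
    v <- library$vectors[[name]]
    if (is.null(v)) rlang::abort(paste0("Vector '", name, "' missing from the library."))
    v
  }

  products <- list()
  log <- list()
  for (i in seq_len(nrow(plan$reactions))) {
    r <- plan$reactions[i, ]
    ins <- r$inserts[[1]]
    reagents <- purrr::map(ins, function(slot) {
      if (identical(slot$slot, "product")) {
        products[[slot$source]]
      } else if (isTRUE(slot$spacer)) {
        side <- if (slot$slot == "promoter") "promoter_side" else "terminator_side"
        next_spacer(side)
      } else {
        get_plasmid(slot$source)
      }
    })
    names(reagents) <- vapply(seq_along(ins), function(k) {
      if (identical(ins[[k]]$slot, "product")) ins[[k]]$source
      else paste0(ins[[k]]$slot, ":", paste(ins[[k]]$source, collapse = "|"))
    }, character(1))
    rx <- reaction_spec(get_vector(r$vector), reagents, level = r$level)
    prods <- withCallingHandlers(
      one_pot_products(rx),
      stst_no_product = function(e) {
        rlang::abort(paste0("Reaction ", r$reaction_id, " (", r$vector,
                            ") failed: ", conditionMessage(e)),
                     class = "stst_no_product", parent = e)
      })
    hit <- which(prods$classification == "intended")
    out <- prods$sequence[[hit[1]]]
    out$id <- r$reaction_id
    products[[r$reaction_id]] <- out
    log[[length(log) + 1L]] <- tibble::tibble(
      reaction_id = r$reaction_id, level = r$level, vector = r$vector,
      n_products = nrow(prods), n_stable = sum(prods$stable),
      product_bp = nchar(out$residues))
  }

  final <- products[[plan$final]]
  final <- annotate_cds(final, plan$design, library)
  products[[plan$final]] <- final
  structure(list(final = final, products = products,
                 log = dplyr::bind_rows(log), plan = plan),
            class = "stst_simulation")
}

# locate each unit's CDS core on the final product and annotate it
annotate_cds <- function(product, design, library) {
  feats <- product$features
  s2 <- paste0(product$residues, product$residues)
  len <- nchar(product$residues)
  for (i in seq_len(nrow(design$units))) {
    cds_name <- design$units$cds[[i]]
    part <- library$parts[[cds_name]]
    if (is.null(part)) next
    core <- part$core
    at <- stringi::stri_locate_first_fixed(s2, core)[1, 1]
    if (is.na(at)) next
    start <- (at - 1L) %% len
    feats <- tibble::add_row(feats, label = paste0("CDS_", cds_name),
                             start = as.integer(start),
                             end = as.integer(start + nchar(core)),
                             strand = "+")
  }
  dna(product$residues, topology = product$topology, features = feats,
      id = product$id)
}

#' @export
print.stst_simulation <- function(x, ...) {
  cat(sprintf("<stst_simulation> %d reaction(s) executed; final product %s: %d bp circular\n",
              nrow(x$log), x$final$id, nchar(x$final$residues)))
  invisible(x)
}
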