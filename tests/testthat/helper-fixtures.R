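# Shared fixtures, memoised across test files (generation is seeded and takes
# a few seconds; every file sees the identical object).
stst_test_env <- new.env(parent = emptyenv())

test_fixtures <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(stst_test_env[[key]])) {
    stst_test_env[[key]] <- generate_fixtures(seed = seed)
  }
  stst_test_env[[key]]
}

test_vector <- function(name, seed = 7L) {
  key <- paste0("vec_", name, "_", seed)
  if (is.null(stst_test_env[[key]])) {
    stst_test_env[[key]] <- synthesize_vector(name, seed = seed)
  }
  stst_test_env[[key]]
}

# independent reverse complement (Biostrings), used as the oracle
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# independent Hamming distance
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force pair scan of an overhang set: all ordered pairs, plain and
# against reverse complements
oracle_overhang_findings <- function(sites) {
  rc <- vapply(sites, oracle_revcomp, character(1))
  n <- length(sites)
  dup <- pal <- rcc <- 0L
  for (i in seq_len(n)) {
    if (sites[i] == rc[i]) pal <- pal + 1L
    for (j in seq_len(n)) {
      if (i < j && sites[i] == sites[j]) dup <- dup + 1L
      if (i < j && sites[i] == rc[j]) rcc <- rcc + 1L
    }
  }
  c(duplicates = dup, palindromes = pal, rc_collisions = rcc)
}

# all permutations of a vector (small n only)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Brute-force circular-product oracle: every subset of fragments, every cyclic
# order (fixed by anchoring the smallest index first), kept iff all junctions
# (including the closing one) can anneal. Returns a sorted key set of
# "sorted-composition|canonical-sequence".
oracle_circular_products <- function(frags) {
  n <- length(frags)
  keys <- character(0)
  compatible <- function(a, b) {
    pa <- a$right_end$protrusion
    pb <- b$left_end$protrusion
    nzchar(pa) && nzchar(pb) && pb == oracle_revcomp(pa)
  }
  for (k in seq_len(n)) {
    for (subset in utils::combn(n, k, simplify = FALSE)) {
      anchor <- subset[1]
      rest <- subset[-1]
      orders <- if (length(rest)) lapply(perms(rest), function(p) c(anchor, p))
                else list(anchor)
      for (ord in orders) {
        ok <- TRUE
        for (i in seq_along(ord)) {
          nxt <- ord[if (i == length(ord)) 1L else i + 1L]
          if (!compatible(frags[[ord[i]]], frags[[nxt]])) { ok <- FALSE; break }
        }
        if (ok) {
          seqs <- vapply(frags[ord], function(f) f$duplex$residues, character(1))
          circ <- canonicalize(dna(paste0(seqs, collapse = ""),
                                   topology = "circular"))
          keys <- c(keys, paste0(paste(sort(ord), collapse = ","), "|",
                                 circ$residues))
        }
      }
    }
  }
  sort(unique(keys))
}

product_keys <- function(products) {
  sort(unique(vapply(seq_len(nrow(products)), function(i) {
    paste0(paste(sort(products$composition[[i]]$idx), collapse = ","), "|",
           products$sequence[[i]]$residues)
  }, character(1))))
}

# string-splicing oracle for hierarchical products (independent of the
# digestion/ligation code path): slices vector sequences by their annotated
# feature coordinates and pastes part cores between them
feature_start <- function(v, label) {
  f <- v$features[v$features$label == label, ]
  stopifnot(nrow(f) == 1L)
  f$start[1]
}

slice_between <- function(v, from_label, to_label) {
  s <- v$residues
  a <- feature_start(v, from_label)
  b <- feature_start(v, to_label)
  if (a < b) substr(s, a + 1L, b) else
    paste0(substr(s, a + 1L, nchar(s)), substr(s, 1L, b))
}

# top-strand contribution of one unit (alpha..epsilon-exclusive), spacers via
# the linker set in fixture order
oracle_unit_train <- function(urow, fx, spacer_counter_env) {
  slot_seq <- function(sl) {
    val <- urow[[sl]][[1]]
    if (identical(val, "<spacer>")) {
      spacer_counter_env$k <- spacer_counter_env$k + 1L
      core <- unique(fx$linkers$core)[spacer_counter_env$k]
      left <- if (sl == "promoter") "CAG" else "TAA"
      paste0(left, core)
    } else {
      core <- fx$parts[[val]]$core
      substr(core, 1L, nchar(core) - 3L)
    }
  }
  paste0(slot_seq("promoter"), slot_seq("rbs"), slot_seq("cds"),
         slot_seq("terminator"))
}

# expected final construct for a concrete design, built purely by string
# splicing from annotated vectors and part cores
oracle_final_sequence <- function(design, plan, fx) {
  env <- new.env(); env$k <- 0L
  u <- design$units
  r <- plan$reactions
  groups <- plan$groups
  block_strings <- character(0)
  l2_backbones <- character(0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    unit_frags <- character(0)
    for (k in seq_along(idx)) {
      rid <- sprintf("L1_u%02d", idx[k])
      v1 <- fx$vectors[[r$vector[r$reaction_id == rid]]]
      pre <- slice_between(v1, "donor_left_site", "acceptor_left_site")
      post <- slice_between(v1, "acceptor_right_site", "donor_right_site")
      unit_frags <- c(unit_frags,
                      paste0(pre, oracle_unit_train(u[idx[k], ], fx, env), post))
    }
    l2_name <- r$vector[r$reaction_id == sprintf("L2_g%d", g)]
    v2 <- fx$vectors[[l2_name]]
    if (length(groups) == 1L) {
      bb <- slice_between(v2, "acceptor_right_site", "acceptor_left_site")
      return(canonicalize(dna(paste0(paste0(unit_frags, collapse = ""), bb),
                              topology = "circular"))$residues)
    }
    pre2 <- slice_between(v2, "donor_left_site", "acceptor_left_site")
    post2 <- slice_between(v2, "acceptor_right_site", "donor_right_site")
    block_strings <- c(block_strings,
                       paste0(pre2, paste0(unit_frags, collapse = ""), post2))
  }
  v3 <- fx$vectors[[r$vector[r$reaction_id == "L3"]]]
  bb3 <- slice_between(v3, "acceptor_right_site", "acceptor_left_site")
  canonicalize(dna(paste0(paste0(block_strings, collapse = ""), bb3),
                   topology = "circular"))$residues
}

# a small concrete monocistronic design over the fixture parts
concrete_design <- function(n, fx = NULL, destination_level = "auto") {
  cds <- c("dxs", "crtE", "crtB", "crtI", "idi", "lcyB", "crtZ", "crtW")
  design_spec(lapply(seq_len(n), function(i) {
    unit_spec(paste0("u", i), cds = cds[(i - 1L) %% 8L + 1L],
              promoter = paste0("P", (i - 1L) %% 6L + 1L),
              rbs = paste0("R", (i - 1L) %% 6L + 1L),
              terminator = paste0("T", (i - 1L) %% 4L + 1L))
  }), destination_level = destination_level)
}

sense_codons_vec <- function() {
  all <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)), 1,
               paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

contains_forbidden_site <- function(s) {
  any(vapply(c("GCTCTTC", "GGTCTC", "GAAGAC"), function(p) {
    grepl(p, s, fixed = TRUE) || grepl(oracle_revcomp(p), s, fixed = TRUE)
  }, logical(1)))
}

random_clean_fixture_raw <- function(kind) {
  len <- switch(kind, promoter = 35L, utr_rbs = 25L, terminator = 60L,
                cds = NA)
  repeat {
    raw <- if (kind == "cds") {
      paste0("ATG", paste(sample(sense_codons_vec(), 120, replace = TRUE),
                          collapse = ""), "TAA")
    } else {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }
    if (contains_forbidden_site(raw)) next
    ok <- tryCatch({ domesticate(raw, kind, "probe"); TRUE },
                   error = function(e) FALSE)
    if (ok) return(raw)
  }
}
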