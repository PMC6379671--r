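level1_reaction <- function(fx, promoter = "P3", rbs = "R3", cds = "eyfp",
                            terminator = "T1", vector = "pStA1AZ",
                            drop = NULL) {
  ins <- list(promoter = fx$plasmids[[promoter]], rbs = fx$plasmids[[rbs]],
              cds = fx$plasmids[[cds]], terminator = fx$plasmids[[terminator]])
  if (!is.null(drop)) ins[[drop]] <- NULL
  reaction_spec(fx$vectors[[vector]], ins, level = 1L)
}

test_that("a single-construct Level 1 reaction yields one intended product and no stable misassembly", {
  fx <- test_fixtures()
  rx <- level1_reaction(fx)
  pr <- one_pot_products(rx)
  tab <- table(pr$classification)
  expect_equal(unname(tab[["intended"]]), 1L)
  expect_gte(unname(tab[["relig_donor"]]), 1L)
  expect_equal(sum(pr$stable & pr$classification == "misassembly"), 0L)
  # every re-ligated donor is unstable (its recognition sites are regenerated)
  expect_true(all(!pr$stable[pr$classification == "relig_donor"]))
  # each of the five inputs reconstructs exactly once under the copy bound
  expect_equal(sum(pr$classification == "relig_donor"), 5L)

  # the intended product reads promoter-RBS-CDS-terminator with 3 nt
  # junction overlaps: each part core appears, overlapping its neighbour
  intended <- pr$sequence[[which(pr$classification == "intended")]]
  s2 <- paste0(intended$residues, intended$residues)
  cores <- vapply(c("P3", "R3", "eyfp", "T1"), function(p) fx$parts[[p]]$core,
                  character(1))
  # the product is canonically rotated, so chain the matches: each core's
  # first occurrence at or after the previous core's start
  starts <- integer(0)
  prev <- 1L
  for (co in cores) {
    hits <- stringi::stri_locate_all_fixed(s2, co)[[1]][, 1]
    hit <- min(hits[hits >= prev])
    starts <- c(starts, hit)
    prev <- hit
  }
  expect_true(all(is.finite(starts)))
  # beta/gamma/delta junctions: consecutive cores overlap by exactly 3 nt
  expect_equal(unname(starts[-1] - (starts[-4] + nchar(cores[-4]))),
               rep(-3L, 3))
})

test_that("product enumeration matches the permutation brute-force oracle on small pools", {
  fx <- test_fixtures()
  # pool of 6 fragments: vector backbone + stuffer, two Level 0 plasmids
  rx <- reaction_spec(fx$vectors$pStA1AZ,
                      list(promoter = fx$plasmids$P1, rbs = fx$plasmids$R1),
                      level = 1L)
  pr <- one_pot_products(rx, classify = FALSE, error_on_no_product = FALSE)
  pool <- list(digest(fx$vectors$pStA1AZ, "SapI"),
               digest(fx$plasmids$P1, "SapI"),
               digest(fx$plasmids$R1, "SapI"))
  frags <- do.call(c, pool)
  expect_identical(product_keys(pr), oracle_circular_products(frags))

  # and on a complete 5-molecule reaction restricted to <= 6 fragments:
  # vector + promoter + terminator (6 fragments)
  rx2 <- reaction_spec(fx$vectors$pStA1AZ,
                       list(p = fx$plasmids$P2, t = fx$plasmids$T2),
                       level = 1L)
  pr2 <- one_pot_products(rx2, classify = FALSE, error_on_no_product = FALSE)
  frags2 <- c(digest(fx$vectors$pStA1AZ, "SapI"),
              digest(fx$plasmids$P2, "SapI"),
              digest(fx$plasmids$T2, "SapI"))
  expect_identical(product_keys(pr2), oracle_circular_products(frags2))
})

test_that("stability dichotomy and length conservation hold for every product", {
  fx <- test_fixtures()
  pr <- one_pot_products(level1_reaction(fx, promoter = "P5", rbs = "R2",
                                         cds = "crtB", terminator = "T3"))
  for (i in seq_len(nrow(pr))) {
    n_sites <- nrow(scan_sites(pr$sequence[[i]], "SapI"))
    expect_identical(pr$stable[i], n_sites == 0L)
    expect_identical(!pr$stable[i], n_sites >= 1L)
  }
  # conservation: product length equals the sum of its fragments' top strands
  pool <- startstop:::pool_fragments(level1_reaction(fx, promoter = "P5",
                                                     rbs = "R2", cds = "crtB",
                                                     terminator = "T3"))
  lens <- vapply(pool$frags, function(f) nchar(f$duplex$residues), integer(1))
  for (i in seq_len(nrow(pr))) {
    expect_equal(pr$length[i], sum(lens[pr$composition[[i]]$idx]))
  }
})

test_that("a missing part is diagnosed as the specific junction gap", {
  fx <- test_fixtures()
  rx <- level1_reaction(fx, drop = "rbs")
  err <- tryCatch(one_pot_products(rx), error = identity)
  expect_s3_class(err, "stst_no_product")
  expect_match(conditionMessage(err), "beta")
  expect_match(conditionMessage(err), "gamma")
})

test_that("a planted overhang collision produces a stable misassembly", {
  fx <- test_fixtures()
  # a 'terminator' Level 0 part whose flanks were (wrongly) built as a
  # promoter's alpha/beta: it competes with the promoter position
  raw <- random_clean_fixture_raw("promoter")
  dup <- domesticate(raw, "promoter", "dupP")
  stored_dup <- simulate_storage_cloning(dup$insert, fx$vectors$pStA0,
                                         id = "pStA0_dupP")
  rx <- reaction_spec(
    fx$vectors$pStA1AZ,
    list(p = fx$plasmids$P1, p2 = stored_dup, r = fx$plasmids$R1,
         c = fx$plasmids$eyfp, t = fx$plasmids$T1),
    level = 1L)
  fid <- fidelity_report(rx)
  expect_false(fid$pass)
  expect_true("CAG" %in% fid$duplicates$sequence)
  pr <- one_pot_products(rx, error_on_no_product = FALSE)
  expect_gte(sum(pr$classification == "misassembly" & pr$stable), 1L)
})

test_that("fidelity audit passes for standard reactions and rejects mixed levels", {
  fx <- test_fixtures()
  expect_true(fidelity_report(level1_reaction(fx))$pass)

  # five-insert Level 2 reaction: A,B,C,D,E,Z ends all distinct
  d5 <- concrete_design(5)
  sim5 <- simulate_plan(plan_assembly(d5), fx)
  l1 <- sim5$products[paste0("L1_u", sprintf("%02d", 1:5))]
  rx2 <- reaction_spec(fx$vectors$pStA212, l1, level = 2L)
  fid2 <- fidelity_report(rx2)
  expect_true(fid2$pass)

  # mixing 3 nt and 4 nt junctions is a hard error
  expect_error(audit_overhang_set(c("CAG", "GGAG")),
               class = "stst_mixed_lengths")
})

test_that("mixtures enumerate one stable product per variant", {
  fx <- test_fixtures()
  rx <- reaction_spec(
    fx$vectors$pStA1AZ,
    list(promoter = list(fx$plasmids$P1, fx$plasmids$P2),
         rbs = fx$plasmids$R1, cds = fx$plasmids$eyfp,
         terminator = fx$plasmids$T1),
    level = 1L)
  pr <- one_pot_products(rx)
  intended <- pr[pr$classification == "intended", ]
  expect_equal(nrow(intended), 2L)
  expect_false(identical(intended$sequence[[1]]$residues,
                         intended$sequence[[2]]$residues))
})

test_that("storage cloning keeps inner SapI sites and sheds outer BsaI sites", {
  fx <- test_fixtures()
  d <- domesticate(random_clean_fixture_raw("cds"), "cds", "sc")
  stored <- simulate_storage_cloning(d$insert, fx$vectors$pStA0)
  expect_equal(nrow(scan_sites(stored, "SapI")), 2L)
  expect_equal(nrow(scan_sites(stored, "BsaI")), 0L)
  fr <- digest(stored, "SapI")
  part <- fr[[which(vapply(fr, function(f)
    f$left_end$protrusion == "ATG", logical(1)))]]
  expect_identical(reverse_complement(part$right_end$protrusion), "TAA")
})
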