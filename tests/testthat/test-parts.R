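test_that("the fusion-site registry holds the published junction sequences", {
  reg <- fusion_sites()
  expect_equal(nrow(reg), 17L)
  golden <- c(alpha = "CAG", beta = "CCA", gamma = "ATG", delta = "TAA",
              epsilon = "GGA",
              A = "GGAG", B = "AATG", C = "AGGT", D = "GCTT", E = "CGCT",
              Z = "TACT",
              `1` = "TGCC", `2` = "ACTA", `3` = "TTAC", `4` = "CGAG")
  for (lab in names(golden)) {
    expect_identical(fusion_site(lab), golden[[lab]], info = lab)
  }
  expect_identical(nchar(golden[1:5]), setNames(rep(3L, 5), names(golden)[1:5]))
  # F/R stand-ins are flagged synthetic and collide with nothing
  fr <- reg[reg$synthetic, ]
  expect_setequal(fr$label, c("F", "R"))
  four_mers <- reg$sequence[reg$length == 4]
  expect_true(audit_overhang_set(four_mers)$pass)
})

test_that("the overhang audit matches a brute-force pair scan", {
  l1 <- c("CAG", "CCA", "ATG", "TAA", "GGA")
  l2 <- c("GGAG", "AATG", "AGGT", "GCTT", "CGCT", "TACT")
  l3 <- c("TGCC", "ACTA", "TTAC", "CGAG")
  for (set in list(l1, l2, l3)) {
    a <- audit_overhang_set(set, hamming_warn = 0L)
    o <- oracle_overhang_findings(set)
    expect_true(a$pass)
    expect_equal(nrow(a$duplicates), 0L)
    expect_equal(unname(o), c(0L, 0L, 0L))
  }

  # planted defects are found exactly where the oracle finds them
  bad <- c("GGAG", "GATC", "GGAG", "CTCC")  # palindrome, duplicate, rc pair
  a <- audit_overhang_set(bad, hamming_warn = 1L)
  o <- oracle_overhang_findings(bad)
  expect_false(a$pass)
  expect_equal(nrow(a$duplicates), 1L)
  expect_identical(a$palindromes$sequence, "GATC")
  expect_equal(nrow(a$rc_collisions), as.integer(o[["rc_collisions"]]))

  # near-collision scan agrees with explicit Hamming distances
  a2 <- audit_overhang_set(l2, hamming_warn = 1L)
  expected_near <- 0L
  for (i in 1:(length(l2) - 1)) for (j in (i + 1):length(l2)) {
    if (oracle_hamming(l2[i], l2[j]) == 1L) expected_near <- expected_near + 1L
    if (oracle_hamming(l2[i], oracle_revcomp(l2[j])) == 1L)
      expected_near <- expected_near + 1L
  }
  expect_equal(nrow(a2$near_collisions), expected_near)

  expect_error(audit_overhang_set(c("CAG", "GGAG")),
               class = "stst_mixed_lengths")
})

test_that("validate_part reports typed violations deterministically", {
  clean <- part_record("ok", "cds", paste0("ATG", strrep("GCT", 30), "TAA"))
  expect_equal(nrow(validate_part(clean)), 0L)

  tga <- part_record("bad_stop", "cds", paste0("ATG", strrep("GCT", 30), "TGA"))
  v <- validate_part(tga)
  expect_true("BAD_STOP_CODON" %in% v$code)

  frame <- part_record("frame", "cds", paste0("ATG", strrep("GCT", 30), "GTAA"))
  v <- validate_part(frame)
  expect_true("CDS_FRAME" %in% v$code)
  expect_identical(v$severity[v$code == "CDS_FRAME"], "warning")

  prom <- part_record("p", "promoter",
                      paste0("CAG", "TTTT", "GGTCTC", "TTTT", "CCA"))
  v <- validate_part(prom)
  expect_true("INTERNAL_SITE:BsaI" %in% v$code)
  expect_equal(v$position[v$code == "INTERNAL_SITE:BsaI"], 7L)

  wrong <- part_record("w", "utr_rbs", "TTTTTTATG")
  expect_true("WRONG_FLANK" %in% validate_part(wrong)$code)
})

test_that("domestication wraps parts so SapI excision yields the kind's overhangs", {
  set.seed(42)
  raws <- list(
    cds = paste0("ATG", paste(sample(sense_codons_vec(), 100, replace = TRUE),
                              collapse = ""), "TAA"),
    promoter = strrep("TTGACA", 6),
    utr_rbs = paste0("TCTAGAGAAAGAGGAGAAATACTAG"),
    terminator = strrep("GCCTTA", 10)
  )
  expected <- list(cds = c("ATG", "TTA"), promoter = c("CAG", "TGG"),
                   utr_rbs = c("CCA", "CAT"), terminator = c("TAA", "TCC"))
  for (kind in names(raws)) {
    d <- domesticate(raws[[kind]], kind, paste0("x_", kind))
    fr <- digest(d$insert, "SapI")
    expect_length(fr, 3L)
    mid <- fr[[2]]
    expect_identical(mid$left_end$protrusion, expected[[kind]][1], info = kind)
    expect_identical(mid$right_end$protrusion, expected[[kind]][2], info = kind)
    # the insert's own record is violation-free
    expect_equal(nrow(validate_part(d$part)), 0L, info = kind)
    # primer tails are prefix and reverse-complemented suffix
    expect_true(startsWith(d$insert$residues, d$primer_tails[["forward"]]))
    expect_true(endsWith(d$insert$residues,
                         reverse_complement(d$primer_tails[["reverse"]])))
  }

  expect_error(domesticate(paste0("ATG", "GAAGAC", "TAA"), "cds"),
               class = "stst_domestication_error")
  expect_error(domesticate(strrep("GCA", 30), "cds"),
               class = "stst_domestication_error")
  err <- tryCatch(domesticate(paste0("TT", "GAAGAC", "TT"), "promoter"),
                  error = identity)
  expect_match(conditionMessage(err), "BbsI@2")
})

test_that("domesticate -> store -> excise is a full round trip for random parts", {
  fx <- test_fixtures()
  set.seed(9)
  kinds <- c("promoter", "utr_rbs", "cds", "terminator")
  for (i in 1:6) {
    kind <- kinds[(i - 1L) %% 4L + 1L]
    raw <- random_clean_fixture_raw(kind)
    d <- domesticate(raw, kind, "rt")
    stored <- simulate_storage_cloning(d$insert, fx$vectors$pStA0)
    expect_equal(nrow(scan_sites(stored, "SapI")), 2L)
    expect_equal(nrow(scan_sites(stored, "BsaI")), 0L)
    fr <- digest(stored, "SapI")
    part_frag <- fr[[which(vapply(fr, function(f)
      nrow(scan_sites(f$duplex, "SapI")) == 0L, logical(1)))]]
    # fragment top + right overhang bases reconstitute the full core,
    # and stripping the added flanks recovers the raw input exactly
    core <- paste0(part_frag$duplex$residues,
                   reverse_complement(part_frag$right_end$protrusion))
    expect_identical(core, d$part$core)
    recovered <- if (kind == "cds") core else
      substr(core, 4L, nchar(core) - 3L)
    expect_identical(recovered, raw)
    # storing the same insert twice is deterministic
    expect_identical(simulate_storage_cloning(d$insert, fx$vectors$pStA0)$residues,
                     stored$residues)
  }
})

test_that("spacer linkers satisfy their design constraints", {
  lk <- make_spacer_linkers(n = 16, seed = 1)
  expect_equal(nrow(lk), 32L)
  cores <- unique(lk$core)
  expect_length(cores, 16L)
  expect_true(all(nchar(cores) == 12L))
  # determinism
  expect_identical(make_spacer_linkers(n = 16, seed = 1), lk)
  expect_false(identical(make_spacer_linkers(n = 16, seed = 2)$core[1],
                         lk$core[1]))
  # pairwise orthogonality and no spurious starts ahead of the RBS
  for (i in 1:15) for (j in (i + 1):16) {
    expect_gte(oracle_hamming(cores[i], cores[j]), 4L)
  }
  prom <- lk[lk$side == "promoter_side", ]
  expect_false(any(grepl("ATG", paste0(prom$oligo_top, "CCA"), fixed = TRUE)))
  # annealed duplex protrusions are the fusion-site sequences
  fragp <- spacer_fragment(cores[1], "promoter_side")
  expect_identical(fragp$left_end$protrusion, "CAG")
  expect_identical(reverse_complement(fragp$right_end$protrusion), "CCA")
  fragt <- spacer_fragment(cores[1], "terminator_side")
  expect_identical(fragt$left_end$protrusion, "TAA")
  expect_identical(reverse_complement(fragt$right_end$protrusion), "GGA")
  # oligo pair implied duplex matches the fragment model
  expect_identical(prom$oligo_top[1], fragp$duplex$residues)
})
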