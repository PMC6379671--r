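test_that("Z-vector substitution gives the stated vector series", {
  expect_identical(choose_level1_vectors(1), "pStA1AZ")
  expect_identical(choose_level1_vectors(3),
                   c("pStA1AB", "pStA1BC", "pStA1CZ"))
  expect_identical(choose_level1_vectors(5),
                   c("pStA1AB", "pStA1BC", "pStA1CD", "pStA1DE", "pStA1EZ"))
  expect_error(choose_level1_vectors(0), class = "stst_capacity_error")
  expect_error(choose_level1_vectors(6), class = "stst_capacity_error")
})

test_that("plans route small designs to one Level 2 reaction and large ones through Level 3", {
  # 3 monocistronic units: AB, BC, CZ + one Level 2 reaction
  p3 <- plan_assembly(concrete_design(3))
  expect_identical(p3$reactions$vector[p3$reactions$level == 1],
                   c("pStA1AB", "pStA1BC", "pStA1CZ"))
  expect_equal(sum(p3$reactions$level == 2), 1L)
  expect_equal(sum(p3$reactions$level == 3), 0L)

  # 8 units as 4-op + 1 mono + 3-op group as (4,1,3) into pStA314
  d8 <- carotenoid_designs()$asta_hybrid
  p8 <- plan_assembly(d8)
  expect_equal(lengths(p8$groups), c(4L, 1L, 3L))
  expect_identical(
    p8$reactions$vector[p8$reactions$level == 2],
    c("pStA212", "pStA223", "pStA234"))
  expect_identical(p8$reactions$vector[p8$reactions$level == 3], "pStA314")

  # the 5-unit 4-op + 1 mono design explicitly routed to Level 3 -> pStA313
  p41 <- plan_assembly(carotenoid_designs()$hybrid_4op_1mono)
  expect_equal(lengths(p41$groups), c(4L, 1L))
  expect_identical(p41$reactions$vector[p41$reactions$level == 3], "pStA313")

  # Z-invariant: first/last donor sites of every Level 2 group are A and Z
  cv <- core_vectors()
  for (p in list(p3, p8, p41)) {
    for (g in p$groups) {
      vecs <- p$reactions$vector[p$reactions$level == 1][
        match(g, unlist(p$groups))]
      expect_identical(cv$donor_left[cv$name == vecs[1]], "A")
      expect_identical(cv$donor_right[cv$name == vecs[length(vecs)]], "Z")
    }
  }
})

test_that("capacity bounds are exact: 1-15 units plan, 0 and 16 fail", {
  for (n in 1:15) {
    p <- plan_assembly(concrete_design(n))
    expect_s3_class(p, "stst_plan")
    # per-reaction caps
    ins <- vapply(seq_len(nrow(p$reactions)), function(i)
      length(p$reactions$inserts[[i]]), integer(1))
    expect_true(all(ins[p$reactions$level == 2] <= 5L))
    expect_true(all(ins[p$reactions$level == 3] <= 3L))
  }
  expect_error(design_spec(list()), class = "stst_capacity_error")
  expect_error(concrete_design(16), class = "stst_capacity_error")

  # an all-monocistronic 15-unit plan consumes 60 Level 0 parts in 15
  # Level 1 reactions
  p15 <- plan_assembly(concrete_design(15))
  expect_equal(p15$n_level0_parts, 60L)
  expect_equal(sum(p15$reactions$level == 1), 15L)
  expect_equal(lengths(p15$groups), c(5L, 5L, 5L))

  # part accounting holds across n: all-mono designs use exactly 4n parts
  for (n in c(2, 7, 11)) {
    expect_equal(plan_assembly(concrete_design(n))$n_level0_parts, 4L * n)
  }

  # operons larger than a Level 2 group are impossible
  too_big <- design_spec(
    c(list(unit_spec("a", cds = "dxs", promoter = "P1", rbs = "R1")),
      lapply(2:5, function(i) unit_spec(letters[i], cds = "crtE", rbs = "R1")),
      list(unit_spec("f", cds = "crtB", rbs = "R1", terminator = "T1"))),
    operon = rep(1L, 6))
  expect_error(plan_assembly(too_big), class = "stst_capacity_error")
})

test_that("operon spacer-slot invariants are enforced at design construction", {
  expect_error(design_spec(
    list(unit_spec("a", cds = "dxs", promoter = "P1", rbs = "R1"),
         unit_spec("b", cds = "crtE", promoter = "P2", rbs = "R1",
                   terminator = "T1")),
    operon = c(1L, 1L)), class = "stst_design_error")
  expect_error(design_spec(
    list(unit_spec("a", cds = "dxs", rbs = "R1"),
         unit_spec("b", cds = "crtE", rbs = "R1", terminator = "T1")),
    operon = c(1L, 1L)), class = "stst_design_error")
  ok <- design_spec(
    list(unit_spec("a", cds = "dxs", promoter = "P1", rbs = "R1"),
         unit_spec("b", cds = "crtE", rbs = "R1", terminator = "T1")),
    operon = c(1L, 1L))
  expect_identical(ok$units$terminator[[1]], "<spacer>")
  expect_identical(ok$units$promoter[[2]], "<spacer>")
})

test_that("recipes render the standard one-pot protocol and accept overrides", {
  fx <- test_fixtures()
  rx <- reaction_spec(fx$vectors$pStA1AZ,
                      list(p = fx$plasmids$P1, r = fx$plasmids$R1,
                           c = fx$plasmids$eyfp, t = fx$plasmids$T1),
                      level = 1L)
  rec <- make_recipe(rx)
  expect_equal(rec$vector_fmol, 20)
  expect_equal(rec$insert_fmol, 40)
  expect_equal(rec$ligase_units, 400)
  expect_equal(rec$enzyme_units, 10)
  expect_equal(rec$volume_ul, 20)
  txt <- format(rec)
  expect_match(txt, "20 fmol destination vector")
  expect_match(txt, "40 fmol of each insert")
  expect_match(txt, "30 two-step cycles of 37 C for 5 min then 16 C for 5 min")
  expect_match(txt, "65 C for 20 min")
  # overriding the volume leaves the amounts untouched
  rec10 <- make_recipe(rx, volume_ul = 10)
  expect_equal(rec10$volume_ul, 10)
  expect_equal(rec10$vector_fmol, 20)
  expect_error(make_recipe(rx, nonsense = 1))
})

test_that("simulated plans telescope to the string-splicing oracle", {
  fx <- test_fixtures()
  # 5-unit monocistronic toy design -> one final Level 2 product
  d5 <- concrete_design(5)
  p5 <- plan_assembly(d5)
  sim5 <- simulate_plan(p5, fx)
  expect_identical(sim5$final$residues, oracle_final_sequence(d5, p5, fx))

  # a hybrid design with operon spacers, routed through Level 3
  dh <- design_spec(
    list(unit_spec("a", cds = "dxs", promoter = "P1", rbs = "R1"),
         unit_spec("b", cds = "crtE", rbs = "R2"),
         unit_spec("c", cds = "crtB", rbs = "R3", terminator = "T1"),
         unit_spec("d", cds = "crtI", promoter = "P2", rbs = "R4",
                   terminator = "T2")),
    operon = c(1L, 1L, 1L, NA), destination_level = 3)
  ph <- plan_assembly(dh)
  simh <- simulate_plan(ph, fx)
  expect_identical(simh$final$residues, oracle_final_sequence(dh, ph, fx))

  # mixtures must be sampled before simulation
  expect_error(simulate_plan(plan_assembly(carotenoid_designs()$mono5), fx),
               class = "stst_design_error")

  # a wrong vector choice (no Z junction) fails with NO_PRODUCT at Level 2
  bad <- plan_assembly(concrete_design(2))
  bad$reactions$vector[bad$reactions$reaction_id == "L1_u02"] <- "pStA1BC"
  expect_error(simulate_plan(bad, fx), class = "stst_no_product")
})

test_that("a single-unit design can end at Level 1 (validation-experiment mode)", {
  fx <- test_fixtures()
  d1 <- design_spec(list(unit_spec("e", cds = "eyfp", promoter = "P3",
                                   rbs = "R3", terminator = "T1")),
                    destination_level = 1)
  p1 <- plan_assembly(d1)
  expect_equal(nrow(p1$reactions), 1L)
  expect_identical(p1$reactions$vector, "pStA1AZ")
  sim <- simulate_plan(p1, fx)
  expect_equal(nrow(scan_sites(sim$final, "SapI")), 0L)
  expect_error(design_spec(list(unit_spec("a", cds = "dxs", promoter = "P1",
                                          rbs = "R1", terminator = "T1"),
                                unit_spec("b", cds = "crtE", promoter = "P1",
                                          rbs = "R1", terminator = "T1")),
                           destination_level = 1),
               class = "stst_design_error")
})
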