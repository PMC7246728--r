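test_that("network construction validates inputs and builds the stoichiometric matrix", {
  net <- tiny_network()
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(5L, 3L))
  # A + B -> AB: column (-1, -1, +1) on (A, B, AB)
  expect_identical(unname(S[c("A", "B", "AB"), 1]), c(-1L, -1L, 1L))
  expect_identical(unname(S[c("AB", "A", "Bstar"), 2]), c(-1L, 1L, 1L))

  expect_error(
    reaction_network(
      data.frame(
        index = 1, reactants = "A", products = "B",
        rate_constant = -1
      ),
      data.frame(name = "A", initial_amount = 1)
    ),
    "nonnegative"
  )
  expect_error(
    reaction_network(
      data.frame(
        index = 1, reactants = "A", products = "B",
        rate_constant = 1
      ),
      data.frame(name = c("A", "A"), initial_amount = c(1, 1))
    ),
    "unique"
  )
  expect_error(
    reaction_network(
      data.frame(
        index = 1, reactants = "A + B + C", products = "D",
        rate_constant = 1
      ),
      data.frame(name = "A", initial_amount = 1)
    ),
    "1 or 2"
  )
})

test_that("shipped models match the printed tables", {
  m1 <- build_model1()
  m2 <- build_model2()
  expect_identical(nrow(m1$reactions), 17L)
  expect_identical(length(m1$reactions$rate_constant), 17L)
  expect_identical(nrow(m2$reactions), 37L)

  x0 <- setNames(m1$species$initial_amount, m1$species$name)
  expect_identical(
    x0[c("LPS", "TLR4", "TIRAP", "MyD88", "IRAK1", "IRAK4", "TRAF6")],
    c(
      LPS = 500, TLR4 = 20, TIRAP = 100, MyD88 = 1000,
      IRAK1 = 100, IRAK4 = 100, TRAF6 = 100
    )
  )
  # everything else starts at zero
  expect_true(all(x0[setdiff(names(x0), tlr4_proteins)] == 0))

  # spot-checked rate constants from the printed tables
  expect_identical(m1$reactions$rate_constant[1], 1.28e-6)
  expect_identical(m2$reactions$rate_constant[30], 1.0e-5)
  expect_identical(m2$reactions$rate_constant[37], 1.2e-3)

  # Model 2 strictly extends Model 1's species set
  expect_true(all(m1$species$name %in% m2$species$name))
  expect_gt(nrow(m2$species), nrow(m1$species))

  # reactions 1-17 of Model 2 mirror Model 1's topology row by row
  for (j in 1:17) {
    expect_setequal(m2$reactions$reactants[[j]], m1$reactions$reactants[[j]])
    expect_setequal(m2$reactions$products[[j]], m1$reactions$products[[j]])
  }
  # with the re-fitted rate constants exactly at rows 5,7,9 and 14-17
  expect_identical(
    which(m1$reactions$rate_constant != m2$reactions$rate_constant[1:17]),
    c(5L, 7L, 9L, 14L, 15L, 16L, 17L)
  )

  # Model 1 reaction 2 column: LPS_TLR4 -> LPS_bind + TLR4_bind
  S <- stoichiometric_matrix(m1)
  expect_identical(
    unname(S[c("LPS_TLR4", "LPS_bind", "TLR4_bind"), 2]),
    c(-1L, 1L, 1L)
  )
})

test_that("conservation laws are found and verified against the matrix", {
  m1 <- build_model1()
  laws <- conservation_laws(m1)
  expect_setequal(laws$protein, tlr4_proteins)
  for (i in seq_len(nrow(laws))) {
    expect_true(indicator_in_left_null_space(m1, laws$members[[i]]))
  }
  members <- setNames(laws$members, laws$protein)
  expect_setequal(members[["LPS"]], c("LPS", "LPS_TLR4", "LPS_bind"))
  # the TIRAP law includes the transient TIRAP_bind_MyD88 intermediate
  expect_setequal(
    members[["TIRAP"]],
    c("TIRAP", "TLR4_bind_TIRAP", "TIRAP_bind", "TIRAP_bind_MyD88", "TIRAP_drop")
  )
  # ... and the four-species set without it is NOT conserved
  expect_false(indicator_in_left_null_space(
    m1, c("TIRAP", "TLR4_bind_TIRAP", "TIRAP_bind", "TIRAP_drop")
  ))
  expect_identical(unname(laws$total[laws$protein == "MyD88"]), 1000)

  # every protein-label column balance is zero for both models (integer)
  for (net in list(m1, build_model2())) {
    laws <- conservation_laws(net)
    for (i in seq_len(nrow(laws))) {
      expect_true(indicator_in_left_null_space(net, laws$members[[i]]))
    }
  }

  empty <- reaction_network(
    data.frame(
      index = integer(), reactants = character(),
      products = character(), rate_constant = numeric()
    ),
    data.frame(name = character(), initial_amount = numeric())
  )
  expect_identical(nrow(conservation_laws(empty)), 0L)

  # a mistranscribed reaction (protein appears on one side only) is caught
  expect_error(
    reaction_network(
      data.frame(
        index = 1, reactants = "TIRAP", products = "MyD88",
        rate_constant = 1
      ),
      data.frame(name = "TIRAP", initial_amount = 1)
    ),
    "not conserved"
  )
})

test_that("species pools follow the catalyst-prefix convention", {
  m2 <- build_model2()
  expect_setequal(
    species_pool(m2, "MyD88_bind"),
    c("MyD88_bind", "MyD88_bind_IRAK1", "MyD88_bind_IRAK4")
  )
  # _binda pools are distinct from _bind pools despite the shared prefix
  expect_setequal(
    species_pool(m2, "MyD88_binda"),
    c("MyD88_binda", "MyD88_binda_IRAK1", "MyD88_binda_IRAK4")
  )
  expect_setequal(
    species_pool(m2, "TRAF6_BIND"),
    c(
      "TRAF6_BIND", "TRAF6_BIND_MyD88_drop", "TRAF6_BIND_IRAK1_drop",
      "TRAF6_BIND_IRAK4_drop"
    )
  )
  expect_identical(species_pool(m2, "IRAK4_binda"), "IRAK4_binda")
})

test_that("network tables round-trip losslessly through delimited files", {
  m2 <- build_model2()
  rx <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_network(m2, rx, sp)
  back <- read_network(rx, sp, model_id = "model2")
  expect_identical(back$reactions$reactants, m2$reactions$reactants)
  expect_identical(back$reactions$products, m2$reactions$products)
  expect_identical(back$reactions$rate_constant, m2$reactions$rate_constant)
  expect_identical(back$species, m2$species)
  expect_identical(back$stoich, m2$stoich)
})

test_that("rate and initial-amount edits validate their targets", {
  m1 <- build_model1()
  m1b <- set_network_values(m1,
    rate_constants = c("3" = 1e-5),
    initial_amounts = c(LPS = 100)
  )
  expect_identical(m1b$reactions$rate_constant[3], 1e-5)
  expect_identical(
    m1b$species$initial_amount[m1b$species$name == "LPS"],
    100
  )
  expect_error(set_network_values(m1, rate_constants = c("99" = 1)), "unknown")
  expect_error(set_network_values(m1, initial_amounts = c(XYZ = 1)), "unknown")
  expect_error(set_network_values(m1, initial_amounts = c(LPS = -1)), "nonnegative")

  dropped <- zero_drop_rates(m1)
  expect_identical(dropped$reactions$rate_constant[13:17], rep(0, 5))
  expect_identical(
    dropped$reactions$rate_constant[1:12],
    m1$reactions$rate_constant[1:12]
  )
})
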