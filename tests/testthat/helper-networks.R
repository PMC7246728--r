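# Tiny two-step network used for hand-checkable unit tests:
# A + B -> AB -> A + Bstar, then Bstar -> Bdrop.
tiny_network <- function(k = c(1e-3, 1, 1e-2), b0 = 5) {
  reaction_network(
    data.frame(
      index = 1:3,
      reactants = c("A + B", "AB", "Bstar"),
      products = c("AB", "A + Bstar", "Bdrop"),
      rate_constant = k
    ),
    data.frame(name = c("A", "B"), initial_amount = c(10, b0)),
    model_id = "tiny"
  )
}

# Brute-force left-null-space oracle: all 0/1 indicator vectors over the
# species that annihilate the stoichiometric matrix. Exponential in the
# number of candidate species, so callers restrict to a label's candidates.
indicator_in_left_null_space <- function(network, members) {
  S <- stoichiometric_matrix(network)
  v <- as.integer(rownames(S) %in% members)
  all(crossprod(v, S) == 0)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
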