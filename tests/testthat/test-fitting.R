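test_that("r_square matches its definition and hand-computed cases", {
  obs <- c(1, 2, 3)
  expect_equal(r_square(obs, obs), 1)
  expect_equal(r_square(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_square(obs, c(3, 2, 1)), -3) # 1 - 8/2

  expect_error(r_square(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_square(1, 1), "two time points")
  expect_error(r_square(c(1, 2), c(1, NA)), "finite")

  # invariant under common positive rescaling
  set.seed(4)
  for (i in 1:20) {
    y <- runif(8)
    s <- runif(8)
    a <- runif(1, 0.1, 100)
    expect_equal(r_square(a * y, a * s), r_square(y, s))
  }
})

test_that("objective is minimal at the generating parameters and penalizes deviations", {
  m1 <- build_model1()
  sd0 <- generate_stoich_data(synth_config(model = "model1", cv = 0, seed = 3))
  k_true <- m1$reactions$rate_constant
  loss0 <- fit_objective(m1, k_true, sd0$data)
  expect_equal(loss0, 0, tolerance = 1e-8) # mean R-square = 1

  k_off <- k_true
  k_off[5] <- k_off[5] * 10
  expect_gt(fit_objective(m1, k_off, sd0$data), loss0)

  # all rate constants zero: flat simulation scores R-square <= 0 on any
  # rising series, so the loss is at least 1
  expect_gte(fit_objective(m1, rep(0, 17), sd0$data), 1)
})

test_that("global fit is seed-reproducible, bound-respecting and monotone", {
  m1 <- build_model1()
  sd0 <- generate_stoich_data(synth_config(model = "model1", cv = 0, seed = 3))
  fit_a <- global_fit(m1, sd0$data,
    free = c(5, 7), lower = 1e-6, upper = 1e-3,
    seed = 99, pop_size = 10, generations = 8
  )
  fit_b <- global_fit(m1, sd0$data,
    free = c(5, 7), lower = 1e-6, upper = 1e-3,
    seed = 99, pop_size = 10, generations = 8
  )
  expect_identical(fit_a$rate_constants, fit_b$rate_constants)
  expect_identical(fit_a$history, fit_b$history)
  expect_true(all(diff(fit_a$history) <= 0)) # best-so-far never worsens
  est <- fit_a$rate_constants[c("5", "7")]
  expect_true(all(est >= 1e-6 & est <= 1e-3))
  expect_lte(max(fit_a$r_squared$r_squared), 1)

  expect_error(
    global_fit(m1, sd0$data, free = c(5, 99), seed = 1),
    "reaction indices"
  )
  expect_error(
    global_fit(m1, sd0$data, free = 5, lower = -1, upper = 1, seed = 1),
    "bounds"
  )
})

test_that("tidy, glance and the R-square report summarize fits coherently", {
  m1 <- build_model1()
  sd0 <- generate_stoich_data(synth_config(model = "model1", cv = 0, seed = 3))
  fit <- global_fit(m1, sd0$data,
    free = c(5, 7), lower = 1e-6, upper = 1e-3,
    seed = 2, pop_size = 8, generations = 5
  )
  td <- tidy(fit)
  expect_identical(td$term, c("k5", "k7"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_identical(gl$n_series, 8L)
  expect_equal(gl$mean_r2, mean(fit$r_squared$r_squared))

  rep <- r_square_report(fit, fit)
  expect_true(all(rep$delta == 0))
  # 8 series + 2 pulldown means + 1 overall mean
  expect_identical(nrow(rep), 11L)
  overall <- rep[rep$pulldown == "(all)", ]
  expect_equal(overall$r_squared_1, mean(fit$r_squared$r_squared))
})
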