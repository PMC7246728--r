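#' Coefficient of determination between observed and simulated series
#'
#' R2 = 1 - sum((y_exp - y_sim)^2) / sum((y_exp - mean(y_exp))^2), the
#' goodness-of-fit used to score each pulldown series. Never clamped: a model
#' worse than the flat mean gives a negative value. Invariant under a common
#' positive rescaling of both series.
#'
#' @param observed,simulated Numeric vectors on the same time grid, at least
#'   two points.
#' @return A scalar no greater than 1.
#' @examples
#' r_square(c(1, 2, 3), c(3, 2, 1)) # -3
#' @export
r_square <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have the same length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("need at least two time points", call. = FALSE)
  }
  if (!all(is.finite(observed)) || !all(is.finite(simulated))) {
    stop("series must be finite", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed series is constant: R-square denominator undefined",
      call. = FALSE
    )
  }
  1 - sum((observed - simulated)^2) / ss_tot
}

## Candidate rate vector -> per-series R2 tibble (or NULL on solver failure).
candidate_r_squares <- function(network, k, data, observables,
                                rtol = 1e-8, atol = 1e-10) {
  network$reactions$rate_constant <- k
  times <- sort(unique(data$time_min))
  traj <- tryCatch(
    simulate_network(network, times, rtol = rtol, atol = atol),
    error = function(e) NULL
  )
  if (is.null(traj)) {
    return(NULL)
  }
  sim <- observe(traj, observables)
  joined <- dplyr::inner_join(data, sim,
    by = c("pulldown", "component", "time_min"),
    suffix = c("_exp", "_sim")
  )
  dplyr::summarise(joined,
    r_squared = r_square(.data$amount_au_exp, .data$amount_au_sim),
    .by = c("pulldown", "component")
  )
}

#' Fitting objective: one minus the mean R-square
#'
#' Simulates the network with a candidate rate-constant vector and scores it
#' against the stoichiometry data. The loss is `1 - mean(R2)` over the
#' series, unweighted, so it is monotone decreasing in the mean R-square and
#' reaches its minimum value 0 when every series is reproduced exactly.
#' Candidate vectors on which the integrator fails score a large finite
#' penalty instead of raising an error, so a global search can pass through
#' pathological corners of parameter space.
#'
#' @param network A `reaction_network`.
#' @param rate_constants Full numeric vector of candidate rate constants, in
#'   reaction-table order.
#' @param data Stoichiometry time series: tibble with columns `pulldown`,
#'   `component`, `time_min`, `amount_au` (the 8 non-bait series on the
#'   common time grid).
#' @param observables Observable mapping; defaults to the network's.
#' @param penalty Loss assigned on integration failure.
#' @return Scalar loss.
#' @export
fit_objective <- function(network, rate_constants, data, observables = NULL,
                          penalty = 1e6) {
  if (is.null(observables)) observables <- default_observables(network)
  r2 <- candidate_r_squares(network, rate_constants, data, observables)
  if (is.null(r2) || !all(is.finite(r2$r_squared))) {
    return(penalty)
  }
  1 - mean(r2$r_squared)
}

## Differential evolution (rand/1/bin) in log10-parameter space.
## Plain and deliberately small: seed-reproducible, bound-respecting,
## best-so-far monotone. d = number of free parameters.
de_optimize <- function(fn, lower, upper, seed, pop_size = NULL,
                        generations = 60, f = 0.8, cr = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(pop_size)) pop_size <- max(15L, 5L * d)
  set.seed(seed)
  pop <- matrix(stats::runif(pop_size * d, lower, upper),
    nrow = pop_size, byrow = TRUE
  )
  cost <- apply(pop, 1, fn)
  history <- numeric(generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(setdiff(seq_len(pop_size), i), 3)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      trial <- pmin(pmax(trial, lower), upper)
      keep <- stats::runif(d) > cr
      keep[sample.int(d, 1)] <- FALSE
      trial[keep] <- pop[i, keep]
      c_trial <- fn(trial)
      if (c_trial <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- c_trial
      }
    }
    history[g] <- min(cost)
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], history = history)
}

#' Global fit of rate constants to stoichiometry time-course data
#'
#' Determines a subset of rate constants by minimizing `1 - mean(R2)` over
#' the pulldown series with a differential-evolution search in log10
#' parameter space. The search is reproducible given `seed`, respects the
#' bounds, and its best-so-far loss is non-increasing across generations.
#' Rate constants not listed in `free` stay at the network's values; by
#' convention the 1-per-second release constants of the printed tables are
#' treated as fixed.
#'
#' @inheritParams fit_objective
#' @param free Integer vector of reaction indices whose rate constants are
#'   fitted.
#' @param lower,upper Bounds on the free rate constants (positive; recycled
#'   to `length(free)`). Defaults span 1e-8 to 1e-1, the range of the printed
#'   association/drop constants.
#' @param seed Integer seed for the stochastic search.
#' @param pop_size,generations Differential-evolution population size (default
#'   `max(15, 5 * length(free))`) and number of generations.
#' @return An object of class `lps_fit`: list with `rate_constants` (full
#'   fitted vector), `free`, `r_squared` (per-series tibble), `mean_r2`,
#'   `loss`, `history` (best loss per generation), `seed`, `bounds`,
#'   `network`, `data`.
#' @seealso [tidy.lps_fit()], [glance.lps_fit()], [r_square_report()]
#' @export
global_fit <- function(network, data, free, lower = 1e-8, upper = 1e-1,
                       seed = 1, pop_size = NULL, generations = 60,
                       observables = NULL) {
  stopifnot(inherits(network, "reaction_network"), length(free) >= 1)
  if (!all(free %in% network$reactions$index)) {
    stop("free must be reaction indices of the network", call. = FALSE)
  }
  if (!nrow(data) || !all(is.finite(data$amount_au))) {
    stop("data must be non-empty and finite", call. = FALSE)
  }
  lower <- rep_len(lower, length(free))
  upper <- rep_len(upper, length(free))
  if (any(lower <= 0) || any(upper < lower)) {
    stop("bounds must be positive with upper >= lower", call. = FALSE)
  }
  if (is.null(observables)) observables <- default_observables(network)
  pos <- match(free, network$reactions$index)
  k_full <- network$reactions$rate_constant
  fn <- function(theta) {
    k <- k_full
    k[pos] <- 10^theta
    fit_objective(network, k, data, observables)
  }
  opt <- de_optimize(fn, log10(lower), log10(upper),
    seed = seed,
    pop_size = pop_size, generations = generations
  )
  k_fit <- k_full
  k_fit[pos] <- 10^opt$par
  r2 <- candidate_r_squares(network, k_fit, data, observables)
  structure(
    list(
      rate_constants = stats::setNames(k_fit, network$reactions$index),
      free = free, r_squared = r2, mean_r2 = mean(r2$r_squared),
      loss = opt$value, history = opt$history, seed = seed,
      bounds = tibble::tibble(index = free, lower = lower, upper = upper),
      generations = length(opt$history),
      network = network, data = data
    ),
    class = "lps_fit"
  )
}

#' @export
print.lps_fit <- function(x, ...) {
  cat(
    "<lps_fit> model", format(x$network$model_id), "-",
    length(x$free), "free rate constants, seed", x$seed, "\n"
  )
  cat(
    "  mean R-square:", signif(x$mean_r2, 4),
    " loss:", signif(x$loss, 4), "\n"
  )
  invisible(x)
}

#' Tidy a fitted kinetic model
#'
#' @param x An `lps_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted rate constant (`term` is the reaction
#'   index as `k<index>`, `estimate` the fitted value, `lower`/`upper` the
#'   search bounds). `glance()`: a one-row model summary.
#' @method tidy lps_fit
#' @export
tidy.lps_fit <- function(x, ...) {
  pos <- match(x$free, as.integer(names(x$rate_constants)))
  tibble::tibble(
    term = paste0("k", x$free),
    estimate = unname(x$rate_constants[pos]),
    lower = x$bounds$lower, upper = x$bounds$upper
  )
}

#' @rdname tidy.lps_fit
#' @method glance lps_fit
#' @export
glance.lps_fit <- function(x, ...) {
  tibble::tibble(
    model_id = format(x$network$model_id),
    n_free = length(x$free), n_series = nrow(x$r_squared),
    mean_r2 = x$mean_r2, loss = x$loss,
    generations = x$generations, seed = x$seed
  )
}

#' Compare per-series R-square between two fitted models
#'
#' Side-by-side comparison of the goodness of fit of two models on the same
#' data: one row per (pulldown, component) series plus per-pulldown mean rows
#' and an overall mean row.
#'
#' @param fit1,fit2 `lps_fit` objects fitted to the same series.
#' @return Tibble with columns `pulldown`, `component`, `r_squared_1`,
#'   `r_squared_2`, `delta` (2 minus 1). Mean rows carry `component = "(mean)"`
#'   and the overall row `pulldown = "(all)"`.
#' @export
r_square_report <- function(fit1, fit2) {
  key <- function(f) dplyr::arrange(f$r_squared, .data$pulldown, .data$component)
  a <- key(fit1)
  b <- key(fit2)
  if (!identical(a[c("pulldown", "component")], b[c("pulldown", "component")])) {
    stop("fits cover different observable series", call. = FALSE)
  }
  per <- dplyr::transmute(a,
    pulldown = .data$pulldown, component = .data$component,
    r_squared_1 = .data$r_squared, r_squared_2 = b$r_squared
  )
  pd_means <- dplyr::summarise(per,
    component = "(mean)",
    r_squared_1 = mean(.data$r_squared_1),
    r_squared_2 = mean(.data$r_squared_2),
    .by = "pulldown"
  )
  overall <- dplyr::summarise(per,
    pulldown = "(all)", component = "(mean)",
    r_squared_1 = mean(.data$r_squared_1),
    r_squared_2 = mean(.data$r_squared_2)
  )
  dplyr::mutate(
    dplyr::bind_rows(per, pd_means, overall),
    delta = .data$r_squared_2 - .data$r_squared_1
  )
}
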