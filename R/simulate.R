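## Precompute fast mass-action RHS data: reactant indices i1, i2 (i2 = 0 for
## unimolecular steps) so that q = k * x[i1] * (i2 ? x[i2] : 1) without any
## per-call list traversal.
compile_rhs <- function(network) {
  nm <- network$species$name
  i1 <- vapply(network$reactions$reactants, function(r) match(r[1], nm), 0L)
  i2 <- vapply(
    network$reactions$reactants,
    function(r) if (length(r) > 1) match(r[2], nm) else 0L, 0L
  )
  has2 <- i2 > 0L
  S <- network$stoich
  storage.mode(S) <- "double"
  m <- nrow(S)
  list(S = S, i1 = i1, i2 = i2, has2 = has2, m = m)
}

rhs_rates <- function(cc, x, k) {
  q <- k * x[cc$i1]
  q[cc$has2] <- q[cc$has2] * x[cc$i2[cc$has2]]
  q
}

apply_overrides <- function(network, overrides) {
  if (is.null(overrides) || length(overrides) == 0) {
    return(network)
  }
  ov <- unlist(overrides)
  if (any(ov < 0)) stop("overrides must be nonnegative", call. = FALSE)
  is_rate <- grepl("^k[0-9]+$", names(ov))
  rates <- ov[is_rate]
  names(rates) <- sub("^k", "", names(rates))
  inits <- ov[!is_rate]
  set_network_values(network,
    rate_constants = if (length(rates)) rates,
    initial_amounts = if (length(inits)) inits
  )
}

as_trajectory <- function(mat, network, fluxes) {
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out)[1] <- "time_min"
  out$time_min <- out$time_min / 60
  structure(out,
    class = c("lps_trajectory", class(out)),
    network = network, fluxes = fluxes
  )
}

#' Simulate a reaction network
#'
#' Integrates the mass-action ODE system dx_i/dt = sum_j v_ij q_j with
#' q_j = k_j * (product of reactant amounts), using a stiff-capable adaptive
#' solver. Rate constants are per second; the public time axis is in minutes
#' (the unit of the stoichiometry data); conversion is internal.
#'
#' @param network A `reaction_network`.
#' @param times Numeric vector of output times in minutes, starting at 0,
#'   strictly increasing.
#' @param overrides Optional named numeric vector: species names override
#'   initial amounts, names of the form `"k<index>"` (e.g. `"k3"`) override
#'   rate constants. Negative values are rejected.
#' @param fluxes If `TRUE`, also integrate the cumulative reaction fluxes
#'   (time integral of each q_j, in A.U.), returned as columns
#'   `flux_<index>`.
#' @param method,rtol,atol Solver settings passed to [deSolve::ode()]. The
#'   defaults (`lsoda`, 1e-8, 1e-10) are tight enough that downstream
#'   analyses are solver-independent; the rate constants span seven orders of
#'   magnitude, so a stiff-capable method is required.
#'
#' @return A tibble of class `lps_trajectory`: column `time_min` then one
#'   column per species (A.U., clipped to 0 when within solver tolerance
#'   below it), plus cumulative flux columns when `fluxes = TRUE`. The
#'   network is attached as attribute `"network"`.
#'
#' @examples
#' traj <- simulate_network(build_model1(), times = seq(0, 360, by = 5))
#' @export
simulate_network <- function(network, times, overrides = NULL, fluxes = FALSE,
                             method = "lsoda", rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 (minutes) and be strictly increasing",
      call. = FALSE
    )
  }
  network <- apply_overrides(network, overrides)
  cc <- compile_rhs(network)
  k <- network$reactions$rate_constant
  x0 <- stats::setNames(network$species$initial_amount, network$species$name)
  if (fluxes) {
    x0 <- c(x0, stats::setNames(
      rep(0, length(k)),
      paste0("flux_", network$reactions$index)
    ))
  }
  deriv <- function(t, x, p) {
    q <- rhs_rates(cc, x[seq_len(cc$m)], p)
    dx <- as.vector(cc$S %*% q)
    if (fluxes) list(c(dx, q)) else list(dx)
  }
  sol <- deSolve::ode(
    y = x0, times = times * 60, func = deriv, parms = k,
    method = method, rtol = rtol, atol = atol
  )
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    stop("ODE integration failed (solver return code ", istate, ")",
      call. = FALSE
    )
  }
  amounts <- sol[, -1, drop = FALSE]
  if (min(amounts) < -1e-9) {
    warning("solver produced amounts below -1e-9 A.U.; check tolerances")
  }
  sol[, -1] <- pmax(amounts, 0)
  as_trajectory(sol, network, fluxes)
}

#' Fixed-step Euler integration (validation oracle)
#'
#' Explicit first-order integration at a fixed step, used to validate the
#' adaptive solver: at a sufficiently small step the two must agree, and the
#' deviation must shrink linearly with the step. Not meant for production
#' runs.
#'
#' @inheritParams simulate_network
#' @param step Step size in seconds. Must divide the output grid; keep it
#'   well below the fastest time constant (1 s in the shipped models) for
#'   stability.
#' @return An `lps_trajectory` tibble on the requested grid.
#' @export
simulate_euler <- function(network, times, step = 0.01, overrides = NULL) {
  stopifnot(inherits(network, "reaction_network"), step > 0)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 (minutes) and be strictly increasing",
      call. = FALSE
    )
  }
  network <- apply_overrides(network, overrides)
  cc <- compile_rhs(network)
  k <- network$reactions$rate_constant
  x <- stats::setNames(network$species$initial_amount, network$species$name)
  t_sec <- times * 60
  nsteps <- diff(t_sec) / step
  if (max(abs(nsteps - round(nsteps))) > 1e-8) {
    stop("step must divide every output interval", call. = FALSE)
  }
  nsteps <- as.integer(round(nsteps))
  out <- matrix(0, length(t_sec), cc$m,
    dimnames = list(NULL, network$species$name)
  )
  out[1, ] <- x
  S <- cc$S
  i1 <- cc$i1
  i2 <- cc$i2
  has2 <- cc$has2
  for (seg in seq_along(nsteps)) {
    for (s in seq_len(nsteps[seg])) {
      q <- k * x[i1]
      q[has2] <- q[has2] * x[i2[has2]]
      x <- x + step * as.vector(S %*% q)
    }
    out[seg + 1, ] <- x
  }
  as_trajectory(cbind(time = t_sec, out), network, fluxes = FALSE)
}

#' Conservation drift of a trajectory
#'
#' Maximum relative drift of each conserved protein total over the
#' trajectory, |total(t) - total(0)| / total(0). Used as a trajectory
#' invariant: with default solver settings the drift stays below 1e-6.
#'
#' @param trajectory An `lps_trajectory`.
#' @return Tibble with columns `protein` and `max_rel_drift`.
#' @export
conservation_drift <- function(trajectory) {
  network <- attr(trajectory, "network")
  laws <- conservation_laws(network)
  counts <- species_label_counts(network)
  drift <- vapply(laws$protein, function(l) {
    w <- counts[, l]
    tot <- as.matrix(trajectory[, rownames(counts)[w > 0], drop = FALSE]) %*%
      w[w > 0]
    max(abs(tot - tot[1])) / tot[1]
  }, 0)
  tibble::tibble(protein = laws$protein, max_rel_drift = unname(drift))
}

#' Tidy (long) form of a trajectory
#'
#' @param trajectory An `lps_trajectory`.
#' @return Tibble with columns `time_min`, `species`, `amount_au`.
#' @export
trajectory_long <- function(trajectory) {
  tidyr::pivot_longer(tibble::as_tibble(trajectory), -"time_min",
    names_to = "species", values_to = "amount_au"
  )
}
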