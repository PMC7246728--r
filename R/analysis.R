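## Map each free signaling protein to its branch-specific recruitment
## reactions. A recruitment is a bimolecular association consuming the free
## protein, paired with the release step that regenerates the catalyst and
## deposits the protein in a bound pool; the bound pool's suffix names the
## branch (bind = Myddosome, binda = TIRAP-independent). Recruitment of
## already-dropped material (the post-Myddosome MyD88-TRAF6 complex) is not a
## recruitment of free protein and is excluded.
recruitment_map <- function(network) {
  rx <- network$reactions
  free_proteins <- setdiff(
    network$species$name[network$species$initial_amount > 0],
    c("LPS", "TLR4")
  )
  rows <- list()
  for (j in seq_len(nrow(rx))) {
    rr <- rx$reactants[[j]]
    if (length(rr) != 2) next
    prot <- intersect(rr, free_proteins)
    if (length(prot) != 1) next
    catalyst <- setdiff(rr, prot)
    ab <- rx$products[[j]]
    if (length(ab) != 1) next
    rel <- which(vapply(
      seq_len(nrow(rx)),
      function(i) identical(rx$reactants[[i]], ab), TRUE
    ))
    if (length(rel) != 1) next
    bound <- setdiff(rx$products[[rel]], catalyst)
    if (length(bound) != 1) next
    suffix <- utils::tail(strsplit(bound, "_", fixed = TRUE)[[1]], 1)
    branch <- switch(suffix,
      bind = "myddosome",
      binda = "independent",
      NA_character_
    )
    if (is.na(branch)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = prot, branch = branch, reaction = rx$index[j],
      bound_form = bound
    )
  }
  dplyr::bind_rows(rows)
}

## Share of engaged receptor committed to each branch at stimulation onset:
## the branch flux partition of the bimolecular reactions consuming the
## engaged receptor form, with the competing substrates at their initial
## amounts. The receptor is catalytic in both branches (regenerated by the
## release steps), so this partition -- not a standing pool -- is its
## recruitment share; evaluated at onset it is independent of the
## stimulation strength.
receptor_onset_partition <- function(network, receptor_bound = "TLR4_bind") {
  rx <- network$reactions
  x0 <- stats::setNames(network$species$initial_amount, network$species$name)
  w <- c(myddosome = 0, independent = 0)
  for (j in seq_len(nrow(rx))) {
    rr <- rx$reactants[[j]]
    if (length(rr) != 2 || !receptor_bound %in% rr) next
    partner <- setdiff(rr, receptor_bound)
    ab <- rx$products[[j]]
    rel <- which(vapply(
      seq_len(nrow(rx)),
      function(i) identical(rx$reactants[[i]], ab), TRUE
    ))
    if (length(rel) != 1) next
    bound <- setdiff(rx$products[[rel]], receptor_bound)
    suffix <- utils::tail(strsplit(bound, "_", fixed = TRUE)[[1]], 1)
    branch <- switch(suffix,
      bind = "myddosome",
      binda = "independent",
      NA_character_
    )
    if (is.na(branch)) next
    w[branch] <- w[branch] + rx$rate_constant[j] * x0[partner]
  }
  if (sum(w) == 0) {
    return(w)
  }
  100 * w / sum(w)
}

#' Distribution of components between the two MyD88 activation complexes
#'
#' For each signaling protein, the percentage of its initial amount recruited
#' into the TIRAP-dependent complex (Myddosome) and into the
#' TIRAP-independent MyD88 complex over the simulation horizon, P_COM/P_INI.
#' P_COM is the *total amount recruited*: the time-integrated flux of the
#' branch's association reaction under the full printed kinetics.
#' Disassociation is thereby excluded from the accounting -- material that
#' later drops out of a complex still counts as recruited -- while the
#' assembly dynamics themselves keep the printed disassociation rates, which
#' is what shapes the competition between the transient Myddosome pools and
#' the persistent TIRAP-independent pool.
#'
#' TLR4 is catalytic in both branches (the release steps regenerate
#' `TLR4_bind`), so its two percentages are the branch flux partition of the
#' engaged receptor at stimulation onset; they always sum to 100.
#'
#' @param network A Model 2 style `reaction_network` (both branches present).
#' @param lps LPS stimulation strength in A.U. (initial LPS amount);
#'   `lps = 0` returns all-zero percentages.
#' @param horizon_h Simulation horizon in hours (default 10).
#' @return Tibble with columns `component`, `pct_myddosome`,
#'   `pct_independent`, `lps`, `horizon_h`. Percentages are >= 0 and the two
#'   branch shares of a component sum to at most 100.
#' @examples
#' \donttest{
#' complex_distribution(build_model2(), lps = 100)
#' }
#' @export
complex_distribution <- function(network, lps = 100, horizon_h = 10) {
  stopifnot(inherits(network, "reaction_network"))
  if (lps < 0 || horizon_h <= 0) {
    stop("lps must be >= 0 and horizon_h > 0", call. = FALSE)
  }
  rec <- recruitment_map(network)
  components <- c("TLR4", unique(rec$component))
  if (lps == 0) {
    return(tibble::tibble(
      component = components, pct_myddosome = 0, pct_independent = 0,
      lps = lps, horizon_h = horizon_h
    ))
  }
  traj <- simulate_network(network,
    times = c(0, horizon_h * 60),
    overrides = c(LPS = lps), fluxes = TRUE
  )
  terminal <- traj[nrow(traj), ]
  x0 <- stats::setNames(network$species$initial_amount, network$species$name)
  rec$recruited <- vapply(
    rec$reaction,
    function(j) terminal[[paste0("flux_", j)]], 0
  )
  shares <- tidyr::pivot_wider(
    dplyr::summarise(rec,
      recruited = sum(.data$recruited),
      .by = c("component", "branch")
    ),
    names_from = "branch", values_from = "recruited", values_fill = 0
  )
  if (!"independent" %in% names(shares)) shares$independent <- 0
  shares <- dplyr::transmute(shares,
    component = .data$component,
    pct_myddosome = 100 * .data$myddosome / unname(x0[.data$component]),
    pct_independent = 100 * .data$independent / unname(x0[.data$component])
  )
  tlr4 <- receptor_onset_partition(network)
  dplyr::bind_rows(
    tibble::tibble(
      component = "TLR4",
      pct_myddosome = tlr4[["myddosome"]],
      pct_independent = tlr4[["independent"]]
    ),
    shares
  ) |>
    dplyr::mutate(lps = lps, horizon_h = horizon_h)
}

#' LPS dose-response scan of component distribution
#'
#' Runs [complex_distribution()] over a grid of LPS stimulation strengths and
#' derives, per component, the threshold LPS at which its Myddosome share
#' first reaches 95% of its maximum over the grid.
#'
#' @inheritParams complex_distribution
#' @param lps_grid Positive LPS values, e.g. logarithmic over 1 to 1e4.
#' @return Tibble of distributions (one block per grid point) with attribute
#'   `"thresholds"`; retrieve it with [dose_thresholds()].
#' @examples
#' \donttest{
#' scan <- dose_response_scan(build_model2(), lps_grid = 10^(0:4))
#' dose_thresholds(scan)
#' }
#' @export
dose_response_scan <- function(network, lps_grid = 10^seq(0, 4, by = 0.5),
                               horizon_h = 10) {
  if (!length(lps_grid) || any(lps_grid <= 0)) {
    stop("lps_grid must be non-empty and positive", call. = FALSE)
  }
  scan <- purrr::map(
    lps_grid,
    function(l) complex_distribution(network, lps = l, horizon_h = horizon_h)
  ) |>
    dplyr::bind_rows()
  thresholds <- dplyr::summarise(scan,
    threshold_lps = min(.data$lps[
      .data$pct_myddosome >= 0.95 * max(.data$pct_myddosome)
    ]),
    max_pct_myddosome = max(.data$pct_myddosome),
    .by = "component"
  )
  structure(scan, thresholds = thresholds)
}

#' @rdname dose_response_scan
#' @param scan Output of [dose_response_scan()].
#' @export
dose_thresholds <- function(scan) {
  attr(scan, "thresholds")
}

myddosome_pools <- function(network, trajectory,
                            components = c(
                              "TIRAP", "MyD88", "IRAK1",
                              "IRAK4", "TRAF6"
                            )) {
  sapply(components, function(comp) {
    sp <- species_pool(network, paste0(comp, "_bind"))
    rowSums(tibble::as_tibble(trajectory)[, sp, drop = FALSE])
  })
}

#' Stoichiometry of Myddosome components relative to TIRAP
#'
#' The ratio of each component's Myddosome pool to the TIRAP Myddosome pool
#' at the requested times, under the full printed kinetics. Ratios above 1
#' quantify higher-order assembly: several copies of a downstream component
#' per recruiting TIRAP.
#'
#' @param network A `reaction_network` (Model 2 for the published analysis).
#' @param lps LPS stimulation strength (A.U.).
#' @param times Times in minutes (positive) at which ratios are read.
#' @return Tibble with columns `component`, `time_min`, `ratio_to_tirap`,
#'   `lps`. The TIRAP:TIRAP row is identically 1.
#' @examples
#' \donttest{
#' stoichiometry_ratios(build_model2(), lps = 1e4, times = c(30, 120))
#' }
#' @export
stoichiometry_ratios <- function(network, lps = 500, times = c(30, 60, 120)) {
  stopifnot(all(times > 0))
  grid <- seq(0, max(times), by = 1)
  traj <- simulate_network(network, grid, overrides = c(LPS = lps))
  pools <- myddosome_pools(network, traj)
  rows <- match(times, grid)
  tirap <- pools[rows, "TIRAP"]
  if (any(tirap == 0)) {
    stop("TIRAP Myddosome pool is 0 at a requested time: ratio undefined",
      call. = FALSE
    )
  }
  tidyr::expand_grid(
    component = colnames(pools),
    time_min = times
  ) |>
    dplyr::mutate(
      ratio_to_tirap = purrr::map2_dbl(
        .data$component, match(.data$time_min, times),
        function(comp, i) pools[rows[i], comp] / tirap[i]
      ),
      lps = lps
    )
}

#' Peak of the TRAF6 complex and the MyD88:TIRAP ratio there
#'
#' Finds the time (1-minute grid) at which the total TRAF6-complex content --
#' the sum of the TRAF6-pulldown component observables -- is maximal, and
#' reads the Myddosome TIRAP pool and the MyD88:TIRAP Myddosome ratio at that
#' time. This is the operating point at which the published stoichiometry
#' (roughly six MyD88 per TIRAP) is quoted.
#'
#' @param network A `reaction_network`.
#' @param lps Optional LPS override (A.U.); `NULL` keeps the table default.
#' @param tirap Optional TIRAP initial-amount override (A.U.).
#' @param t_max Scan horizon in minutes.
#' @return One-row tibble: `peak_time_min`, `tirap_in_myddosome`,
#'   `myd88_tirap_ratio`.
#' @export
traf6_complex_peak <- function(network, lps = NULL, tirap = NULL,
                               t_max = 360) {
  overrides <- c(
    if (!is.null(lps)) c(LPS = lps),
    if (!is.null(tirap)) c(TIRAP = tirap)
  )
  traj <- simulate_network(network, seq(0, t_max, by = 1),
    overrides = overrides
  )
  net <- attr(traj, "network")
  obs <- default_observables(net)
  total <- observe(traj, obs[obs$pulldown == "TRAF6_complex", ]) |>
    dplyr::summarise(total = sum(.data$amount_au), .by = "time_min")
  peak <- which.max(total$total)
  pools <- myddosome_pools(net, traj, components = c("TIRAP", "MyD88"))
  tibble::tibble(
    peak_time_min = total$time_min[peak],
    tirap_in_myddosome = pools[peak, "TIRAP"],
    myd88_tirap_ratio = pools[peak, "MyD88"] / pools[peak, "TIRAP"]
  )
}

#' Scan the TIRAP initial level
#'
#' How the TIRAP amount in the Myddosome at the TRAF6-complex peak, and the
#' MyD88:TIRAP ratio there, change with the initial TIRAP level at fixed LPS.
#' Higher TIRAP availability recruits more TIRAP and lowers the degree of
#' MyD88 higher-order assembly.
#'
#' @param network A `reaction_network`.
#' @param tirap_grid Positive initial TIRAP amounts (A.U.).
#' @param lps LPS stimulation strength (A.U.); `NULL` keeps the default.
#' @return Tibble with columns `tirap_initial`, `peak_time_min`,
#'   `tirap_in_myddosome`, `myd88_tirap_ratio`.
#' @examples
#' \donttest{
#' tirap_scan(build_model2(), tirap_grid = 10^seq(1, 3, by = 1))
#' }
#' @export
tirap_scan <- function(network, tirap_grid, lps = NULL) {
  if (!length(tirap_grid) || any(tirap_grid <= 0)) {
    stop("tirap_grid must be non-empty and positive", call. = FALSE)
  }
  purrr::map(tirap_grid, function(ti) {
    traf6_complex_peak(network, lps = lps, tirap = ti)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(tirap_initial = tirap_grid, .before = 1)
}

#' LPS scan of Myddosome TIRAP content and MyD88:TIRAP ratio
#'
#' The two response curves whose joint behavior defines the assembly phases:
#' the amount of TIRAP recruited into the Myddosome rises with LPS (a
#' saturating sigmoid, measured as the total recruited over the horizon, the
#' same accounting as [complex_distribution()]) while the MyD88:TIRAP
#' higher-order ratio falls. The ratio is read at a fixed time because the
#' assembly peak drifts with dose; 120 min (default) is the latest published
#' reading time and spans the full published range (about 7-fold at weak
#' stimulation down to near-dimer at strong).
#'
#' @param network A `reaction_network`.
#' @param lps_grid Positive LPS values, ideally covering several decades.
#' @param ratio_time Time (minutes) at which the MyD88:TIRAP pool ratio is
#'   read.
#' @param horizon_h Horizon (hours) for the recruited-TIRAP accounting.
#' @return Tibble with columns `lps`, `tirap_in_myddosome` (A.U. recruited),
#'   `myd88_tirap_ratio`.
#' @export
assembly_scan <- function(network, lps_grid = 10^seq(0, 4, by = 0.5),
                          ratio_time = 120, horizon_h = 10) {
  if (!length(lps_grid) || any(lps_grid <= 0)) {
    stop("lps_grid must be non-empty and positive", call. = FALSE)
  }
  rec <- recruitment_map(network)
  tirap_rx <- rec$reaction[rec$component == "TIRAP" &
    rec$branch == "myddosome"]
  purrr::map(lps_grid, function(l) {
    traj <- simulate_network(network,
      times = c(0, ratio_time, horizon_h * 60),
      overrides = c(LPS = l), fluxes = TRUE
    )
    pools <- myddosome_pools(network, traj,
      components = c("TIRAP", "MyD88")
    )
    recruited <- sum(vapply(
      tirap_rx,
      function(j) traj[[paste0("flux_", j)]][nrow(traj)], 0
    ))
    tibble::tibble(
      lps = l,
      tirap_in_myddosome = recruited,
      myd88_tirap_ratio = pools[2, "MyD88"] / pools[2, "TIRAP"]
    )
  }) |>
    dplyr::bind_rows()
}

#' Classify the MyD88 higher-order assembly phases
#'
#' Partitions the scanned LPS axis into three contiguous regimes from the
#' TIRAP-in-Myddosome response curve: phase I (weak stimulation, TIRAP low,
#' MyD88:TIRAP ratio at its high plateau -- long MyD88 chains), phase III
#' (strong stimulation, TIRAP at its high plateau, ratio low -- short
#' chains), and phase II in between. Boundaries are placed at 10% and 90% of
#' the TIRAP curve's dynamic range; the published phase diagram is drawn
#' qualitatively, so the cutoffs are a declared convention of this package.
#'
#' @param scan Output of [assembly_scan()]: requires columns `lps`,
#'   `tirap_in_myddosome`, `myd88_tirap_ratio`, spanning at least three
#'   decades of LPS.
#' @return Tibble with one row per phase: `phase` (`"I"`, `"II"`, `"III"`),
#'   `lps_min`, `lps_max`, `n_points`, `mean_ratio`.
#' @export
classify_phases <- function(scan) {
  req <- c("lps", "tirap_in_myddosome", "myd88_tirap_ratio")
  stopifnot(all(req %in% names(scan)))
  scan <- dplyr::arrange(scan, .data$lps)
  if (log10(max(scan$lps) / min(scan$lps)) < 3) {
    stop("LPS scan must cover at least three decades", call. = FALSE)
  }
  tir <- scan$tirap_in_myddosome
  rng <- max(tir) - min(tir)
  if (rng <= 1e-9 * max(abs(tir), 1)) {
    stop("classification refused: TIRAP response curve is constant",
      call. = FALSE
    )
  }
  if (any(diff(tir) < -1e-6 * rng)) {
    stop(
      "classification refused: TIRAP response is not monotone in LPS ",
      "(max decrease ", signif(-min(diff(tir)), 3), " A.U.)",
      call. = FALSE
    )
  }
  lo <- min(tir) + 0.1 * rng
  hi <- min(tir) + 0.9 * rng
  phase <- dplyr::case_when(
    tir <= lo ~ "I",
    tir >= hi ~ "III",
    .default = "II"
  )
  dplyr::summarise(
    tibble::tibble(
      phase = phase, lps = scan$lps,
      ratio = scan$myd88_tirap_ratio
    ),
    lps_min = min(.data$lps), lps_max = max(.data$lps),
    n_points = dplyr::n(), mean_ratio = mean(.data$ratio),
    .by = "phase"
  )
}
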