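obs_components <- list(
  MyD88_complex = c("TIRAP", "IRAK1", "IRAK4", "TRAF6"),
  TRAF6_complex = c("TIRAP", "MyD88", "IRAK1", "IRAK4")
)

#' Default pulldown observable mapping
#'
#' Maps each (pulldown, component) pair of the SWATH-MS stoichiometry table
#' shape to the model species whose amounts sum to that readout. Each
#' pulldown carries the four non-bait components (the bait itself, MyD88 or
#' TRAF6, is not a plotted series).
#'
#' For Model 1, every component maps to its Myddosome pool (`X_bind` plus the
#' catalytic intermediates led by it, see [species_pool()]) in both
#' pulldowns, so the two readouts of a component are identical series. For
#' Model 2 the MyD88-complex readout of a component sums its Myddosome pool,
#' its TIRAP-independent pool (`X_binda`, where the branch defines one) and
#' its MyD88-TRAF6 pool (`X_BIND`, where defined), while the TRAF6-complex
#' readout sums only the Myddosome and MyD88-TRAF6 pools: the
#' TIRAP-independent complex contains no TRAF6 and therefore never
#' co-purifies with it.
#'
#' @param model Either a `reaction_network` built by [build_model1()] /
#'   [build_model2()] or the string `"model1"` / `"model2"`.
#' @return Tibble (class `lps_observables`) with columns `pulldown`,
#'   `component`, `species` (list-column of species names).
#' @examples
#' default_observables("model2")
#' @export
default_observables <- function(model) {
  if (inherits(model, "reaction_network")) {
    network <- model
    model_id <- network$model_id
  } else {
    model_id <- model
    network <- switch(model_id,
      model1 = build_model1(),
      model2 = build_model2(),
      stop("unknown model_id: ", model_id, call. = FALSE)
    )
  }
  if (is.null(model_id) || !model_id %in% c("model1", "model2")) {
    stop("unknown model_id: ", format(model_id), call. = FALSE)
  }
  grid <- tibble::tibble(
    pulldown = rep(names(obs_components), lengths(obs_components)),
    component = unlist(obs_components, use.names = FALSE)
  )
  pools <- function(comp, pulldown) {
    bases <- paste0(comp, "_bind")
    if (model_id == "model2") {
      if (pulldown == "MyD88_complex") {
        bases <- c(bases, paste0(comp, "_binda"))
      }
      bases <- c(bases, paste0(comp, "_BIND"))
    }
    sp <- unlist(lapply(bases, function(b) species_pool(network, b)))
    unique(sp)
  }
  grid$species <- purrr::map2(grid$component, grid$pulldown, pools)
  if (any(lengths(grid$species) == 0)) {
    stop("component with empty species mapping", call. = FALSE)
  }
  structure(grid, class = c("lps_observables", class(grid)))
}

#' Evaluate pulldown observables along a trajectory
#'
#' Sums, at every trajectory time, the species of each (pulldown, component)
#' readout. The result has the shape of the SWATH-MS stoichiometry tables:
#' one series per component per pulldown.
#'
#' @param trajectory An `lps_trajectory` from [simulate_network()].
#' @param observables Observable mapping, e.g. from [default_observables()];
#'   defaults to the mapping of the trajectory's network.
#' @return Tibble with columns `pulldown`, `component`, `time_min`,
#'   `amount_au`.
#' @examples
#' build_model2() |>
#'   simulate_network(times = c(0, 5, 15, 30, 45, 60, 90, 120, 240, 360)) |>
#'   observe()
#' @export
observe <- function(trajectory, observables = NULL) {
  network <- attr(trajectory, "network")
  if (is.null(observables)) observables <- default_observables(network)
  missing <- setdiff(unlist(observables$species), network$species$name)
  if (length(missing)) {
    stop(
      "observable references unknown species: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  rows <- purrr::pmap(observables, function(pulldown, component, species) {
    tibble::tibble(
      pulldown = pulldown, component = component,
      time_min = trajectory$time_min,
      amount_au = rowSums(tibble::as_tibble(trajectory)[, species,
        drop = FALSE
      ])
    )
  })
  dplyr::bind_rows(rows)
}
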