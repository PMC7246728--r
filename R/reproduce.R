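#' Recompute the headline quantities of the assembly analysis
#'
#' Runs the full desk-scale analysis pipeline on the shipped Model 2 and
#' returns the quantities the model is known for: the branch distribution
#' percentages at reference LPS doses and the MyD88:TIRAP higher-order
#' assembly ratios at reference times. Everything is deterministic ODE
#' output; `seed` only affects nothing here and is accepted for interface
#' symmetry with the stochastic experiments.
#'
#' @param seed Unused placeholder for interface consistency.
#' @return Tibble with columns `quantity`, `value`, `units`, `n` (the
#'   problem size behind the number: reactions simulated).
#' @examples
#' \donttest{
#' reproduce_headline_results()
#' }
#' @export
reproduce_headline_results <- function(seed = 1) {
  m2 <- build_model2()
  n_rx <- nrow(m2$reactions)
  d100 <- complex_distribution(m2, lps = 100)
  d1e4 <- complex_distribution(m2, lps = 1e4)
  weak_grid <- 10^seq(0, 1, by = 0.5)
  weak <- purrr::map(
    weak_grid,
    function(l) complex_distribution(m2, lps = l)
  ) |> dplyr::bind_rows()
  irak1_weak <- mean(weak$pct_myddosome[weak$component == "IRAK1"])
  pk <- traf6_complex_peak(m2)
  strong <- stoichiometry_ratios(m2, lps = 1e4, times = c(30, 120))
  weak_ratio <- stoichiometry_ratios(m2, lps = 1, times = 30)
  val <- function(d, comp, col) d[[col]][d$component == comp]
  rat <- function(r, comp, t) {
    r$ratio_to_tirap[r$component == comp & r$time_min == t]
  }
  tibble::tribble(
    ~quantity, ~value, ~units,
    "model1_reactions", nrow(build_model1()$reactions), "count",
    "model2_reactions", n_rx, "count",
    "tlr4_pct_myddosome_lps100", val(d100, "TLR4", "pct_myddosome"), "%",
    "myd88_pct_myddosome_lps100", val(d100, "MyD88", "pct_myddosome"), "%",
    "irak4_pct_independent_lps100", val(d100, "IRAK4", "pct_independent"), "%",
    "irak1_pct_myddosome_weak_lps", irak1_weak, "%",
    "myd88_tirap_ratio_at_traf6_peak", pk$myd88_tirap_ratio, "fold",
    "myd88_tirap_ratio_30min_lps1e4", rat(strong, "MyD88", 30), "fold",
    "myd88_tirap_ratio_120min_lps1e4", rat(strong, "MyD88", 120), "fold",
    "myd88_tirap_ratio_30min_lps1", rat(weak_ratio, "MyD88", 30), "fold",
    "irak4_tirap_ratio_30min_lps1", rat(weak_ratio, "IRAK4", 30), "fold",
    "traf6_pct_myddosome_lps1e4", val(d1e4, "TRAF6", "pct_myddosome"), "%"
  ) |>
    dplyr::mutate(n = n_rx)
}
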