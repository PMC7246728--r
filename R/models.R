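model_path <- function(file) {
  system.file("extdata", file, package = "myddosome", mustWork = TRUE)
}

#' The published TLR4 complex assembly models
#'
#' `build_model1()` constructs the Myddosome-only assembly model: 17
#' mass-action reactions describing LPS engagement of TLR4 and the sequential
#' recruitment of TIRAP, MyD88, IRAK1/4 and TRAF6, each recruitment written as
#' an association step (bimolecular, rate constant in per A.U. per second)
#' followed by a release step (the catalyst is regenerated and the recruit is
#' left in its bound pool), plus five first-order drop steps that disassemble
#' the bound pools. Initial amounts (A.U.): LPS 500, TLR4 20, TIRAP 100,
#' MyD88 1000, IRAK1 100, IRAK4 100, TRAF6 100; every intermediate and
#' bound/dropped pool starts at 0.
#'
#' `build_model2()` extends the topology with two branches: a TIRAP-independent
#' MyD88 activation complex in which TLR4_bind recruits MyD88 and then IRAK1/4
#' directly (the `_binda`/`_dropa` species, reactions 30-37, without TRAF6),
#' and a post-Myddosome MyD88-TRAF6 complex assembled from dropped components
#' (the `_BIND`/`_DROP` species, reactions 18-29). Reactions 1-17 share Model
#' 1's topology with five re-fitted rate constants. 37 reactions in total.
#'
#' Both networks are read from the tab-separated reaction tables shipped under
#' `inst/extdata`, so the models are data, not code.
#'
#' @return A `reaction_network` with `model_id` `"model1"` or `"model2"`.
#' @examples
#' m1 <- build_model1()
#' nrow(m1$reactions) # 17
#' @export
build_model1 <- function() {
  read_network(model_path("model1_reactions.tsv"),
    model_path("model1_species.tsv"),
    model_id = "model1"
  )
}

#' @rdname build_model1
#' @export
build_model2 <- function() {
  read_network(model_path("model2_reactions.tsv"),
    model_path("model2_species.tsv"),
    model_id = "model2"
  )
}
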