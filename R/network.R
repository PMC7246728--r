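#' Protein labels tracked by the TLR4 assembly models
#'
#' The seven proteins whose total amount is conserved by every reaction of the
#' shipped models. Species names are underscore-joined tokens, so a species
#' contains a protein exactly when the protein's label appears among its
#' tokens (e.g. `TLR4_bind_TIRAP` contains one TLR4 and one TIRAP).
#'
#' @format Character vector of length 7.
#' @export
tlr4_proteins <- c("LPS", "TLR4", "TIRAP", "MyD88", "IRAK1", "IRAK4", "TRAF6")

split_side <- function(x) {
  out <- lapply(strsplit(x, "+", fixed = TRUE), trimws)
  lapply(out, function(s) s[nzchar(s)])
}

join_side <- function(x) vapply(x, paste, "", collapse = " + ")

#' Construct a mass-action reaction network
#'
#' Builds a validated reaction network from a table of reactions and a table
#' of initial amounts. Species that appear in reactions but not in the species
#' table are added with an initial amount of 0 (they are assembly
#' intermediates or product pools). The stoichiometric matrix is computed once
#' at construction: its column j is the product multiset minus the reactant
#' multiset of reaction j.
#'
#' @param reactions Data frame with columns `index` (1-based integer),
#'   `reactants` and `products` (strings such as `"A + B"`, one or two species
#'   per side), and `rate_constant` (per second for unimolecular steps, per
#'   A.U. per second for bimolecular steps; amounts are in arbitrary units).
#' @param species Data frame with columns `name` and `initial_amount` (A.U.,
#'   nonnegative). Only species with nonzero initial amounts need to be
#'   listed.
#' @param model_id Optional identifier string (e.g. `"model1"`) attached to
#'   the network.
#'
#' @return An object of class `reaction_network`: a list with elements
#'   `species` (tibble: `name`, `initial_amount`), `reactions` (tibble:
#'   `index`, `reactants`, `products` as list-columns of character vectors,
#'   `rate_constant`), `stoich` (integer matrix, species x reactions) and
#'   `model_id`.
#'
#' @examples
#' net <- reaction_network(
#'   data.frame(index = 1, reactants = "A + B", products = "C",
#'              rate_constant = 1e-3),
#'   data.frame(name = c("A", "B"), initial_amount = c(10, 5))
#' )
#' stoichiometric_matrix(net)
#' @export
reaction_network <- function(reactions, species, model_id = NULL) {
  reactions <- tibble::as_tibble(reactions)
  species <- tibble::as_tibble(species)
  stopifnot(
    all(c("index", "reactants", "products", "rate_constant") %in% names(reactions)),
    all(c("name", "initial_amount") %in% names(species))
  )
  if (anyDuplicated(species$name)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (any(species$initial_amount < 0)) {
    stop("initial amounts must be nonnegative", call. = FALSE)
  }
  if (any(reactions$rate_constant < 0)) {
    stop("rate constants must be nonnegative", call. = FALSE)
  }
  if (is.character(reactions$reactants)) {
    reactions$reactants <- split_side(reactions$reactants)
  }
  if (is.character(reactions$products)) {
    reactions$products <- split_side(reactions$products)
  }
  n_side <- function(col) lengths(reactions[[col]])
  if (nrow(reactions) && (any(n_side("reactants") < 1 | n_side("reactants") > 2) ||
    any(n_side("products") < 1 | n_side("products") > 2))) {
    stop("each reaction must have 1 or 2 reactants and 1 or 2 products",
      call. = FALSE
    )
  }
  all_names <- unique(c(
    species$name,
    unlist(reactions$reactants), unlist(reactions$products)
  ))
  extra <- setdiff(all_names, species$name)
  species <- dplyr::bind_rows(
    species,
    tibble::tibble(name = extra, initial_amount = 0)
  )
  m <- nrow(species)
  n <- nrow(reactions)
  stoich <- matrix(0L, m, n, dimnames = list(species$name, reactions$index))
  for (j in seq_len(n)) {
    for (s in reactions$reactants[[j]]) stoich[s, j] <- stoich[s, j] - 1L
    for (s in reactions$products[[j]]) stoich[s, j] <- stoich[s, j] + 1L
  }
  net <- structure(
    list(
      species = species, reactions = reactions,
      stoich = stoich, model_id = model_id
    ),
    class = "reaction_network"
  )
  validate_conservation(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(
    "<reaction_network", if (!is.null(x$model_id)) paste0("'", x$model_id, "'"),
    ">\n"
  )
  cat(
    " ", nrow(x$species), "species,", nrow(x$reactions), "reactions;",
    sum(x$species$initial_amount > 0), "with nonzero initial amount\n"
  )
  invisible(x)
}

#' Stoichiometric matrix of a reaction network
#'
#' Returns the integer matrix v (species x reactions) of the ODE system
#' dx_i/dt = sum_j v_ij q_j, where q_j is the mass-action rate of reaction j.
#' The matrix is computed at network construction and stored, not recomputed.
#'
#' @param network A `reaction_network`.
#' @return Integer matrix with species names as row names.
#' @export
stoichiometric_matrix <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  network$stoich
}

species_label_counts <- function(network, labels = tlr4_proteins) {
  toks <- strsplit(network$species$name, "_", fixed = TRUE)
  counts <- vapply(
    labels,
    function(l) vapply(toks, function(tt) sum(tt == l), 0L),
    integer(nrow(network$species))
  )
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  rownames(counts) <- network$species$name
  counts
}

validate_conservation <- function(network, labels = tlr4_proteins) {
  if (nrow(network$reactions) == 0) {
    return(invisible(network))
  }
  counts <- species_label_counts(network, labels)
  present <- labels[colSums(counts) > 0]
  bad <- present[vapply(
    present,
    function(l) any(crossprod(counts[, l], network$stoich) != 0), TRUE
  )]
  if (length(bad)) {
    stop(
      "protein total not conserved by the reaction table for: ",
      paste(bad, collapse = ", "),
      " (a reaction is probably mistranscribed)",
      call. = FALSE
    )
  }
  invisible(network)
}

#' Conservation laws of a reaction network
#'
#' One law per protein label present in the network: the indicator vector of
#' the species containing that protein lies in the left null space of the
#' stoichiometric matrix, so the summed amount over `members` is invariant
#' along any trajectory. Construction fails (with the offending label named)
#' if a label's indicator is not conserved, which indicates a mistranscribed
#' reaction.
#'
#' @param network A `reaction_network`.
#' @param labels Protein labels to check; defaults to [tlr4_proteins].
#' @return Tibble with columns `protein`, `members` (list-column of species
#'   names) and `total` (the conserved amount, from initial amounts). Empty
#'   networks give an empty tibble.
#' @examples
#' conservation_laws(build_model1())
#' @export
conservation_laws <- function(network, labels = tlr4_proteins) {
  stopifnot(inherits(network, "reaction_network"))
  if (nrow(network$reactions) == 0 || nrow(network$species) == 0) {
    return(tibble::tibble(
      protein = character(), members = list(),
      total = numeric()
    ))
  }
  counts <- species_label_counts(network, labels)
  present <- labels[colSums(counts) > 0]
  validate_conservation(network, present)
  x0 <- stats::setNames(network$species$initial_amount, network$species$name)
  tibble::tibble(
    protein = present,
    members = lapply(present, function(l) rownames(counts)[counts[, l] > 0]),
    total = vapply(present, function(l) sum(counts[, l] * x0), 0)
  )
}

#' Species pool of a bound form
#'
#' The pulldown-relevant pool of a bound species: the species itself plus the
#' transient catalytic intermediates in which it is the leading (catalyst)
#' partner. With the models' naming convention the pool of `X_bind` is every
#' species whose underscore tokens start with the tokens of `X_bind` (e.g.
#' `MyD88_bind`, `MyD88_bind_IRAK1`, `MyD88_bind_IRAK4`), while `MyD88_binda`
#' and its intermediates form a separate pool.
#'
#' @param network A `reaction_network`.
#' @param base Bound-form species name (e.g. `"MyD88_bind"`).
#' @return Character vector of species names (possibly just `base`).
#' @export
species_pool <- function(network, base) {
  stopifnot(inherits(network, "reaction_network"))
  toks <- strsplit(network$species$name, "_", fixed = TRUE)
  bt <- strsplit(base, "_", fixed = TRUE)[[1]]
  hit <- vapply(
    toks,
    function(tt) length(tt) >= length(bt) && all(tt[seq_along(bt)] == bt),
    TRUE
  )
  network$species$name[hit]
}

#' Read / write a reaction network as delimited text
#'
#' Networks are shipped and exchanged as two tab-separated tables: a reaction
#' table (`index`, `reactants`, `products` as `"A + B"` strings,
#' `rate_constant`) and a species table (`name`, `initial_amount`) listing the
#' species with nonzero initial amounts. The round trip is lossless.
#'
#' @param reactions_file,species_file Paths to the two tables.
#' @param model_id Optional identifier attached to the network.
#' @return `read_network()` returns a `reaction_network`;
#'   `write_network()` returns `network` invisibly.
#' @export
read_network <- function(reactions_file, species_file, model_id = NULL) {
  rx <- readr::read_tsv(reactions_file,
    col_types = readr::cols(
      index = readr::col_integer(),
      reactants = readr::col_character(),
      products = readr::col_character(),
      rate_constant = readr::col_double()
    )
  )
  sp <- readr::read_tsv(species_file,
    col_types = readr::cols(
      name = readr::col_character(),
      initial_amount = readr::col_double()
    )
  )
  reaction_network(rx, sp, model_id = model_id)
}

#' @rdname read_network
#' @param network A `reaction_network` to write.
#' @export
write_network <- function(network, reactions_file, species_file) {
  stopifnot(inherits(network, "reaction_network"))
  rx <- dplyr::mutate(network$reactions,
    reactants = join_side(.data$reactants),
    products = join_side(.data$products)
  )
  readr::write_tsv(rx, reactions_file)
  readr::write_tsv(
    dplyr::filter(network$species, .data$initial_amount > 0),
    species_file
  )
  invisible(network)
}

#' Modify rate constants or initial amounts of a network
#'
#' @param network A `reaction_network`.
#' @param rate_constants Named numeric: names are reaction indices (as
#'   characters or integers); values replace the printed rate constants.
#' @param initial_amounts Named numeric: names are species; values replace the
#'   initial amounts (must be nonnegative).
#' @return The modified `reaction_network`.
#' @examples
#' net <- set_network_values(build_model2(), initial_amounts = c(LPS = 100))
#' @export
set_network_values <- function(network, rate_constants = NULL,
                               initial_amounts = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.null(rate_constants)) {
    idx <- match(as.integer(names(rate_constants)), network$reactions$index)
    if (anyNA(idx)) {
      stop("unknown reaction index in rate_constants", call. = FALSE)
    }
    if (any(rate_constants < 0)) {
      stop("rate constants must be nonnegative", call. = FALSE)
    }
    network$reactions$rate_constant[idx] <- unname(rate_constants)
  }
  if (!is.null(initial_amounts)) {
    idx <- match(names(initial_amounts), network$species$name)
    if (anyNA(idx)) {
      stop("unknown species in initial_amounts", call. = FALSE)
    }
    if (any(initial_amounts < 0)) {
      stop("initial amounts must be nonnegative", call. = FALSE)
    }
    network$species$initial_amount[idx] <- unname(initial_amounts)
  }
  network
}

#' Zero the complex-disassembly ("drop") rate constants
#'
#' The drop steps are the first-order conversions of a bound pool into its
#' terminal dropped form (single reactant, single product). This helper sets
#' all their rate constants to 0, which freezes every assembled pool in place.
#'
#' @param network A `reaction_network`.
#' @return The network with drop rate constants set to 0.
#' @export
zero_drop_rates <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  is_drop <- lengths(network$reactions$reactants) == 1 &
    lengths(network$reactions$products) == 1
  network$reactions$rate_constant[is_drop] <- 0
  network
}
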