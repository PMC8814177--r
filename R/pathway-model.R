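#' Define a molecular species
#'
#' @param id short identifier (unique within a model).
#' @param name human-readable name.
#' @param role `"metabolite"` or `"enzyme"`.
#' @param molecular_weight g/mol; determines the sphere radius.
#' @param initial_concentration mmol/l.
#' @param approx flag marking values that are documented approximations
#'   rather than published numbers.
#' @return a one-row data frame.
#' @export
species_spec <- function(id, name = id, role = c("metabolite", "enzyme"),
                         molecular_weight, initial_concentration,
                         approx = FALSE) {
  role <- match.arg(role)
  stopifnot(is.character(id), nchar(id) > 0,
            molecular_weight > 0, initial_concentration >= 0)
  data.frame(id = id, name = name, role = role,
             molecular_weight = molecular_weight,
             initial_concentration = initial_concentration,
             approx = approx, stringsAsFactors = FALSE)
}

#' Define a reaction catalysed by one isoenzyme
#'
#' One `reaction_spec` per isoenzyme: isoenzymes catalysing the same chemistry
#' are separate reactions sharing substrates and products.  A reversible
#' reaction carries one kcat for both directions unless `kcat_reverse` is
#' given.
#'
#' @param id reaction identifier.
#' @param enzyme id of the catalysing enzyme species.
#' @param substrates named integer vector: species id -> stoichiometry.
#' @param products named integer vector: species id -> stoichiometry.
#' @param reversible logical.
#' @param kcat turnover number in 1/s (forward direction).
#' @param kcat_reverse optional reverse-direction turnover number.
#' @param km optional named vector of Michaelis constants (mmol/l) per
#'   substrate; only needed for the specificity-priority binding mode.
#' @param name readable name (used by exclusion-rule pattern matching).
#' @return a list of class `reaction_spec`.
#' @export
reaction_spec <- function(id, enzyme, substrates, products,
                          reversible = FALSE, kcat, kcat_reverse = NULL,
                          km = NULL, name = id) {
  stopifnot(length(substrates) > 0, length(products) > 0,
            !is.null(names(substrates)), !is.null(names(products)))
  if (!is.na(kcat) && kcat <= 0) stop("kcat must be positive in ", id)
  if (any(substrates <= 0) || any(products <= 0) ||
      any(substrates != round(substrates)) || any(products != round(products)))
    stop("stoichiometries must be positive integers in ", id)
  structure(list(id = id, name = name, enzyme = enzyme,
                 substrates = substrates, products = products,
                 reversible = isTRUE(reversible), kcat = kcat,
                 kcat_reverse = kcat_reverse, km = km),
            class = "reaction_spec")
}

#' Assemble a pathway model
#'
#' The complete input of the simulator: species (with weights and initial
#' concentrations), reactions, and the simulated volume.
#'
#' @param species data frame of rows built with [species_spec()].
#' @param reactions list of [reaction_spec()] objects.
#' @param volume litres (default one attolitre).
#' @param provenance free-text source tag (e.g. an SBML id or `"fixture"`).
#' @param validate run [validate_pathway_model()] on the result.
#' @return an object of class `pathway_model`.
#' @export
pathway_model <- function(species, reactions, volume = 1e-18,
                          provenance = "fixture", validate = TRUE) {
  m <- structure(list(species = species, reactions = reactions,
                      volume = volume, provenance = provenance),
                 class = "pathway_model")
  if (validate) validate_pathway_model(m)
  m
}

#' Validate a pathway model
#'
#' Checks id uniqueness, referential integrity of reactions, positivity of
#' weights and kcat, and that catalysts have the enzyme role.
#'
#' @param model a `pathway_model`.
#' @param allow_missing_enzyme tolerate reactions without a catalysing enzyme
#'   (as produced by [parse_sbml()] for transport-like steps before
#'   exclusions are applied).
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_pathway_model <- function(model, allow_missing_enzyme = FALSE) {
  sp <- model$species
  if (anyDuplicated(sp$id)) stop("duplicate species ids: ",
                                 paste(sp$id[duplicated(sp$id)], collapse = ", "))
  if (any(sp$molecular_weight <= 0)) stop("non-positive molecular weight")
  if (any(sp$initial_concentration < 0)) stop("negative initial concentration")
  if (!is.numeric(model$volume) || model$volume <= 0) stop("volume must be positive")
  ids <- sp$id
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  for (r in model$reactions) {
    refs <- c(names(r$substrates), names(r$products))
    miss <- setdiff(refs, ids)
    if (length(miss))
      stop("reaction ", r$id, " references unknown species: ",
           paste(miss, collapse = ", "))
    if (is.na(r$enzyme) || !nzchar(r$enzyme)) {
      if (!allow_missing_enzyme)
        stop("reaction ", r$id, " has no catalysing enzyme")
    } else {
      if (!r$enzyme %in% ids)
        stop("reaction ", r$id, " names unknown enzyme ", r$enzyme)
      if (sp$role[match(r$enzyme, ids)] != "enzyme")
        stop("catalyst ", r$enzyme, " of reaction ", r$id,
             " does not have role 'enzyme'")
      if (r$enzyme %in% refs)
        stop("enzyme ", r$enzyme, " appears among substrates/products of ", r$id)
    }
    if (is.na(r$kcat) || r$kcat <= 0)
      stop("reaction ", r$id, " needs a positive kcat")
  }
  invisible(TRUE)
}

#' Convert a molar concentration to a particle count
#'
#' count = round(c * 1e-3 * N_A * V) for c in mmol/l and V in litres.
#'
#' @param concentration mmol/l.
#' @param volume litres.
#' @return non-negative integer count(s).
#' @examples
#' concentration_to_count(1, 1e-18) # 602 molecules in one attolitre
#' @export
concentration_to_count <- function(concentration, volume) {
  if (any(concentration < 0) || any(volume <= 0))
    stop("concentration must be >= 0 and volume > 0")
  as.integer(round(concentration * 1e-3 * .NA_CONST * volume))
}

#' Convert a particle count to a molar concentration
#'
#' Exact inverse scale of [concentration_to_count()] (mmol/l).
#'
#' @param count number of molecules.
#' @param volume litres.
#' @return concentration in mmol/l.
#' @export
count_to_concentration <- function(count, volume) {
  if (any(count < 0) || any(volume <= 0))
    stop("count must be >= 0 and volume > 0")
  count / (1e-3 * .NA_CONST * volume)
}

#' Initial particle counts of every species in a model
#'
#' @param model a `pathway_model`.
#' @return named integer vector.
#' @export
initial_counts <- function(model) {
  n <- concentration_to_count(model$species$initial_concentration, model$volume)
  names(n) <- model$species$id
  n
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> ", x$provenance, "\n", sep = "")
  cat("  species:  ", nrow(x$species), " (",
      sum(x$species$role == "enzyme"), " enzymes)\n", sep = "")
  cat("  reactions:", length(x$reactions), "\n")
  cat("  volume:   ", format(x$volume), "l -> ",
      sum(initial_counts(x)), "initial molecules\n")
  invisible(x)
}

#' @export
print.reaction_spec <- function(x, ...) {
  arrow <- if (x$reversible) "<->" else "-->"
  lhs <- paste(ifelse(x$substrates > 1, paste0(x$substrates, " "), ""),
               names(x$substrates), sep = "", collapse = " + ")
  rhs <- paste(ifelse(x$products > 1, paste0(x$products, " "), ""),
               names(x$products), sep = "", collapse = " + ")
  cat(sprintf("%s [%s] %s %s %s  kcat=%g/s\n", x$id, x$enzyme, lhs, arrow,
              rhs, x$kcat))
  invisible(x)
}

# net stoichiometry matrix (reactions x species, forward direction)
.stoich_matrices <- function(model) {
  ids <- model$species$id
  R <- length(model$reactions)
  S <- length(ids)
  sub <- matrix(0L, R, S, dimnames = list(NULL, ids))
  prod <- matrix(0L, R, S, dimnames = list(NULL, ids))
  for (i in seq_len(R)) {
    r <- model$reactions[[i]]
    sub[i, names(r$substrates)] <- sub[i, names(r$substrates)] +
      as.integer(r$substrates)
    prod[i, names(r$products)] <- prod[i, names(r$products)] +
      as.integer(r$products)
  }
  list(sub = sub, prod = prod)
}
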