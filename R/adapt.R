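#' Pathway adaptation rules
#'
#' Rules applied when converting a kinetic model into agent-based form.  The
#' defaults reproduce the adaptation of the yeast glycolysis network used
#' throughout this package: bulk reactions with no explicit catalyst pool
#' (adenylate kinase, ATPase, the UDP to UTP conversion, glucose transport)
#' and the fermentation steps (pyruvate decarboxylases PDC1/5/6, alcohol
#' dehydrogenases ADH1/5) are dropped, and the three glycolytic control
#' points (hexokinase/glucokinase, phosphofructokinase, pyruvate kinase) are
#' forced irreversible.
#'
#' Patterns are case-insensitive regular expressions matched against both the
#' reaction id and its name.
#'
#' @param removed_reactions patterns of reactions to delete.
#' @param removed_species ids of species to delete outright.
#' @param forced_irreversible patterns of reactions whose `reversible` flag
#'   is cleared.
#' @return list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(
    removed_reactions = c(
      "adenylate[ _-]?kinase", "\\bADK1?\\b",
      "ATPase",
      "UDP.{0,4}UTP",
      "glucose[ _-]?transport", "\\bHXT\\b",
      "pyruvate[ _-]?decarboxylase", "\\bPDC[156]\\b",
      "alcohol[ _-]?dehydrogenase", "\\bADH[15]\\b"),
    removed_species = character(),
    forced_irreversible = c(
      "hexokinase", "\\bHXK[12]\\b",
      "glucokinase", "\\bGLK1\\b",
      "phosphofructokinase", "\\bPFK[12]?\\b",
      "pyruvate[ _-]?kinase", "\\bCDC19\\b", "\\bPYK[12]?\\b")) {
  structure(list(removed_reactions = removed_reactions,
                 removed_species = removed_species,
                 forced_irreversible = forced_irreversible),
            class = "exclusion_rules")
}

.match_any <- function(patterns, id, name) {
  if (length(patterns) == 0) return(FALSE)
  any(vapply(patterns, function(p)
    grepl(p, id, ignore.case = TRUE) || grepl(p, name, ignore.case = TRUE),
    logical(1)))
}

#' Apply adaptation rules to a pathway model
#'
#' Removes the listed reactions, clears the reversibility of control-point
#' reactions, drops reactions left without a catalysing enzyme, and
#' (optionally) prunes metabolites no longer referenced by any reaction.
#' Idempotent: applying the same rules twice changes nothing further.
#'
#' @param model a `pathway_model`.
#' @param rules an [exclusion_rules()] object; the default is the glycolysis
#'   rule set.
#' @param prune_orphans drop non-enzyme species referenced by no remaining
#'   reaction (reported with a message).
#' @param drop_enzymeless drop reactions that have no catalysing enzyme
#'   (bulk reactions cannot be represented by molecular agents).
#' @return the adapted `pathway_model`.
#' @export
apply_exclusions <- function(model, rules = exclusion_rules(),
                             prune_orphans = TRUE, drop_enzymeless = TRUE) {
  stopifnot(inherits(rules, "exclusion_rules"))
  matched <- logical(length(rules$removed_reactions))
  keep <- vapply(model$reactions, function(r) {
    hit <- .match_any(rules$removed_reactions, r$id, r$name)
    !hit
  }, logical(1))
  for (p in seq_along(rules$removed_reactions)) {
    matched[p] <- any(vapply(model$reactions, function(r)
      .match_any(rules$removed_reactions[p], r$id, r$name), logical(1)))
  }
  if (length(rules$removed_reactions) && !any(matched) &&
      length(model$reactions))
    warning("no reaction matched any removal pattern")
  reactions <- model$reactions[keep]
  if (drop_enzymeless) {
    has_enz <- vapply(reactions, function(r)
      !is.na(r$enzyme) && nzchar(r$enzyme), logical(1))
    if (any(!has_enz))
      message("dropping ", sum(!has_enz), " reaction(s) without a catalyst: ",
              paste(vapply(reactions[!has_enz], `[[`, "", "id"),
                    collapse = ", "))
    reactions <- reactions[has_enz]
  }
  reactions <- lapply(reactions, function(r) {
    if (r$reversible && .match_any(rules$forced_irreversible, r$id, r$name))
      r$reversible <- FALSE
    r
  })
  species <- model$species[!model$species$id %in% rules$removed_species, ,
                           drop = FALSE]
  if (prune_orphans) {
    used <- unique(unlist(lapply(reactions, function(r)
      c(names(r$substrates), names(r$products), r$enzyme))))
    orphan <- !(species$id %in% used) & species$role != "enzyme"
    if (any(orphan))
      message("pruning ", sum(orphan), " orphan species: ",
              paste(species$id[orphan], collapse = ", "))
    species <- species[!orphan, , drop = FALSE]
  }
  rownames(species) <- NULL
  out <- pathway_model(species, reactions, volume = model$volume,
                       provenance = model$provenance, validate = FALSE)
  validate_pathway_model(out, allow_missing_enzyme = !drop_enzymeless)
  out
}

#' Rescale initial concentrations below a cap
#'
#' Proportional scaling that keeps every species representable by at least
#' one particle at the model volume.  All concentrations are divided by
#' `max(1, max_c / cap * (1 + eps))` so the largest lands strictly below the
#' cap; any positive concentration whose particle count would then round to
#' zero is floored to the concentration of exactly one particle.  The map is
#' monotone non-decreasing, so the ordering of species concentrations is
#' preserved.
#'
#' @param model a `pathway_model`.
#' @param cap upper bound in mmol/l (exclusive).
#' @return the rescaled model.
#' @export
scale_concentrations <- function(model, cap = 1.0) {
  stopifnot(cap > 0)
  conc <- model$species$initial_concentration
  one_particle <- count_to_concentration(1, model$volume)
  if (one_particle >= cap)
    stop("volume ", format(model$volume), " l cannot represent one particle ",
         "below the cap of ", cap, " mmol/l: offending species: ",
         paste(model$species$id[conc > 0], collapse = ", "))
  f <- max(1, max(conc) / cap * (1 + 1e-6))
  scaled <- conc / f
  floor_up <- scaled > 0 &
    concentration_to_count(scaled, model$volume) < 1
  scaled[floor_up] <- one_particle
  model$species$initial_concentration <- scaled
  model
}
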