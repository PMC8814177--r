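#' Perception-sphere binding model
#'
#' A single perception distance `d` applies to the whole simulation (one
#' type of radius per modelled system).  An enzyme's perception sphere has
#' radius (enzyme radius + d); a cognate metabolite whose surface-to-surface
#' separation `s` lies within `d` is bound with probability `p(s)`:
#'
#' * `"inv_cube"` (default): p = 1 for s <= `contact_distance`, then
#'   (contact_distance/s)^3, truncated at `d`.  The cubic decay mirrors the
#'   1/r^3 shape of a resonant long-range electrodynamic potential, while
#'   keeping certainty of binding at van der Waals contact range.
#' * `"uniform"`: p = 1 anywhere inside the perception sphere.
#' * `"inv_six"`: like `inv_cube` with a sixth-power (van der Waals-like)
#'   decay.
#'
#' In `"random"` mode perceived candidates are tried in uniformly random
#' order; `"specificity"` mode sorts them by the specificity constant
#' kcat/Km first and requires Km values in the model.
#'
#' @param distance perception distance d in Angstrom (5, 10 and 300 are the
#'   regimes of interest).
#' @param law name of the distance -> probability law.
#' @param contact_distance s0 below which binding is certain (Angstrom).
#' @param mode candidate ordering.
#' @return list of class `binding_model`.
#' @export
binding_model <- function(distance, law = c("inv_cube", "uniform", "inv_six"),
                          contact_distance = 5,
                          mode = c("random", "specificity")) {
  law <- match.arg(law)
  mode <- match.arg(mode)
  stopifnot(distance >= 0, contact_distance > 0)
  structure(list(distance = distance, law = law,
                 contact_distance = contact_distance, mode = mode),
            class = "binding_model")
}

#' Binding probability at a given separation
#'
#' Evaluates the distance -> probability law of a [binding_model()]:
#' 1 within the contact distance, non-increasing beyond it, 0 outside the
#' perception distance.
#'
#' @param s surface-to-surface separation(s), Angstrom.
#' @param binding a `binding_model`.
#' @return probabilities in `[0, 1]`.
#' @export
binding_probability <- function(s, binding) {
  stopifnot(inherits(binding, "binding_model"))
  s0 <- binding$contact_distance
  p <- switch(binding$law,
              uniform = rep(1, length(s)),
              inv_cube = ifelse(s <= s0, 1, pmin(1, (s0 / s)^3)),
              inv_six = ifelse(s <= s0, 1, pmin(1, (s0 / s)^6)))
  p[s > binding$distance] <- 0
  p[s < 0] <- 1
  p
}

#' Perception radius of an enzyme
#'
#' The perception sphere's radius: enzyme radius plus the perception
#' distance.
#'
#' @param enzyme_radius Angstrom.
#' @param distance perception distance d, Angstrom.
#' @return radius in Angstrom.
#' @export
perception_radius <- function(enzyme_radius, distance) {
  stopifnot(all(enzyme_radius > 0), all(distance >= 0))
  enzyme_radius + distance
}

.law_code <- function(law) {
  match(law, c("uniform", "inv_cube", "inv_six")) - 1L
}
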