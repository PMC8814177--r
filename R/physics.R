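#' Environment parameters for a simulation
#'
#' The cytoplasm is represented as a cube with reflecting walls.  Defaults
#' reproduce a 1-attolitre cube (side 1000 Angstrom) of water-like cytosol at
#' room temperature, advanced in ticks of 1e-4 s.
#'
#' @param temperature kelvin.
#' @param viscosity pascal-second.
#' @param tick tick length in seconds.
#' @param side box side in Angstrom.
#' @return list of class `environment_params`; `volume` (litres) is derived
#'   from the side length.
#' @export
environment_params <- function(temperature = 298.15, viscosity = 0.0011,
                               tick = 1e-4, side = 1000) {
  stopifnot(temperature > 0, viscosity > 0, tick > 0, side > 0)
  structure(list(
    temperature = temperature,
    viscosity = viscosity,
    tick = tick,
    side = side,
    volume = (side * 1e-10)^3 * 1e3
  ), class = "environment_params")
}

#' Sphere radius from molecular weight
#'
#' Every simulated molecule is a sphere whose volume is its molar volume
#' (partial specific volume times molecular weight) divided by the Avogadro
#' number: r = (3 v M / (4 pi N_A))^(1/3).
#'
#' @param mass molecular weight in g/mol.
#' @param v_bar partial specific volume in cm^3/g.
#' @return radius in Angstrom.
#' @examples
#' radius_from_mass(54000) # about 25 Angstrom
#' @export
radius_from_mass <- function(mass, v_bar = 0.73) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("molecular weight must be positive")
  vol_cm3 <- v_bar * mass / .NA_CONST        # cm^3 per molecule
  r_cm <- (3 * vol_cm3 / (4 * pi))^(1 / 3)
  r_cm * 1e8                                  # cm -> Angstrom
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (6 pi eta r) for a sphere of radius r.
#'
#' @param radius sphere radius in Angstrom.
#' @param temperature kelvin.
#' @param viscosity pascal-second.
#' @return diffusion coefficient in m^2/s.
#' @export
diffusion_coefficient <- function(radius, temperature = 298.15,
                                  viscosity = 0.0011) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive")
  .KB * temperature / (6 * pi * viscosity * radius * 1e-10)
}

#' Per-tick step length from the mean squared displacement law
#'
#' The engine moves each molecule by a fixed modulus per tick, obtained from
#' <x^2> = 2 D t.  `msd` = "3d" switches to the three-dimensional form
#' sqrt(6 D t) for sensitivity studies.
#'
#' @param D diffusion coefficient in m^2/s.
#' @param tick tick length in seconds.
#' @param msd which displacement law to use for the step modulus.
#' @return step length in Angstrom.
#' @export
step_length <- function(D, tick = 1e-4, msd = c("1d", "3d")) {
  msd <- match.arg(msd)
  if (any(!is.finite(D)) || any(D < 0)) stop("D must be non-negative")
  stopifnot(tick > 0)
  k <- if (msd == "1d") 2 else 6
  sqrt(k * D * tick) * 1e10
}

#' Isotropic random unit vectors
#'
#' Uniform directions on the sphere: cos(theta) uniform on \[-1, 1\], phi
#' uniform on \[0, 2 pi).
#'
#' @param n number of draws.
#' @return an n x 3 matrix of unit vectors.
#' @export
random_unit_vector <- function(n = 1) {
  ct <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(x = st * cos(ph), y = st * sin(ph), z = ct)
}

#' Per-species step length with paper-default environment
#'
#' Convenience composition radius -> diffusion coefficient -> step length.
#'
#' @param mass molecular weight in g/mol.
#' @param env an [environment_params()] object.
#' @param v_bar partial specific volume in cm^3/g.
#' @param msd displacement law, see [step_length()].
#' @return step length in Angstrom.
#' @export
species_step_length <- function(mass, env = environment_params(),
                                v_bar = 0.73, msd = "1d") {
  r <- radius_from_mass(mass, v_bar)
  D <- diffusion_coefficient(r, env$temperature, env$viscosity)
  step_length(D, env$tick, msd)
}

# step-length coefficient A such that L(r) = A / sqrt(r_Angstrom);
# used by the engine to rescale complex mobility as complexes grow
.step_coefficient <- function(env, msd = "1d") {
  k <- if (msd == "1d") 2 else 6
  sqrt(k * env$tick * .KB * env$temperature /
         (6 * pi * env$viscosity * 1e-10)) * 1e10
}

#' Free-diffusion random walk in unbounded space
#'
#' Test harness for the displacement statistics: `n_replicas` independent
#' walkers take `n_ticks` steps of fixed modulus `step` in isotropic random
#' directions, with no box and no collisions.  The expected mean squared
#' displacement after k ticks is k * step^2 (equivalently 2 D t when the step
#' comes from [step_length()]).
#'
#' @param n_replicas number of independent walkers.
#' @param n_ticks number of ticks.
#' @param step step modulus (any length unit; the MSD comes back squared).
#' @return numeric vector of length `n_ticks`: empirical MSD after each tick.
#' @export
free_diffusion_msd <- function(n_replicas, n_ticks, step) {
  stopifnot(n_replicas >= 1, n_ticks >= 1, step >= 0)
  u <- random_unit_vector(n_replicas * n_ticks) * step
  msd <- numeric(n_ticks)
  xs <- matrix(u[, 1], nrow = n_ticks)
  ys <- matrix(u[, 2], nrow = n_ticks)
  zs <- matrix(u[, 3], nrow = n_ticks)
  xs <- apply(xs, 2, cumsum)
  ys <- apply(ys, 2, cumsum)
  zs <- apply(zs, 2, cumsum)
  rowMeans(xs^2 + ys^2 + zs^2)
}
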