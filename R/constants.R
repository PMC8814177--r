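#' Physical constants used by the simulator
#'
#' CODATA values for the Boltzmann constant and the Avogadro number, together
#' with the default partial specific volume of a protein in solution
#' (0.73 cm^3/g), which converts molecular weight into an equivalent sphere
#' radius for every simulated molecule.
#'
#' @param v_bar partial specific volume in cm^3/g; the 0.73 default is the
#'   textbook average for globular proteins and is applied to metabolites as
#'   well, since every molecule is modelled as a sphere derived from its
#'   weight.
#' @return a list with `k_B` (J/K), `N_A` (1/mol) and `v_bar` (cm^3/g).
#' @export
physical_constants <- function(v_bar = 0.73) {
  stopifnot(is.numeric(v_bar), v_bar > 0)
  list(k_B = 1.380649e-23, N_A = 6.02214076e23, v_bar = v_bar)
}

.KB <- 1.380649e-23
.NA_CONST <- 6.02214076e23
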