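# shared helpers for building tiny inputs in code

# minimal SBML document (level 2) with optional extras, returned as a file
write_test_sbml <- function(path,
                            glucose_conc = 6.28,
                            enzyme_conc = 0.02,
                            with_reactions = TRUE,
                            with_kcat = TRUE,
                            with_transport = FALSE) {
  kinetic <- if (with_kcat) paste0(
    '      <kineticLaw>\n',
    '        <listOfParameters>\n',
    '          <parameter id="kcat" value="150"/>\n',
    '        </listOfParameters>\n',
    '      </kineticLaw>\n') else ""
  reactions <- if (!with_reactions) "" else paste0(
    '  <listOfReactions>\n',
    '    <reaction id="R_HXK" name="hexokinase" reversible="true">\n',
    '      <listOfReactants>\n',
    '        <speciesReference species="GLC" stoichiometry="1"/>\n',
    '      </listOfReactants>\n',
    '      <listOfProducts>\n',
    '        <speciesReference species="G6P" stoichiometry="1"/>\n',
    '      </listOfProducts>\n',
    '      <listOfModifiers>\n',
    '        <modifierSpeciesReference species="HXK1"/>\n',
    '      </listOfModifiers>\n',
    kinetic,
    '    </reaction>\n',
    if (with_transport) paste0(
      '    <reaction id="R_GLT" name="glucose transport" reversible="true">\n',
      '      <listOfReactants>\n',
      '        <speciesReference species="GLC_e" stoichiometry="1"/>\n',
      '      </listOfReactants>\n',
      '      <listOfProducts>\n',
      '        <speciesReference species="GLC" stoichiometry="1"/>\n',
      '      </listOfProducts>\n',
      '      <kineticLaw><listOfParameters>\n',
      '        <parameter id="kcat" value="10"/>\n',
      '      </listOfParameters></kineticLaw>\n',
      '    </reaction>\n') else "",
    '  </listOfReactions>\n')
  enzyme_attr <- if (is.na(enzyme_conc)) "" else
    sprintf(' initialConcentration="%g"', enzyme_conc)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '<model id="testmodel">\n',
    '  <listOfSpecies>\n',
    sprintf('    <species id="GLC" name="glucose" initialConcentration="%g"/>\n',
            glucose_conc),
    '    <species id="G6P" name="glucose 6-phosphate" initialConcentration="0.3"/>\n',
    if (with_transport)
      '    <species id="GLC_e" name="extracellular glucose" initialConcentration="2"/>\n'
    else "",
    sprintf('    <species id="HXK1" name="hexokinase 1"%s/>\n', enzyme_attr),
    '  </listOfSpecies>\n',
    reactions,
    '</model>\n</sbml>\n')
  writeLines(xml, path)
  path
}

# one-enzyme model with configurable stoichiometry, for release/automaton tests
two_product_model <- function(kcat = 100) {
  v <- 1e-18
  species <- rbind(
    species_spec("E", "aldolase-like", "enzyme", 40000,
                 count_to_concentration(1, v)),
    species_spec("S", "S", "metabolite", 340, count_to_concentration(30, v)),
    species_spec("P1", "P1", "metabolite", 170, 0),
    species_spec("P2", "P2", "metabolite", 170, 0))
  pathway_model(species,
                list(reaction_spec("R_SPLIT", "E", c(S = 1),
                                   c(P1 = 1, P2 = 1), FALSE, kcat)),
                volume = v, provenance = "fixture:test")
}

two_substrate_model <- function(n_s1 = 20, n_s2 = 0, kcat = 100) {
  v <- 1e-18
  species <- rbind(
    species_spec("E", "E", "enzyme", 50000, count_to_concentration(1, v)),
    species_spec("S1", "S1", "metabolite", 200, count_to_concentration(n_s1, v)),
    species_spec("S2", "S2", "metabolite", 200, count_to_concentration(n_s2, v)),
    species_spec("P", "P", "metabolite", 200, 0))
  pathway_model(species,
                list(reaction_spec("R2", "E", c(S1 = 1, S2 = 1), c(P = 1),
                                   FALSE, kcat)),
                volume = v, provenance = "fixture:test")
}

# all-pairs overlap audit of a world: TRUE when no two live agents overlap
no_overlaps <- function(world, tol = 1e-9) {
  ag <- world_agents(world)
  if (nrow(ag) < 2) return(TRUE)
  pos <- as.matrix(ag[, c("x", "y", "z")])
  d <- as.matrix(dist(pos))
  rsum <- outer(ag$radius, ag$radius, "+")
  all(d[upper.tri(d)] >= rsum[upper.tri(rsum)] - tol)
}

# quick simulation config for tiny boxes
quick_config <- function(distance = 2000, law = "uniform", duration = 0.01,
                         seed = 1, record_every = 1, ...) {
  simulation_config(binding = binding_model(distance, law = law),
                    duration = duration, seed = seed,
                    record_every = record_every, ...)
}
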