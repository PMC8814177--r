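test_that("concentration/count conversion is exact and monotone", {
  expect_identical(concentration_to_count(1, 1e-18), 602L)
  expect_identical(concentration_to_count(0, 1e-15), 0L)
  # 0.086 mmol/l of NADH in one attolitre
  expect_identical(concentration_to_count(0.086, 1e-18), 52L)
  expect_error(concentration_to_count(-1, 1e-18))
  expect_error(concentration_to_count(1, 0))
  set.seed(1)
  for (i in 1:100) {
    v <- 10^runif(1, -19, -15)
    c1 <- runif(1, 0, 10); c2 <- c1 + runif(1, 0, 5)
    expect_lte(concentration_to_count(c1, v), concentration_to_count(c2, v))
    expect_equal(concentration_to_count(c1, v),
                 as.integer(round(c1 * 1e-3 * 6.02214076e23 * v)))
  }
  # count -> concentration -> count is the identity
  counts <- c(0L, 1L, 52L, 602L, 120L, sample.int(1e6, 20))
  expect_identical(
    concentration_to_count(count_to_concentration(counts, 1e-18), 1e-18),
    counts)
})

test_that("model validation catches structural errors", {
  sp <- rbind(species_spec("A", role = "metabolite",
                           molecular_weight = 100, initial_concentration = 1),
              species_spec("E", role = "enzyme",
                           molecular_weight = 5e4, initial_concentration = 0.01))
  ok <- pathway_model(sp, list(reaction_spec("R1", "E", c(A = 1), c(A = 1),
                                             kcat = 10)))
  expect_s3_class(ok, "pathway_model")
  expect_error(pathway_model(rbind(sp, sp[1, ]), list()), "duplicate")
  expect_error(pathway_model(sp, list(reaction_spec("R1", "E", c(X = 1),
                                                    c(A = 1), kcat = 10))),
               "unknown species")
  expect_error(pathway_model(sp, list(reaction_spec("R1", "A", c(A = 1),
                                                    c(A = 1), kcat = 10))),
               "role 'enzyme'")
  expect_error(reaction_spec("R1", "E", c(A = 0), c(A = 1), kcat = 10),
               "positive integers")
  expect_error(reaction_spec("R1", "E", c(A = 1), c(A = 1), kcat = -1),
               "kcat")
})

test_that("SBML models parse with enzymes taken from modifiers", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_test_sbml(f)
  m <- parse_sbml(f)
  expect_equal(m$species$initial_concentration[m$species$id == "GLC"], 6.28)
  expect_equal(m$species$role[m$species$id == "HXK1"], "enzyme")
  expect_equal(m$species$role[m$species$id == "GLC"], "metabolite")
  expect_length(m$reactions, 1)
  expect_equal(m$reactions[[1]]$enzyme, "HXK1")
  expect_equal(m$reactions[[1]]$kcat, 150)
  expect_true(m$reactions[[1]]$reversible)
})

test_that("SBML corner cases behave as specified", {
  # zero reactions is fine
  f <- withr::local_tempfile(fileext = ".xml")
  write_test_sbml(f, with_reactions = FALSE)
  m <- parse_sbml(f)
  expect_length(m$reactions, 0)
  expect_gt(nrow(m$species), 0)
  # an enzyme without an initial concentration is a hard error naming it
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_test_sbml(f2, enzyme_conc = NA)
  expect_error(parse_sbml(f2), "HXK1")
  # malformed XML reports a parse error
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f3)
  expect_error(parse_sbml(f3), "malformed|error")
  # missing kcat without a default is an error naming the reaction
  f4 <- withr::local_tempfile(fileext = ".xml")
  write_test_sbml(f4, with_kcat = FALSE)
  expect_error(parse_sbml(f4), "kcat")
  expect_length(parse_sbml(f4, default_kcat = 99)$reactions, 1)
})

test_that("native format round trip is the identity", {
  m <- glycolysis_model(scale = 0.5)
  for (ext in c(".xml", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_model(m, f)
    m2 <- read_model(f)
    expect_equal(m2$species, m$species)
    expect_equal(m2$volume, m$volume)
    expect_equal(length(m2$reactions), length(m$reactions))
    for (i in seq_along(m$reactions))
      expect_equal(unclass(m2$reactions[[i]]), unclass(m$reactions[[i]]))
  }
})

test_that("native format guards schema version and minimal models parse", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway-model format-version="1" provenance="hand">',
    '  <environment volume="1e-18"/>',
    '  <species-list>',
    '    <species id="E" name="E" role="enzyme" molecular-weight="50000" initial-concentration="0.005" approx="false"/>',
    '    <species id="S" name="S" role="metabolite" molecular-weight="200" initial-concentration="0.5" approx="false"/>',
    '    <species id="P" name="P" role="metabolite" molecular-weight="200" initial-concentration="0" approx="false"/>',
    '  </species-list>',
    '  <reaction-list>',
    '    <reaction id="R" name="R" enzyme="E" reversible="false" kcat="100">',
    '      <substrate species="S" stoichiometry="1"/>',
    '      <product species="P" stoichiometry="1"/>',
    '    </reaction>',
    '  </reaction-list>',
    '</pathway-model>'), f)
  m <- read_model(f)
  expect_length(m$reactions, 1)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('format-version="1"', 'format-version="99"', readLines(f)), f2)
  expect_error(read_model(f2), "version")
})

test_that("km and reverse kcat survive the round trip", {
  sp <- rbind(species_spec("E", role = "enzyme", molecular_weight = 5e4,
                           initial_concentration = 0.01),
              species_spec("A", role = "metabolite", molecular_weight = 100,
                           initial_concentration = 0.2),
              species_spec("B", role = "metabolite", molecular_weight = 100,
                           initial_concentration = 0))
  m <- pathway_model(sp, list(
    reaction_spec("R", "E", c(A = 1), c(B = 1), reversible = TRUE,
                  kcat = 100, kcat_reverse = 40, km = c(A = 0.3))))
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f)
  r <- read_model(f)$reactions[[1]]
  expect_equal(r$kcat_reverse, 40)
  expect_equal(r$km, c(A = 0.3))
})

test_that("default exclusions remove the adapted reactions and force irreversibility", {
  v <- 1e-18
  sp <- rbind(
    species_spec("GLC", role = "metabolite", molecular_weight = 180,
                 initial_concentration = 0.5),
    species_spec("G6P", role = "metabolite", molecular_weight = 260,
                 initial_concentration = 0.1),
    species_spec("ATP", role = "metabolite", molecular_weight = 507,
                 initial_concentration = 0.5),
    species_spec("ADP", role = "metabolite", molecular_weight = 427,
                 initial_concentration = 0.2),
    species_spec("AMP", role = "metabolite", molecular_weight = 347,
                 initial_concentration = 0.1),
    species_spec("PYR", role = "metabolite", molecular_weight = 88,
                 initial_concentration = 0.2),
    species_spec("ACD", role = "metabolite", molecular_weight = 44,
                 initial_concentration = 0),
    species_spec("HXK1", role = "enzyme", molecular_weight = 5e4,
                 initial_concentration = 0.01),
    species_spec("ADK1", role = "enzyme", molecular_weight = 2e4,
                 initial_concentration = 0.01),
    species_spec("PDC1", role = "enzyme", molecular_weight = 6e4,
                 initial_concentration = 0.01))
  rx <- list(
    reaction_spec("R_HXK1", "HXK1", c(GLC = 1, ATP = 1), c(G6P = 1, ADP = 1),
                  reversible = TRUE, kcat = 100, name = "hexokinase 1"),
    reaction_spec("R_ADK1", "ADK1", c(ADP = 2), c(ATP = 1, AMP = 1),
                  reversible = TRUE, kcat = 100, name = "adenylate kinase"),
    reaction_spec("R_PDC1", "PDC1", c(PYR = 1), c(ACD = 1),
                  reversible = FALSE, kcat = 100,
                  name = "pyruvate decarboxylase 1"),
    reaction_spec("R_GLT", NA_character_, c(GLC = 1), c(G6P = 1),
                  reversible = TRUE, kcat = 10, name = "glucose transport"))
  m <- pathway_model(sp, rx, volume = v, validate = FALSE)
  out <- suppressMessages(apply_exclusions(m))
  ids <- vapply(out$reactions, `[[`, "", "id")
  expect_setequal(ids, "R_HXK1")
  expect_false(out$reactions[[1]]$reversible)       # hexokinase forced
  # removed enzymes' orphan metabolites pruned, enzymes kept
  expect_false("ACD" %in% out$species$id)
  expect_true("PDC1" %in% out$species$id)
  # idempotent (the second pass warns that nothing matched, by design)
  out2 <- suppressWarnings(suppressMessages(apply_exclusions(out)))
  expect_equal(out2$species, out$species)
  expect_equal(length(out2$reactions), length(out$reactions))
  # empty rules leave the model untouched
  none <- exclusion_rules(removed_reactions = character(),
                          forced_irreversible = character())
  same <- apply_exclusions(m, none, prune_orphans = FALSE,
                           drop_enzymeless = FALSE)
  expect_equal(length(same$reactions), length(m$reactions))
  # a pattern that matches nothing is a warning, not an error
  expect_warning(
    apply_exclusions(out, exclusion_rules(removed_reactions = "nonexistent"),
                     prune_orphans = FALSE),
    "no reaction matched")
})

test_that("concentration scaling caps values and preserves counts", {
  v <- 1e-18
  sp <- rbind(
    species_spec("HI", role = "metabolite", molecular_weight = 180,
                 initial_concentration = 6.28),
    species_spec("LO", role = "metabolite", molecular_weight = 266,
                 initial_concentration = 0.0007),
    species_spec("E", role = "enzyme", molecular_weight = 5e4,
                 initial_concentration = 0.05))
  m <- pathway_model(sp, list(reaction_spec("R", "E", c(HI = 1), c(LO = 1),
                                            kcat = 10)), volume = v)
  out <- scale_concentrations(m, cap = 1)
  conc <- out$species$initial_concentration
  expect_true(all(conc < 1))
  # no positive species dropped to a zero particle count
  expect_true(all(concentration_to_count(conc, v)[conc > 0] >= 1))
  # ordering preserved (monotone map)
  expect_equal(order(m$species$initial_concentration), order(conc))
  # already-compliant models are unchanged
  m2 <- glycolysis_model()
  expect_equal(scale_concentrations(m2)$species$initial_concentration,
               m2$species$initial_concentration)
})
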