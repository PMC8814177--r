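test_that("perception radius is enzyme radius plus perception distance", {
  expect_equal(perception_radius(25, 300), 325)
  expect_equal(perception_radius(25, 0), 25)
  expect_gt(perception_radius(30, 10), perception_radius(20, 10))
})

test_that("binding probability laws honour the printed constraints", {
  for (law in c("inv_cube", "uniform", "inv_six")) {
    b <- binding_model(300, law = law)
    s <- seq(0, 320, by = 1)
    p <- binding_probability(s, b)
    expect_true(all(p[s <= 5] == 1))           # certainty at contact range
    expect_true(all(diff(p) <= 1e-12))         # non-increasing
    expect_true(all(p[s > 300] == 0))          # zero beyond d
  }
  b3 <- binding_model(300, law = "inv_cube")
  b6 <- binding_model(300, law = "inv_six")
  expect_equal(binding_probability(50, b3), (5 / 50)^3)
  expect_lt(binding_probability(50, b6), binding_probability(50, b3))
  expect_equal(binding_probability(150, binding_model(300, law = "uniform")), 1)
})

test_that("kcat wait times are the reciprocal turnover in ticks, floored at 1", {
  expect_identical(abmetab:::.wait_ticks(100, 1e-4), 100L)
  expect_identical(abmetab:::.wait_ticks(1e5, 1e-4), 1L)
  expect_identical(abmetab:::.wait_ticks(5000, 1e-4), 2L)
})

test_that("candidate selection is uniform in random mode and ordered in specificity mode", {
  # empty candidate set binds nothing
  expect_identical(abmetab:::.select_candidate_cpp(numeric(0), 0L, 5, 20, 0L,
                                                   numeric(0)), 0L)
  # two candidates at equal distance, certain binding: 50/50 within 3 sigma
  set.seed(9)
  picks <- replicate(1e4, abmetab:::.select_candidate_cpp(c(10, 10), 0L, 5,
                                                          20, 0L, c(0, 0)))
  expect_true(all(picks %in% 1:2))
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.031)
  # specificity mode always tries the higher kcat/Km first when p = 1
  picks2 <- replicate(200, abmetab:::.select_candidate_cpp(c(10, 10), 0L, 5,
                                                           20, 1L, c(1, 5)))
  expect_true(all(picks2 == 2L))
  # beyond the perception distance nothing is bound
  expect_identical(abmetab:::.select_candidate_cpp(c(30), 0L, 5, 20, 0L, 0),
                   0L)
})

test_that("specificity mode requires Km values at startup", {
  m <- toy_single_reaction(10)
  cfg <- quick_config(duration = 0.001)
  cfg$binding$mode <- "specificity"
  expect_error(run_simulation(m, cfg), "Km")
})

test_that("a world of metabolites alone conserves every count", {
  v <- 1e-18
  sp <- rbind(species_spec("A", role = "metabolite", molecular_weight = 180,
                           initial_concentration = 0.3),
              species_spec("B", role = "metabolite", molecular_weight = 507,
                           initial_concentration = 0.2),
              species_spec("E", role = "enzyme", molecular_weight = 5e4,
                           initial_concentration = 0.01))
  # enzyme catalyses nothing relevant: no A/B substrate overlap
  sp2 <- rbind(sp, species_spec("X", role = "metabolite",
                                molecular_weight = 100,
                                initial_concentration = 0))
  m <- pathway_model(sp2, list(reaction_spec("R", "E", c(X = 1), c(X = 1),
                                             kcat = 10)), volume = v)
  run <- run_simulation(m, quick_config(duration = 0.005, seed = 2))
  expect_true(all(run$series$free["A", ] == run$series$free["A", 1]))
  expect_true(all(run$series$free["B", ] == run$series$free["B", 1]))
})

test_that("fixed seeds reproduce trajectories exactly", {
  m <- toy_single_reaction(40)
  cfg <- quick_config(duration = 0.01, seed = 31, record_every = 5)
  r1 <- run_simulation(m, cfg)
  r2 <- run_simulation(m, cfg)
  expect_identical(serialize(r1$series, NULL), serialize(r2$series, NULL))
  cfg2 <- quick_config(duration = 0.01, seed = 32, record_every = 5)
  r3 <- run_simulation(m, cfg2)
  # different seeds follow different trajectories (positions diverge even
  # when the sparse count series happens to coincide)
  expect_false(identical(r1$world$a_x, r3$world$a_x))
})

test_that("a lone enzyme-substrate pair yields a product after bind + kcat wait", {
  m <- toy_single_reaction(1, kcat = 100)
  run <- run_simulation(m, quick_config(duration = 0.015, seed = 3))
  p <- run$series$free["P", ]
  # certain perception at tick 1, wait 100 ticks, release at tick 101
  expect_equal(run$series$ticks[min(which(p > 0))], 101)
  # substrate exhaustion: never more product than substrate existed
  expect_true(all(p <= 1))
  expect_equal(run$series$free["S", length(p)], 0, ignore_attr = TRUE)
})

test_that("contact-only binding finds nothing across an empty box", {
  m <- toy_single_reaction(1)
  n <- sum(initial_counts(m))
  pos <- rbind(c(100, 100, 100), c(900, 900, 900))[seq_len(n), , drop = FALSE]
  pos <- pos[c(1, 2), ]
  cfg <- quick_config(distance = 0, duration = 0.002, seed = 5)
  run <- run_simulation(m, cfg, positions = pos)
  expect_true(all(run$series$free["P", ] == 0))
})

test_that("complex radius follows volume additivity and products balance stoichiometry", {
  # slow enzyme so the saturated complex persists at the end of the run
  m <- toy_single_reaction(5, kcat = 1)
  run <- run_simulation(m, quick_config(duration = 0.005, seed = 6))
  ag <- world_agents(run$world)
  cx <- ag[ag$kind == "complex", ]
  expect_equal(nrow(cx), 1)
  rE <- radius_from_mass(54000); rS <- radius_from_mass(220)
  expect_equal(cx$radius, (rE^3 + rS^3)^(1 / 3), tolerance = 1e-12)
  expect_gt(cx$wait, 0)  # single-substrate complex saturates immediately

  # a splitting reaction creates both products in equal number
  m2 <- two_product_model(kcat = 200)
  run2 <- run_simulation(m2, quick_config(duration = 0.1, seed = 7,
                                          record_every = 50))
  fin <- run2$series$free[, ncol(run2$series$free)]
  expect_gt(fin["P1"], 0)
  expect_equal(fin["P1"], fin["P2"], ignore_attr = TRUE)
  comp <- run2$series$completions
  expect_equal(as.numeric(fin["P1"]),
               comp["R_SPLIT:fwd", ncol(comp)], ignore_attr = TRUE)
})

test_that("two-substrate automaton saturates only with both substrates", {
  # S2 absent: the enzyme can only form a partial complex, never a product
  m <- two_substrate_model(n_s1 = 20, n_s2 = 0)
  run <- run_simulation(m, quick_config(duration = 0.02, seed = 8,
                                        record_every = 10))
  expect_true(all(run$series$free["P", ] == 0))
  partial <- run$series$complex_partial["R2", ]
  expect_gt(max(partial), 0)
  expect_true(all(run$series$complex_saturated["R2", ] == 0))
  # with S2 present the reaction completes
  m2 <- two_substrate_model(n_s1 = 20, n_s2 = 20)
  run2 <- run_simulation(m2, quick_config(duration = 0.2, seed = 8,
                                          record_every = 100))
  expect_gt(run2$series$free["P", ncol(run2$series$free)], 0)
})

test_that("optional dissociation frees long-lived partial complexes", {
  m <- two_substrate_model(n_s1 = 20, n_s2 = 0)
  # without unbinding the substrate stays sequestered
  r0 <- run_simulation(m, quick_config(duration = 0.02, seed = 9,
                                       record_every = 10))
  expect_lt(r0$series$free["S1", ncol(r0$series$free)], 20)
  # with a 30-tick timeout the partial complex returns its metabolite
  r1 <- run_simulation(m, quick_config(duration = 0.02, seed = 9,
                                       record_every = 10,
                                       unbind_timeout = 30))
  last <- ncol(r1$series$free)
  expect_equal(r1$series$free["S1", last] +
                 r1$series$bound["S1", last], 20, ignore_attr = TRUE)
  expect_equal(conservation_check(r1, m), 0)
})

test_that("irreversible reactions never run backwards", {
  m <- toy_reversible_pair(n_a = 0, n_b = 60, reversible = FALSE)
  run <- run_simulation(m, quick_config(duration = 0.05, seed = 10,
                                        record_every = 25))
  expect_true(all(run$series$free["A", ] == 0))
  expect_true(all(run$series$completions["R_AB:rev", ] == 0))
})

test_that("reversible interconversion relaxes toward a 1:1 mixture", {
  m <- toy_reversible_pair(n_a = 120, n_b = 0, kcat = 1000)
  run <- run_simulation(m, quick_config(duration = 0.5, seed = 13,
                                        record_every = 100))
  fin <- run$series$free[, ncol(run$series$free)]
  frac <- fin["B"] / (fin["A"] + fin["B"])
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
  # the mirrored start behaves symmetrically
  m2 <- toy_reversible_pair(n_a = 0, n_b = 120, kcat = 1000)
  run2 <- run_simulation(m2, quick_config(duration = 0.5, seed = 13,
                                          record_every = 100))
  expect_gt(run2$series$free["A", ncol(run2$series$free)], 0)
})

test_that("conservation ledger balances exactly on random pathways", {
  for (seed in 1:10) {
    m <- random_pathway(n_species = 5, n_reactions = 3, seed = seed)
    cfg <- simulation_config(binding = binding_model(10), duration = 0.01,
                             seed = seed, record_every = 10)
    run <- run_simulation(m, cfg)
    expect_equal(conservation_check(run, m), 0)
  }
})

test_that("world invariants hold after full runs", {
  m <- glycolysis_model(scale = 0.05)
  run <- run_simulation(m, simulation_config(binding = binding_model(300),
                                             duration = 0.02, seed = 14,
                                             record_every = 100))
  expect_true(no_overlaps(run$world))
  ag <- world_agents(run$world)
  expect_true(all(ag[, c("x", "y", "z")] >= 0 &
                    ag[, c("x", "y", "z")] < 1000))
  expect_equal(conservation_check(run, m), 0)
})

test_that("checkpointed runs resume to the same trajectory", {
  m <- toy_single_reaction(30)
  dir <- withr::local_tempdir()
  cfg <- quick_config(duration = 0.02, seed = 17, record_every = 10,
                      checkpoint_every = 100L, checkpoint_dir = dir)
  full <- run_simulation(m, quick_config(duration = 0.02, seed = 17,
                                         record_every = 10))
  part <- run_simulation(m, cfg)
  ck <- file.path(dir, "checkpoint-000000100.rds")
  expect_true(file.exists(ck))
  resumed <- resume_simulation(ck)
  # the resumed tail matches the uninterrupted run
  tail_cols <- (ncol(full$series$free) - ncol(resumed$series$free) + 1):
    ncol(full$series$free)
  expect_equal(resumed$series$free, full$series$free[, tail_cols],
               ignore_attr = TRUE)
})
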