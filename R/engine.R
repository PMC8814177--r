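#' Simulation configuration
#'
#' Bundles the physical environment, the binding model, the run length and
#' the bookkeeping options of a run.
#'
#' @param env an [environment_params()] object.
#' @param binding a [binding_model()] object.
#' @param duration simulated seconds; must be an integer number of ticks.
#' @param seed integer seed; every source of randomness in the run derives
#'   from it.
#' @param record_every snapshot interval in ticks.
#' @param k_retries fresh random directions tried when a move is blocked.
#' @param unbind_timeout ticks after which a partially saturated complex
#'   dissociates and returns its metabolites; 0 (the default) disables
#'   dissociation, which reproduces the permanent partial complexes seen in
#'   contact-range runs.
#' @param gaussian_steps draw each displacement from an isotropic Gaussian
#'   with matching MSD instead of using a fixed per-species step modulus.
#' @param msd displacement law for the step modulus, see [step_length()].
#' @param checkpoint_every optional tick interval at which the full world is
#'   written to `checkpoint_dir` during [run_simulation()].
#' @param checkpoint_dir directory for checkpoints.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(env = environment_params(),
                              binding = binding_model(10),
                              duration = 1.0, seed = 1L,
                              record_every = 100L, k_retries = 5L,
                              unbind_timeout = 0L, gaussian_steps = FALSE,
                              msd = c("1d", "3d"),
                              checkpoint_every = NULL,
                              checkpoint_dir = NULL) {
  msd <- match.arg(msd)
  n_ticks <- duration / env$tick
  if (abs(n_ticks - round(n_ticks)) > 1e-6)
    stop("duration must be an integer number of ticks")
  stopifnot(record_every >= 1, k_retries >= 0)
  structure(list(env = env, binding = binding, duration = duration,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 k_retries = as.integer(k_retries),
                 unbind_timeout = as.integer(unbind_timeout),
                 gaussian_steps = isTRUE(gaussian_steps), msd = msd,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "simulation_config")
}

# wait_ticks = max(1, round((1/kcat)/tick)); the reciprocal of the turnover
# number expressed in ticks, floored at one tick
.wait_ticks <- function(kcat, tick) {
  pmax(1L, as.integer(round((1 / kcat) / tick)))
}

#' Instantiate the agent world of a model
#'
#' Converts initial concentrations to particle counts, derives radii, step
#' lengths and kcat wait times, and places all agents collision-free at
#' uniformly random positions.  Exposed mainly for testing and custom
#' drivers; [run_simulation()] calls it internally.
#'
#' @param model a validated `pathway_model`.
#' @param config a [simulation_config()].
#' @param positions optional n x 3 matrix to use instead of random
#'   placement (rows follow the agent order: species in model order, counts
#'   expanded).
#' @return a `abm_world` list understood by the engine.
#' @export
init_world <- function(model, config, positions = NULL) {
  validate_pathway_model(model)
  env <- config$env
  if (abs(env$volume - model$volume) / model$volume > 1e-9)
    stop("config box volume (", format(env$volume),
         " l) differs from model volume (", format(model$volume), " l)")
  sp <- model$species
  S <- nrow(sp)
  radius <- radius_from_mass(sp$molecular_weight)
  D <- diffusion_coefficient(radius, env$temperature, env$viscosity)
  step <- step_length(D, env$tick, config$msd)
  counts <- initial_counts(model)

  rx <- model$reactions
  R <- length(rx)
  stoich <- .stoich_matrices(model)
  enzyme_idx <- match(vapply(rx, `[[`, "", "enzyme"), sp$id) - 1L
  reversible <- vapply(rx, function(r) as.integer(r$reversible), 0L)
  kcat_f <- vapply(rx, `[[`, 0, "kcat")
  kcat_r <- vapply(rx, function(r)
    if (is.null(r$kcat_reverse)) r$kcat else r$kcat_reverse, 0)
  spec_const <- matrix(NA_real_, R, S)
  for (i in seq_len(R)) {
    r <- rx[[i]]
    if (!is.null(r$km)) {
      j <- match(names(r$km), sp$id)
      spec_const[i, j] <- r$kcat / r$km
    }
  }
  if (config$binding$mode == "specificity" &&
      any(vapply(rx, function(r) is.null(r$km), logical(1))))
    stop("specificity mode requires Km values for every reaction")

  a_species <- rep.int(seq_len(S), counts)
  N <- length(a_species)
  if (is.null(positions)) {
    positions <- place_initial(radius[a_species], env$side)
  } else {
    stopifnot(nrow(positions) == N)
  }

  list(
    species_id = sp$id,
    species_radius = radius,
    species_step = step,
    species_is_enzyme = as.integer(sp$role == "enzyme"),
    reaction_id = vapply(rx, `[[`, "", "id"),
    r_enzyme = enzyme_idx,
    r_reversible = reversible,
    r_wait_f = .wait_ticks(kcat_f, env$tick),
    r_wait_r = .wait_ticks(kcat_r, env$tick),
    r_sub = stoich$sub,
    r_prod = stoich$prod,
    r_spec_const = spec_const,
    a_species = a_species - 1L,
    a_kind = ifelse(sp$role[a_species] == "enzyme", 1L, 0L),
    a_reaction = rep.int(-1L, N),
    a_dir = rep.int(0L, N),
    a_wait = rep.int(-1L, N),
    a_age = rep.int(0L, N),
    a_alive = rep.int(TRUE, N),
    a_x = positions[, 1], a_y = positions[, 2], a_z = positions[, 3],
    a_radius = radius[a_species],
    a_step = step[a_species],
    a_bound = matrix(0L, N, S),
    side = env$side,
    boundary = 0L,
    perception_distance = config$binding$distance,
    law = .law_code(config$binding$law),
    law_s0 = config$binding$contact_distance,
    mode = if (config$binding$mode == "specificity") 1L else 0L,
    k_retries = config$k_retries,
    unbind_timeout = config$unbind_timeout,
    gaussian = as.integer(config$gaussian_steps),
    step_coef = .step_coefficient(env, config$msd),
    tick = 0,
    completions = rep(0, 2 * R),
    deferred = 0,
    volume = model$volume
  )
}

# snapshot of a world computed in R (used for the tick-0 record)
.world_snapshot <- function(world) {
  S <- length(world$species_id)
  R <- length(world$reaction_id)
  alive <- world$a_alive
  free <- integer(S); bound <- integer(S)
  partial <- integer(R); saturated <- integer(R)
  sp <- world$a_species + 1L
  is_free <- alive & world$a_kind %in% c(0L, 1L)
  f <- tabulate(sp[is_free], nbins = S)
  free <- f
  cx <- which(alive & world$a_kind == 2L)
  for (i in cx) {
    bound[sp[i]] <- bound[sp[i]] + 1L
    bound <- bound + world$a_bound[i, ]
    r <- world$a_reaction[i] + 1L
    if (world$a_wait[i] >= 1L) saturated[r] <- saturated[r] + 1L
    else partial[r] <- partial[r] + 1L
  }
  list(free = free, bound = bound, partial = partial, saturated = saturated,
       completions = world$completions)
}

#' Run a simulation
#'
#' Executes `duration / tick` ticks of the see-perceive-act loop.  Each tick
#' has three phases, each iterating the agents in a fresh random order drawn
#' from the seeded stream: (1) free molecules and non-saturated complexes
#' move by their per-species step modulus in a random direction, with up to
#' `k_retries` re-aims when the landing spot is occupied; (2) free enzymes
#' and non-saturated complexes perceive cognate metabolites within the
#' perception distance and probabilistically bind at most one of them;
#' (3) saturated complexes count down their kcat wait and release products
#' at collision-free positions adjacent to the enzyme.  Snapshots are taken
#' every `record_every` ticks.
#'
#' @param model a `pathway_model`.
#' @param config a [simulation_config()].
#' @param positions optional fixed initial positions (see [init_world()]).
#' @return an object of class `abm_run`: `$series` (a `conc_series`),
#'   `$world` (final world state) and `$config`.
#' @export
run_simulation <- function(model, config, positions = NULL) {
  set.seed(config$seed)
  world <- init_world(model, config, positions = positions)
  n_ticks <- as.integer(round(config$duration / config$env$tick))
  rec <- config$record_every

  snap0 <- .world_snapshot(world)
  S <- length(world$species_id)
  R <- length(world$reaction_id)
  free <- matrix(snap0$free, S, 1)
  bound <- matrix(snap0$bound, S, 1)
  partial <- matrix(snap0$partial, R, 1)
  saturated <- matrix(snap0$saturated, R, 1)
  completions <- matrix(snap0$completions, 2 * R, 1)
  ticks <- 0

  chunk <- if (!is.null(config$checkpoint_every))
    as.integer(config$checkpoint_every) else max(rec * 50L, 1000L)
  done <- 0L
  while (done < n_ticks) {
    n <- min(chunk, n_ticks - done)
    out <- .abm_advance_cpp(world, as.integer(n), rec)
    world <- out$world
    if (length(out$rec_ticks)) {
      free <- cbind(free, out$rec_free)
      bound <- cbind(bound, out$rec_bound)
      partial <- cbind(partial, out$rec_partial)
      saturated <- cbind(saturated, out$rec_saturated)
      completions <- cbind(completions, out$rec_completions)
      ticks <- c(ticks, out$rec_ticks)
    }
    done <- done + n
    if (!is.null(config$checkpoint_every) && !is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(world = world, done = done, model = model, config = config,
                   rng = .Random.seed),
              file.path(config$checkpoint_dir,
                        sprintf("checkpoint-%09d.rds", done)))
    }
  }

  rownames(free) <- rownames(bound) <- world$species_id
  rownames(partial) <- rownames(saturated) <- world$reaction_id
  rownames(completions) <- c(rbind(paste0(world$reaction_id, ":fwd"),
                                   paste0(world$reaction_id, ":rev")))
  series <- structure(list(
    times = ticks * config$env$tick,
    ticks = ticks,
    free = free, bound = bound,
    complex_partial = partial, complex_saturated = saturated,
    completions = completions,
    species = world$species_id,
    reactions = world$reaction_id,
    volume = world$volume,
    meta = list(seed = config$seed,
                config_hash = object_hash(config),
                model_hash = object_hash(model),
                tick = config$env$tick,
                record_every = rec,
                perception_distance = config$binding$distance,
                deferred_releases = world$deferred)
  ), class = "conc_series")

  structure(list(series = series, world = world, config = config),
            class = "abm_run")
}

#' Resume a checkpointed run
#'
#' Continues a run written by [run_simulation()] with `checkpoint_every`
#' set, reproducing exactly the remaining ticks of the original trajectory.
#'
#' @param checkpoint_file an `.rds` checkpoint.
#' @return an `abm_run` covering the remaining ticks (series times continue
#'   from the checkpoint tick).
#' @export
resume_simulation <- function(checkpoint_file) {
  ck <- readRDS(checkpoint_file)
  config <- ck$config
  n_ticks <- as.integer(round(config$duration / config$env$tick))
  remaining <- n_ticks - ck$done
  if (remaining <= 0) stop("checkpoint is already at the end of the run")
  assign(".Random.seed", ck$rng, envir = globalenv())
  world <- ck$world
  out <- .abm_advance_cpp(world, remaining, config$record_every)
  world <- out$world
  S <- length(world$species_id); R <- length(world$reaction_id)
  free <- out$rec_free; bound <- out$rec_bound
  rownames(free) <- rownames(bound) <- world$species_id
  series <- structure(list(
    times = out$rec_ticks * config$env$tick, ticks = out$rec_ticks,
    free = free, bound = bound,
    complex_partial = out$rec_partial,
    complex_saturated = out$rec_saturated,
    completions = out$rec_completions,
    species = world$species_id, reactions = world$reaction_id,
    volume = world$volume,
    meta = list(seed = config$seed, config_hash = object_hash(config),
                model_hash = object_hash(ck$model), tick = config$env$tick,
                record_every = config$record_every,
                perception_distance = config$binding$distance,
                deferred_releases = world$deferred)
  ), class = "conc_series")
  structure(list(series = series, world = world, config = config),
            class = "abm_run")
}

#' Agents of a world as a data frame
#'
#' Position snapshot for export to external 3-D viewers and for invariant
#' checks in tests.
#'
#' @param world an `abm_world` (e.g. `run$world`).
#' @return data frame with id, species, kind, x, y, z, radius, wait.
#' @export
world_agents <- function(world) {
  alive <- world$a_alive
  kinds <- c("metabolite", "enzyme", "complex")
  data.frame(
    id = which(alive),
    species = world$species_id[world$a_species[alive] + 1L],
    kind = kinds[world$a_kind[alive] + 1L],
    x = world$a_x[alive], y = world$a_y[alive], z = world$a_z[alive],
    radius = world$a_radius[alive],
    wait = world$a_wait[alive],
    stringsAsFactors = FALSE)
}

#' Verify the species conservation ledger of a run
#'
#' At every recorded tick and for each species, free + bound - initial must
#' equal the net stoichiometric production of the completed reactions, as an
#' exact integer identity.
#'
#' @param run an `abm_run` (or its `conc_series` together with `model`).
#' @param model the `pathway_model` that produced the run.
#' @return maximum absolute deviation (0 when the ledger balances).
#' @export
conservation_check <- function(run, model) {
  series <- if (inherits(run, "abm_run")) run$series else run
  st <- .stoich_matrices(model)
  net_f <- t(st$prod - st$sub)   # S x R
  S <- length(series$species)
  R <- length(series$reactions)
  total <- series$free + series$bound
  delta <- total - total[, 1]
  comp <- series$completions
  fwd <- comp[seq(1, 2 * R, by = 2), , drop = FALSE]
  rev <- comp[seq(2, 2 * R, by = 2), , drop = FALSE]
  expected <- net_f %*% fwd - net_f %*% rev
  max(abs(delta - expected))
}
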