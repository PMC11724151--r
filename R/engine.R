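# Per-timestep process chain: suitability -> metabolic scaling -> local
# reproduction -> kernel dispersal -> recruitment. Abundance is integerised
# once per timestep, after recruitment (round-down), so the deterministic
# closed-cell dynamics settle within one individual of the effective
# carrying capacity.

#' Habitat suitability of one species at one timestep
#'
#' Applies the cardinal tolerance curve to every niche variable the species
#' has limits for (temperature; precipitation when both layer and limits are
#' present), passes pre-computed suitability layers through unchanged,
#' combines them with the configured `env_attribute_mode`, and applies the
#' restriction layer with `env_restriction_mode`. Uninhabitable (missing)
#' cells get suitability 0.
#'
#' @param sim a `dynrange_sim`.
#' @param species species index or name.
#' @param t timestep index.
#' @return suitability matrix in \[0, 1\].
#' @export
compute_suitability <- function(sim, species = 1, t = 1) {
  sp <- sim$species[[species]]
  env <- sim$env
  cfg <- sim$config
  fields <- list(
    tolerance_suitability(env$vars$temperature[, , t],
                          sp$lower_limit_temperature,
                          sp$optimum_temperature,
                          sp$upper_limit_temperature)
  )
  if (!is.null(env$vars$precipitation) &&
      !is.null(sp$lower_limit_precipitation)) {
    fields <- c(fields, list(
      tolerance_suitability(env$vars$precipitation[, , t],
                            sp$lower_limit_precipitation,
                            sp$optimum_precipitation,
                            sp$upper_limit_precipitation)
    ))
  }
  for (nm in setdiff(names(env$vars),
                     c("temperature", "precipitation", "restriction"))) {
    layer <- env$vars[[nm]][, , t]
    layer[is.na(layer)] <- 0
    fields <- c(fields, list(layer))
  }
  h <- combine_suitability(fields, mode = cfg$env_attribute_mode)
  if (!is.null(env$vars$restriction)) {
    restr <- env$vars$restriction[, , t]
    h <- apply_restriction(h, restr, mode = cfg$env_restriction_mode)
  }
  h[!env$habitable] <- 0
  h
}

#' Initial abundance grid
#'
#' * `habitat`: every cell with positive suitability starts at
#'   `round(K_h) = round(K * h)`, i.e. population size proportional to
#'   habitat suitability;
#' * `all`: every habitable cell starts at `round(K)` regardless of
#'   suitability;
#' * `random`: like `habitat`, but each suitable cell is occupied
#'   independently with probability 0.5 (drawn from the seeded generator).
#'
#' @param K carrying-capacity grid (already metabolically scaled, 0 at
#'   uninhabitable cells).
#' @param h suitability grid in \[0, 1\].
#' @param mode one of `"habitat"`, `"all"`, `"random"`.
#' @return integer-valued abundance matrix.
#' @export
initialise_abundance <- function(K, h, mode = c("habitat", "all", "random")) {
  mode <- match.arg(mode)
  switch(mode,
    habitat = ifelse(h > 0, round(K * h), 0),
    all = round(K),
    random = {
      occupied <- matrix(stats::runif(length(h)) < 0.5, nrow(h), ncol(h))
      ifelse(h > 0 & occupied, round(K * h), 0)
    }
  )
}

#' Initialise the simulation state for one species
#'
#' Seeds the random generator from `config$randomseed`, builds the dispersal
#' kernel from the species' dispersal traits, computes the timestep-1 fields
#' and places the initial population according to `config$initialise_cells`.
#'
#' @param sim a `dynrange_sim`.
#' @param species species index or name.
#' @return an object of class `dynrange_state` holding the current abundance
#'   grid `N`, the next timestep index `t`, the accumulating output stacks
#'   and references to the inputs.
#' @export
initialise_state <- function(sim, species = 1) {
  cfg <- sim$config
  sp <- sim$species[[species]]
  env <- sim$env
  set.seed(cfg$randomseed)
  kernel <- build_kernel(sp$mean_dispersal_dist, sp$max_dispersal_dist)
  h1 <- compute_suitability(sim, species, 1)
  dem1 <- scale_demography(sp, env$vars$temperature[, , 1],
                           cfg$use_metabolic_theory)
  N0 <- initialise_abundance(dem1$K, h1, cfg$initialise_cells)
  structure(list(sim = sim, species = species, kernel = kernel,
                 N = N0, t = 1L,
                 output = new_output(env$rows, env$cols, cfg$timesteps)),
            class = "dynrange_state")
}

#' Advance the simulation by one timestep
#'
#' Executes, in order: (1) habitat suitability, (2) metabolic scaling of the
#' demographic rates, (3) effective carrying capacity `K_h = K * h`,
#' (4) the local survivor/seed step under the configured reproduction model,
#' (5) kernel dispersal of the seeds with absorbing edges, (6) recruitment
#' (Poisson when `use_stoch_num`), and (7) the abundance update
#' `N' = floor(survivors + recruits)`. The post-update abundance and the
#' fields used in the step (`habitat`, `carry = K_h`, `growrate`, `bevmort`)
#' are recorded in the output stacks at the current timestep.
#'
#' @param state a `dynrange_state`.
#' @return the advanced state.
#' @export
simulate_timestep <- function(state) {
  sim <- state$sim
  cfg <- sim$config
  sp <- sim$species[[state$species]]
  t <- state$t
  if (t > cfg$timesteps) {
    dr_stop("dynrange_bad_value", "simulation already completed")
  }
  temp <- sim$env$vars$temperature[, , t]
  h <- compute_suitability(sim, state$species, t)
  dem <- scale_demography(sp, temp, cfg$use_metabolic_theory)
  K_h <- effective_capacity(dem$K, h)
  step <- local_step(cfg$reproduction_model, state$N, dem$r, dem$m_mort,
                     K_h, dem$A)
  arrivals <- disperse(step$seeds, state$kernel)
  recruits <- if (cfg$use_stoch_num) recruit(arrivals, TRUE) else arrivals
  N_next <- floor(step$survivors_real + recruits)
  N_next[!sim$env$habitable] <- 0
  state$N <- N_next
  state$output$abundances[, , t] <- N_next
  state$output$habitat[, , t] <- h
  state$output$carry[, , t] <- K_h
  state$output$growrate[, , t] <- dem$r
  state$output$bevmort[, , t] <- dem$m_mort
  state$t <- t + 1L
  state
}

#' Run the full simulation for one species
#'
#' Initialises the state (see [initialise_state()]) and iterates
#' [simulate_timestep()] over all configured timesteps, logging progress and
#' total elapsed time to standard error. With the same configuration and
#' random seed, repeated runs are bit-identical.
#'
#' @param sim a `dynrange_sim` (from [read_input()], [demo_input()] or
#'   [simulation_input()]).
#' @param species species index or name (one species is simulated at a
#'   time; loop over `sim$species` for several).
#' @param quiet suppress progress logging.
#' @param verbose log per-timestep total abundance as well.
#' @return a `dynrange_output`: stacks `abundances`, `habitat`, `carry`,
#'   `growrate`, `bevmort`, each `[row, col, timestep]`.
#' @export
run_simulation <- function(sim, species = 1, quiet = FALSE, verbose = FALSE) {
  stopifnot(inherits(sim, "dynrange_sim"))
  t0 <- Sys.time()
  state <- initialise_state(sim, species)
  tn <- sim$config$timesteps
  for (t in seq_len(tn)) {
    state <- simulate_timestep(state)
    if (!quiet) {
      if (verbose) {
        message(sprintf("timestep %d/%d  total abundance %.0f",
                        t, tn, sum(state$N)))
      } else {
        message(sprintf("timestep %d/%d", t, tn))
      }
    }
  }
  if (!quiet) {
    message(sprintf("simulation finished in %.2f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- state$output
  attr(out, "species") <- sim$species[[species]]$name
  attr(out, "experiment") <- sim$config$experiment_name
  out
}

#' Per-cell abundance change between two timesteps
#'
#' `N(t_to) - N(t_from)` per cell; used e.g. to compare the end of a
#' simulation with the end of its burn-in period when mapping range gains
#' and losses.
#'
#' @param output a `dynrange_output`.
#' @param t_from,t_to timestep indices with `1 <= t_from < t_to <= timesteps`.
#' @param variable which stack to difference (default `abundances`; use
#'   `habitat` for suitability-change maps).
#' @return signed change matrix.
#' @export
abundance_change <- function(output, t_from, t_to, variable = "abundances") {
  tn <- dim(output$abundances)[3]
  if (!(t_from >= 1 && t_from < t_to && t_to <= tn)) {
    dr_stop("dynrange_bad_value",
            sprintf("need 1 <= t_from < t_to <= %d", tn))
  }
  if (!variable %in% output_variables) {
    dr_stop("dynrange_bad_value",
            sprintf("unknown output variable '%s'", variable))
  }
  output[[variable]][, , t_to] - output[[variable]][, , t_from]
}

#' @export
print.dynrange_output <- function(x, ...) {
  d <- dim(x$abundances)
  cat(sprintf("<dynrange_output> %d x %d grid, %d timesteps\n",
              d[1], d[2], d[3]))
  cat(sprintf("  final total abundance: %.0f\n", sum(x$abundances[, , d[3]])))
  invisible(x)
}

#' @export
print.dynrange_sim <- function(x, ...) {
  cat(sprintf("<dynrange_sim> experiment '%s': %d x %d grid, %d timesteps, %d species (%s)\n",
              x$config$experiment_name, x$env$rows, x$env$cols,
              x$config$timesteps, length(x$species),
              paste(names(x$species), collapse = ", ")))
  invisible(x)
}
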