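# Shared fixtures: all inputs are built in code at test time.

# Brute-force per-cell scatter loop; independent oracle for disperse().
scatter_oracle <- function(seeds, kernel) {
  R <- kernel$radius
  w <- kernel$weights
  nr <- nrow(seeds); nc <- ncol(seeds)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (seeds[i, j] == 0) next
      for (di in -R:R) {
        for (dj in -R:R) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            out[ii, jj] <- out[ii, jj] +
              seeds[i, j] * w[di + R + 1, dj + R + 1]
          }
        }
      }
    }
  }
  out
}

# A species whose temperature niche is centred on 293.15 K.
test_species <- function(...) {
  args <- utils::modifyList(
    list(name = "test_sp", carry = 1000, growrate = 1.15, bevmort = 0.44,
         max_dispersal_dist = 1, mean_dispersal_dist = 0.0005, mass = 10,
         lower_limit_temperature = 283.15, optimum_temperature = 293.15,
         upper_limit_temperature = 303.15),
    list(...))
  do.call(species_params, args)
}

# Minimal in-memory simulation on a temperature-only landscape.
uniform_sim <- function(temperature = 293.15, rows = 3, cols = 3,
                        timesteps = 5, species = list(), config = list()) {
  temp <- if (is.matrix(temperature) || length(dim(temperature)) == 3) {
    temperature
  } else {
    matrix(temperature, rows, cols)
  }
  cfg <- do.call(simulation_config,
                 utils::modifyList(list(timesteps = timesteps), config))
  env <- environment_series(list(temperature = temp), cfg$timesteps)
  simulation_input(cfg, do.call(test_species, species), env)
}

# Two-patch contrast landscape: a central block starts at the species
# optimum and warms out of the niche, the surrounding ring starts below the
# optimum and warms into it (uniform warming trend, 10-step burn-in).
two_patch_sim <- function(mean_dispersal) {
  rows <- 20; cols <- 20; tn <- 30
  core <- matrix(FALSE, rows, cols)
  core[7:14, 7:14] <- TRUE
  base <- matrix(285.15, rows, cols)
  base[core] <- 293.15
  stack <- climate_trend_series(base, timesteps = tn, onset = 11,
                                delta_per_step = 0.4)
  sim <- uniform_sim(stack, timesteps = tn,
                     species = list(max_dispersal_dist = 5,
                                    mean_dispersal_dist = mean_dispersal),
                     config = list(use_metabolic_theory = FALSE))
  list(sim = sim, core = core)
}

write_config_file <- function(dir, lines) {
  path <- file.path(dir, "configuration.csv")
  writeLines(lines, path)
  path
}

write_species_file <- function(dir, name = "sp", ...) {
  over <- list(...)
  kv <- utils::modifyList(
    list(carry = 1000, growrate = 1.15, bevmort = 0.44,
         max_dispersal_dist = 1, mean_dispersal_dist = 0.5, mass = 10,
         lower_limit_temperature = 10, optimum_temperature = 20,
         upper_limit_temperature = 30),
    over)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(name, ".csv"))
  writeLines(sprintf("%s,%s", names(kv), unlist(kv)), path)
  path
}
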