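# Synthetic landscapes and packaged example experiments, so that the whole
# simulator is exercisable without any external data.

# Gaussian-blur smoothing with edge renormalisation (smoothing a constant
# field returns the constant everywhere, including corners).
gaussian_smooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  R <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- seq(-R, R)
  w <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  kernel <- structure(list(weights = w / sum(w), radius = R),
                      class = "dynrange_kernel")
  num <- disperse(z - min(z), kernel) # disperse() requires non-negative input
  den <- disperse(matrix(1, nrow(z), ncol(z)), kernel)
  num / den + min(z)
}

#' Spatially autocorrelated neutral landscape
#'
#' Generates a Gaussian random field by smoothing white noise with a Gaussian
#' kernel (autocorrelation length = kernel standard deviation in cells), then
#' affinely standardises it so the sample mean and sample standard deviation
#' equal the targets exactly, independent of seed and autocorrelation length.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param mean,sd target sample mean and standard deviation (`sd >= 0`;
#'   `sd = 0` gives a constant grid).
#' @param autocorr_length smoothing length in cells (0 = white noise).
#' @param seed optional integer seed; when given, the field is reproducible.
#' @return a `rows x cols` numeric matrix.
#' @export
neutral_landscape <- function(rows, cols, mean = 0, sd = 1,
                              autocorr_length = 3, seed = NULL) {
  if (rows < 1 || cols < 1) {
    dr_stop("dynrange_bad_value", "rows and cols must be >= 1")
  }
  if (sd < 0) dr_stop("dynrange_bad_value", "sd must be >= 0")
  if (sd == 0) return(matrix(mean, rows, cols))
  if (rows * cols < 2) {
    dr_stop("dynrange_bad_value",
            "cannot standardise a single-cell grid to sd > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  z <- gaussian_smooth(z, autocorr_length)
  (z - base::mean(z)) / stats::sd(z) * sd + mean
}

#' Default demonstration species
#'
#' A perennial-plant-like parameter set: the demographic reference values
#' (reproduction 1.15, mortality 0.44, carrying capacity 266667 per cell)
#' and body mass (23.82 g) of a terrestrial orchid, with the temperature
#' niche centred on the demonstration landscape (optimum 293.15 K, +-10 K
#' tolerance), a broad precipitation niche around 500 mm/yr, and dispersal
#' raised to mean 1 / maximum 3 cells so that dispersal is visible at demo
#' scale.
#'
#' @return a `dynrange_species`.
#' @export
default_species <- function() {
  species_params(
    name = "demo_species",
    carry = 266667, growrate = 1.15, bevmort = 0.44,
    max_dispersal_dist = 3, mean_dispersal_dist = 1,
    mass = 23.82,
    lower_limit_temperature = 283.15,
    optimum_temperature = 293.15,
    upper_limit_temperature = 303.15,
    lower_limit_precipitation = 100,
    optimum_precipitation = 500,
    upper_limit_precipitation = 1000
  )
}

#' Out-of-the-box demonstration input
#'
#' Builds a fully initialised, immediately runnable simulation on a random
#' 20 x 20 neutral landscape: temperature with sample mean 293.15 K and
#' standard deviation 2.5 K, precipitation with mean 500 and standard
#' deviation 100 mm/yr (both exact by construction), the
#' [default_species()], default configuration and 25 timesteps. The internal
#' landscape seed is fixed, so repeated calls return identical inputs.
#'
#' @return a `dynrange_sim`; run it with [run_simulation()].
#' @examples
#' sim <- demo_input()
#' out <- run_simulation(sim, quiet = TRUE)
#' dim(out$abundances)
#' @export
demo_input <- function() {
  temperature <- neutral_landscape(20, 20, mean = 293.15, sd = 2.5,
                                   autocorr_length = 3, seed = 42L)
  precipitation <- neutral_landscape(20, 20, mean = 500, sd = 100,
                                     autocorr_length = 3, seed = 43L)
  config <- simulation_config(experiment_name = "demo", timesteps = 25L)
  env <- environment_series(
    list(temperature = temperature, precipitation = precipitation),
    timesteps = 25L
  )
  simulation_input(config, default_species(), env)
}

#' Additive climate trend on top of a base grid
#'
#' Produces an environment stack whose slices `1 .. onset-1` equal the base
#' grid (the burn-in period with stable conditions) and which thereafter
#' accumulates a uniform additive trend of `delta_per_step` per timestep:
#' slice `t >= onset` equals `base + (t - onset + 1) * delta_per_step`.
#'
#' @param base numeric matrix (e.g. a [neutral_landscape()]).
#' @param timesteps total number of slices.
#' @param onset first timestep affected by the trend
#'   (`1 <= onset <= timesteps`; `onset = 1` means no burn-in).
#' @param delta_per_step additive change per timestep (same units as `base`).
#' @return a `[row, col, timesteps]` array.
#' @export
climate_trend_series <- function(base, timesteps, onset, delta_per_step) {
  if (onset < 1 || onset > timesteps) {
    dr_stop("dynrange_bad_value", "need 1 <= onset <= timesteps")
  }
  shift <- pmax(0, seq_len(timesteps) - onset + 1) * delta_per_step
  out <- array(0, dim = c(nrow(base), ncol(base), timesteps))
  for (t in seq_len(timesteps)) out[, , t] <- base + shift[t]
  out
}

write_stack_csv <- function(stack, dir, prefix = "t") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tn <- dim(stack)[3]
  for (t in seq_len(tn)) {
    write_matrix_csv(stack[, , t],
                     file.path(dir, sprintf("%s%03d.csv", prefix, t)))
  }
  invisible(dir)
}

orchis_species_file <- function() {
  system.file("extdata", "species", "Orchis_militaris.csv",
              package = "dynrange")
}

#' Write a self-contained example experiment to disk
#'
#' Creates a ready-to-run input directory (configuration file, species
#' folder with the packaged *Orchis militaris* trait file, environment
#' folder with synthetic CSV layers) in one of two flavours:
#'
#' * `"static"` (`Example1_Static_Environment`): a static synthetic
#'   landscape whose temperature is centred on the species optimum
#'   (mean 283.35 K, sd 2.5 K) and precipitation on 1000 mm/yr (sd 200);
#'   20 timesteps.
#' * `"change"` (`Example2_Environmental_Change`): the same landscape with a
#'   40-timestep temperature series, a 10-timestep burn-in and a uniform
#'   warming trend of `+0.1` K per timestep from timestep 11 on (a
#'   desk-scale stand-in for a downscaled climate-projection series).
#'
#' @param path directory in which to create the example (created if needed).
#' @param example `"static"` or `"change"`.
#' @param rows,cols landscape size.
#' @param seed seed for the synthetic landscape.
#' @return the path of the created example directory (containing
#'   `configuration.csv`), invisibly usable with [read_input()].
#' @export
create_example <- function(path, example = c("static", "change"),
                           rows = 25, cols = 25, seed = 42L) {
  example <- match.arg(example)
  name <- if (example == "static") {
    "Example1_Static_Environment"
  } else {
    "Example2_Environmental_Change"
  }
  root <- file.path(path, name)
  env_dir <- file.path(root, "environment")
  sp_dir <- file.path(root, "species")
  dir.create(env_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(orchis_species_file(), file.path(sp_dir, "Orchis_militaris.csv"),
            overwrite = TRUE)
  temp0 <- neutral_landscape(rows, cols, mean = 283.35, sd = 2.5,
                             autocorr_length = 4, seed = seed)
  prec0 <- neutral_landscape(rows, cols, mean = 1000, sd = 200,
                             autocorr_length = 4, seed = seed + 1L)
  lines <- c(
    sprintf("experiment_name,%s", name),
    "species_dir,./species/",
    "environment_dir,./environment/",
    "precipitation,precipitation.csv",
    "reproduction_model,Beverton",
    "use_metabolic_theory,true",
    "initialise_cells,habitat"
  )
  write_matrix_csv(prec0, file.path(env_dir, "precipitation.csv"))
  if (example == "static") {
    write_matrix_csv(temp0, file.path(env_dir, "temperature.csv"))
    lines <- c(lines, "temperature,temperature.csv", "timesteps,20")
  } else {
    stack <- climate_trend_series(temp0, timesteps = 40, onset = 11,
                                  delta_per_step = 0.1)
    write_stack_csv(stack, file.path(env_dir, "temperature"))
    lines <- c(lines, "temperature,temperature", "timesteps,40")
  }
  writeLines(lines, file.path(root, "configuration.csv"))
  invisible(root)
}
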