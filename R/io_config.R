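# Reading and validating the three plain-CSV input kinds (configuration,
# species traits, gridded environment layers), assembling the simulation
# container, and writing/reading the long-format TSV output.

config_defaults <- function() {
  list(
    experiment_name = "default",
    output_dir = "./output/",
    species_dir = "./species/",
    environment_dir = "./environment/",
    input_backup = FALSE,
    temperature = NULL,
    precipitation = NULL,
    restriction = NULL,
    env_attribute_mode = "minimum",
    env_restriction_mode = "minimum",
    timesteps = 20L,
    randomseed = 42L,
    reproduction_model = "Beverton",
    use_metabolic_theory = TRUE,
    use_stoch_num = FALSE,
    initialise_cells = "habitat",
    temperature_unit = NULL
  )
}

#' Construct a validated simulation configuration
#'
#' Programmatic equivalent of [read_config()]: any field not supplied keeps
#' its documented default (`timesteps = 20`, `randomseed = 42`,
#' `reproduction_model = "Beverton"`, `env_attribute_mode = "minimum"`,
#' `env_restriction_mode = "minimum"`, `initialise_cells = "habitat"`,
#' `use_metabolic_theory = TRUE`, `use_stoch_num = FALSE`,
#' `input_backup = FALSE`, `experiment_name = "default"`).
#'
#' @param ... configuration fields to override; see [read_config()] for the
#'   full key list.
#' @param config_dir directory against which relative input paths are
#'   resolved (defaults to the working directory).
#' @return an object of class `dynrange_config`.
#' @export
simulation_config <- function(..., config_dir = ".") {
  cfg <- config_defaults()
  over <- list(...)
  extra <- character(0)
  for (key in names(over)) {
    if (key %in% names(cfg)) {
      cfg[[key]] <- over[[key]]
    } else if (startsWith(key, "suitability_")) {
      extra <- c(extra, key)
      cfg[[key]] <- over[[key]]
    } else {
      dr_stop("dynrange_unknown_key",
              sprintf("unknown configuration key '%s'", key))
    }
  }
  cfg$config_dir <- config_dir
  cfg$suitability_layers <- extra
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$timesteps) || cfg$timesteps < 1 ||
      cfg$timesteps != round(cfg$timesteps)) {
    dr_stop("dynrange_bad_value", "timesteps must be an integer >= 1")
  }
  cfg$timesteps <- as.integer(cfg$timesteps)
  cfg$randomseed <- as.integer(cfg$randomseed)
  parse_enum(cfg$reproduction_model, "reproduction_model",
             c("Beverton", "Ricker", "RickerAllee"))
  parse_enum(cfg$env_attribute_mode, "env_attribute_mode",
             c("multiplication", "minimum"))
  parse_enum(cfg$env_restriction_mode, "env_restriction_mode",
             c("multiplication", "minimum"))
  parse_enum(cfg$initialise_cells, "initialise_cells",
             c("habitat", "all", "random"))
  if (!is.null(cfg$temperature_unit)) {
    parse_enum(cfg$temperature_unit, "temperature_unit",
               c("Celsius", "Kelvin"))
  }
  stopifnot(is.logical(cfg$input_backup), is.logical(cfg$use_stoch_num),
            is.logical(cfg$use_metabolic_theory))
  structure(cfg, class = "dynrange_config")
}

#' Read a simulation configuration file
#'
#' The configuration file is a headerless two-column CSV of `key,value`
#' records. Unknown keys are rejected; missing keys are filled with their
#' defaults (see [simulation_config()]). The `temperature` key (path to the
#' temperature layer file or folder, relative to `environment_dir`) is
#' required. Recognised keys:
#'
#' * `experiment_name`, `output_dir`, `species_dir`, `environment_dir`,
#'   `input_backup`
#' * `temperature`, `precipitation`, `restriction`, and any number of
#'   `suitability_<name>` keys pointing to layers already expressed as
#'   suitability in \[0, 1\]
#' * `env_attribute_mode`, `env_restriction_mode` (`multiplication` or
#'   `minimum`)
#' * `timesteps`, `randomseed`, `reproduction_model` (`Beverton`, `Ricker`,
#'   `RickerAllee`), `use_metabolic_theory`, `use_stoch_num`,
#'   `initialise_cells` (`habitat`, `all`, `random`)
#' * `temperature_unit` (`Celsius`/`Kelvin`), overriding the automatic unit
#'   detection for temperature layers
#'
#' Validation failures raise classed conditions (`dynrange_missing_file`,
#' `dynrange_unknown_key`, `dynrange_bad_value`, `dynrange_missing_key`).
#'
#' @param path path to the configuration CSV.
#' @return an object of class `dynrange_config`; input paths are interpreted
#'   relative to the configuration file's directory.
#' @export
read_config <- function(path) {
  kv <- read_keyvalue_csv(path)
  if (anyDuplicated(names(kv))) {
    dr_stop("dynrange_bad_value",
            sprintf("duplicated configuration key '%s'",
                    names(kv)[duplicated(names(kv))][1]))
  }
  cfg <- config_defaults()
  extra <- character(0)
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key == "config_dir") next # implied by the file location
    if (startsWith(key, "suitability_")) {
      extra <- c(extra, key)
      cfg[[key]] <- val
      next
    }
    if (!key %in% names(cfg)) {
      dr_stop("dynrange_unknown_key",
              sprintf("unknown configuration key '%s'", key))
    }
    cfg[[key]] <- switch(key,
      timesteps = parse_integer(val, key),
      randomseed = parse_integer(val, key),
      input_backup = parse_flag(val, key),
      use_metabolic_theory = parse_flag(val, key),
      use_stoch_num = parse_flag(val, key),
      val
    )
  }
  if (is.null(cfg$temperature)) {
    dr_stop("dynrange_missing_key",
            "required configuration key 'temperature' is missing")
  }
  cfg$config_dir <- dirname(normalizePath(path))
  cfg$suitability_layers <- extra
  validate_config(cfg)
}

# ---------------------------------------------------------------------------
# Species

species_defaults <- function() {
  list(
    # canonical MTE allometry: rates scale with mass^-1/4 and rise with
    # temperature (E = +0.65 eV); carrying capacity scales with mass^-3/4
    # and falls with temperature (E = -0.65 eV)
    exponent_growrate = -0.25,
    exponent_bevmort = -0.25,
    exponent_carry = -0.75,
    activation_energy_growrate = 0.65,
    activation_energy_bevmort = 0.65,
    activation_energy_carry = -0.65,
    allee = NULL
  )
}

species_numeric_keys <- function() {
  c("carry", "growrate", "bevmort", "max_dispersal_dist",
    "mean_dispersal_dist", "mass",
    "upper_limit_temperature", "lower_limit_temperature",
    "optimum_temperature",
    "upper_limit_precipitation", "lower_limit_precipitation",
    "optimum_precipitation",
    names(species_defaults()))
}

# Temperature unit heuristic: a limit triple whose mean exceeds 150 is
# already Kelvin; otherwise it is Celsius and shifted by 273.15. The
# conversion is therefore idempotent.
to_kelvin <- function(x, unit = NULL) {
  if (is.null(unit)) {
    if (mean(x, na.rm = TRUE) > 150) x else x + 273.15
  } else if (unit == "Kelvin") x else x + 273.15
}

#' Construct validated species parameters
#'
#' Programmatic equivalent of one species file. Temperature limits may be
#' given in degrees Celsius or Kelvin; they are stored in Kelvin (values
#' whose mean exceeds 150 are taken to already be Kelvin, or set
#' `temperature_unit` explicitly). MTE exponents and activation energies
#' default to the canonical allometric values (`-1/4` and `+0.65` eV for
#' rates, `-3/4` and `-0.65` eV for carrying capacity) and may be overridden
#' per species.
#'
#' @param name species label.
#' @param carry carrying capacity, individuals per cell.
#' @param growrate reference reproduction rate per timestep.
#' @param bevmort reference mortality probability per timestep, in \[0, 1\].
#' @param max_dispersal_dist maximum dispersal distance, integer cells >= 1.
#' @param mean_dispersal_dist mean dispersal distance, cells > 0.
#' @param mass body mass in grams.
#' @param lower_limit_temperature,optimum_temperature,upper_limit_temperature
#'   cardinal temperature limits (Celsius or Kelvin; stored as Kelvin).
#' @param lower_limit_precipitation,optimum_precipitation,upper_limit_precipitation
#'   optional cardinal precipitation limits (mm per year).
#' @param temperature_unit `"Celsius"`, `"Kelvin"` or `NULL` (auto-detect).
#' @param ... MTE overrides (`exponent_growrate`, `exponent_bevmort`,
#'   `exponent_carry`, `activation_energy_growrate`,
#'   `activation_energy_bevmort`, `activation_energy_carry`) and the optional
#'   `allee` threshold (individuals, must be below `carry`).
#' @return an object of class `dynrange_species`.
#' @export
species_params <- function(name = "species",
                           carry, growrate, bevmort,
                           max_dispersal_dist, mean_dispersal_dist, mass,
                           lower_limit_temperature, optimum_temperature,
                           upper_limit_temperature,
                           lower_limit_precipitation = NULL,
                           optimum_precipitation = NULL,
                           upper_limit_precipitation = NULL,
                           temperature_unit = NULL, ...) {
  sp <- species_defaults()
  over <- list(...)
  for (key in names(over)) {
    if (!key %in% names(sp)) {
      dr_stop("dynrange_unknown_key",
              sprintf("unknown species key '%s'", key))
    }
    sp[[key]] <- over[[key]]
  }
  sp$name <- name
  sp$carry <- carry
  sp$growrate <- growrate
  sp$bevmort <- bevmort
  sp$max_dispersal_dist <- max_dispersal_dist
  sp$mean_dispersal_dist <- mean_dispersal_dist
  sp$mass <- mass

  tl <- to_kelvin(c(lower_limit_temperature, optimum_temperature,
                    upper_limit_temperature), temperature_unit)
  sp$lower_limit_temperature <- tl[1]
  sp$optimum_temperature <- tl[2]
  sp$upper_limit_temperature <- tl[3]

  prec <- c(!is.null(lower_limit_precipitation),
            !is.null(optimum_precipitation),
            !is.null(upper_limit_precipitation))
  if (any(prec) && !all(prec)) {
    dr_stop("dynrange_bad_value",
            "precipitation limits must be given as a complete triple")
  }
  if (all(prec)) {
    sp$lower_limit_precipitation <- lower_limit_precipitation
    sp$optimum_precipitation <- optimum_precipitation
    sp$upper_limit_precipitation <- upper_limit_precipitation
  }
  validate_species(sp)
}

validate_species <- function(sp) {
  if (!is.finite(sp$mass) || sp$mass <= 0) {
    dr_stop("dynrange_bad_species", "mass must be positive")
  }
  if (sp$bevmort < 0 || sp$bevmort > 1) {
    dr_stop("dynrange_bad_species", "bevmort must lie in [0, 1]")
  }
  if (sp$max_dispersal_dist < 1 ||
      sp$max_dispersal_dist != round(sp$max_dispersal_dist)) {
    dr_stop("dynrange_bad_species",
            "max_dispersal_dist must be an integer >= 1")
  }
  if (sp$mean_dispersal_dist <= 0) {
    dr_stop("dynrange_bad_species", "mean_dispersal_dist must be > 0")
  }
  if (!(sp$lower_limit_temperature < sp$optimum_temperature &&
        sp$optimum_temperature < sp$upper_limit_temperature)) {
    dr_stop("dynrange_bad_species",
            "temperature limits must satisfy lower < optimum < upper")
  }
  if (!is.null(sp$lower_limit_precipitation) &&
      !(sp$lower_limit_precipitation < sp$optimum_precipitation &&
        sp$optimum_precipitation < sp$upper_limit_precipitation)) {
    dr_stop("dynrange_bad_species",
            "precipitation limits must satisfy lower < optimum < upper")
  }
  if (!is.null(sp$allee) && sp$allee >= sp$carry) {
    dr_stop("dynrange_bad_species",
            "allee threshold must be below the carrying capacity")
  }
  structure(sp, class = "dynrange_species")
}

#' Read species parameter files
#'
#' Each CSV file in `dir` describes one species as headerless `key,value`
#' records using the trait argument names `carry`, `growrate`, `bevmort`,
#' `max_dispersal_dist`, `mean_dispersal_dist`, `mass`,
#' `lower_limit_temperature`, `optimum_temperature`,
#' `upper_limit_temperature` and (optionally) the precipitation triple, the
#' MTE overrides and `allee`. An optional `species_name` key labels the
#' species; it defaults to the file name. Temperature limits may be written
#' in Celsius or Kelvin (see [species_params()]).
#'
#' @param dir directory containing at least one species CSV file.
#' @param temperature_unit optional `"Celsius"`/`"Kelvin"` override.
#' @return a list of `dynrange_species` objects, one per file, in file-name
#'   order. The simulator runs species independently, one at a time.
#' @export
read_species <- function(dir, temperature_unit = NULL) {
  if (!dir.exists(dir)) {
    dr_stop("dynrange_missing_file",
            sprintf("species directory not found: %s", dir))
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    dr_stop("dynrange_empty_dir",
            sprintf("no species files in %s", dir))
  }
  lapply(files, function(f) {
    kv <- read_keyvalue_csv(f)
    name <- if ("species_name" %in% names(kv)) {
      kv[["species_name"]]
    } else {
      sub("\\.csv$", "", basename(f))
    }
    kv <- kv[names(kv) != "species_name"]
    unknown <- setdiff(names(kv), species_numeric_keys())
    if (length(unknown) > 0) {
      dr_stop("dynrange_unknown_key",
              sprintf("unknown species key '%s' in %s", unknown[1], f))
    }
    required <- c("carry", "growrate", "bevmort", "max_dispersal_dist",
                  "mean_dispersal_dist", "mass",
                  "lower_limit_temperature", "optimum_temperature",
                  "upper_limit_temperature")
    missing <- setdiff(required, names(kv))
    if (length(missing) > 0) {
      dr_stop("dynrange_missing_key",
              sprintf("species file %s lacks required key '%s'",
                      f, missing[1]))
    }
    args <- lapply(seq_along(kv),
                   function(i) parse_number(kv[[i]], names(kv)[i]))
    names(args) <- names(kv)
    args$name <- name
    args$temperature_unit <- temperature_unit
    do.call(species_params, args)
  })
}

# ---------------------------------------------------------------------------
# Environment

as_stack <- function(x, timesteps, what = "layer") {
  if (is.matrix(x)) {
    array(x, dim = c(nrow(x), ncol(x), timesteps))
  } else if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] < timesteps) {
      dr_stop("dynrange_bad_value",
              sprintf("%s provides %d timesteps, %d required",
                      what, dim(x)[3], timesteps))
    }
    x[, , seq_len(timesteps), drop = FALSE]
  } else {
    dr_stop("dynrange_bad_value",
            sprintf("%s must be a matrix or a [row, col, time] array", what))
  }
}

#' Assemble an environment series from grids
#'
#' Bundles named environmental variables into a common `[row, col, time]`
#' stack. A static variable (plain matrix) is replicated across all
#' timesteps; a 3-d array must provide at least `timesteps` slices (excess
#' trailing slices are ignored). All variables must share one grid shape.
#' Cells that are `NA` in any variable at any time are treated as permanently
#' uninhabitable. The `temperature` variable is required and stored in
#' Kelvin; variables other than `temperature`, `precipitation` and
#' `restriction` are taken to be pre-computed suitability layers and must lie
#' in \[0, 1\].
#'
#' @param vars named list of matrices or `[row, col, time]` arrays; must
#'   contain `temperature`.
#' @param timesteps number of timesteps the series must cover.
#' @param temperature_unit optional `"Celsius"`/`"Kelvin"` override (default:
#'   values with mean above 150 are taken as Kelvin).
#' @return an object of class `dynrange_env` with fields `vars`, `rows`,
#'   `cols`, `timesteps` and the logical `habitable` mask.
#' @export
environment_series <- function(vars, timesteps, temperature_unit = NULL) {
  if (!"temperature" %in% names(vars)) {
    dr_stop("dynrange_missing_key", "environment must include 'temperature'")
  }
  stacks <- mapply(as_stack, vars, what = names(vars),
                   MoreArgs = list(timesteps = timesteps), SIMPLIFY = FALSE)
  shapes <- vapply(stacks, function(s) paste(dim(s)[1:2], collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) {
    dr_stop("dynrange_shape_mismatch",
            sprintf("environment variables differ in grid shape: %s",
                    paste(unique(shapes), collapse = " vs ")))
  }
  tt <- stacks$temperature
  if (any(is.finite(tt))) {
    unit_guess <- if (!is.null(temperature_unit)) temperature_unit
      else if (mean(tt, na.rm = TRUE) > 150) "Kelvin" else "Celsius"
    if (unit_guess == "Celsius") tt <- tt + 273.15
  }
  stacks$temperature <- tt
  for (nm in setdiff(names(stacks),
                     c("temperature", "precipitation", "restriction"))) {
    v <- stacks[[nm]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      dr_stop("dynrange_bad_value",
              sprintf("suitability layer '%s' has values outside [0, 1]", nm))
    }
  }
  if (!is.null(stacks$restriction) &&
      any(stacks$restriction < 0 | stacks$restriction > 1, na.rm = TRUE)) {
    dr_stop("dynrange_bad_value", "restriction values must lie in [0, 1]")
  }
  habitable <- Reduce(`&`, lapply(stacks, function(s) {
    apply(is.finite(s), c(1, 2), all)
  }))
  structure(list(vars = stacks,
                 rows = dim(tt)[1], cols = dim(tt)[2],
                 timesteps = as.integer(timesteps),
                 habitable = habitable),
            class = "dynrange_env")
}

resolve_path <- function(base, p) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

read_layer_files <- function(path, timesteps, what) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    files <- files[natural_order(files)]
    if (length(files) < timesteps) {
      dr_stop("dynrange_bad_value",
              sprintf("%s: %d files found, %d timesteps required",
                      what, length(files), timesteps))
    }
    files <- files[seq_len(timesteps)]
    mats <- lapply(files, read_matrix_csv)
    shapes <- vapply(mats, function(m) paste(dim(m), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1) {
      dr_stop("dynrange_shape_mismatch",
              sprintf("%s: files differ in grid shape", what))
    }
    array(unlist(mats), dim = c(dim(mats[[1]]), timesteps))
  } else if (file.exists(path)) {
    read_matrix_csv(path)
  } else {
    dr_stop("dynrange_missing_file",
            sprintf("%s layer not found: %s", what, path))
  }
}

#' Read the environment layers referenced by a configuration
#'
#' Each referenced layer path may be a single CSV matrix (a static layer,
#' replicated across timesteps) or a folder of CSV matrices, one per
#' timestep, ordered by the first number occurring in their file names.
#' Folders must contain at least `timesteps` files; excess trailing files are
#' ignored.
#'
#' @param config a `dynrange_config`.
#' @return a [environment_series()] object.
#' @export
read_environment <- function(config) {
  env_dir <- resolve_path(config$config_dir, config$environment_dir)
  vars <- list()
  for (key in c("temperature", "precipitation", "restriction",
                config$suitability_layers)) {
    if (is.null(config[[key]])) next
    vars[[key]] <- read_layer_files(resolve_path(env_dir, config[[key]]),
                                    config$timesteps, key)
  }
  environment_series(vars, config$timesteps,
                     temperature_unit = config$temperature_unit)
}

#' Read a full simulation input (configuration, species, environment)
#'
#' Convenience wrapper: reads the configuration file, the species folder and
#' every referenced environment layer, validates their mutual consistency and
#' returns a runnable simulation container.
#'
#' @param path path to the configuration CSV.
#' @return a `dynrange_sim` object; pass it to [run_simulation()].
#' @export
read_input <- function(path) {
  config <- read_config(path)
  species <- read_species(resolve_path(config$config_dir, config$species_dir),
                          temperature_unit = config$temperature_unit)
  env <- read_environment(config)
  simulation_input(config, species, env)
}

#' Assemble a simulation container from its parts
#'
#' @param config a [simulation_config()].
#' @param species one `dynrange_species` or a list of them.
#' @param environment a [environment_series()].
#' @return a `dynrange_sim` object.
#' @export
simulation_input <- function(config, species, environment) {
  if (inherits(species, "dynrange_species")) species <- list(species)
  for (sp in species) {
    if (config$reproduction_model == "Beverton" &&
        !(sp$growrate > sp$bevmort)) {
      dr_stop("dynrange_bad_species",
              sprintf("species '%s': growrate must exceed bevmort under the Beverton model",
                      sp$name))
    }
    if (config$reproduction_model == "RickerAllee" && is.null(sp$allee)) {
      dr_stop("dynrange_bad_species",
              sprintf("species '%s': RickerAllee model requires an 'allee' threshold",
                      sp$name))
    }
    if (!is.null(environment$vars$precipitation) &&
        is.null(sp$lower_limit_precipitation)) {
      dr_stop("dynrange_bad_species",
              sprintf("species '%s' lacks precipitation limits but a precipitation layer is provided",
                      sp$name))
    }
  }
  names(species) <- vapply(species, `[[`, character(1), "name")
  structure(list(config = config, species = species, env = environment),
            class = "dynrange_sim")
}

# ---------------------------------------------------------------------------
# Output

output_variables <- c("abundances", "habitat", "carry", "growrate", "bevmort")

# label used in the TSV 'parameter' column for each output stack
tsv_label <- c(abundances = "abundance", habitat = "habitat",
               carry = "carry", growrate = "growrate", bevmort = "bevmort")

new_output <- function(rows, cols, timesteps) {
  mk <- function() array(0, dim = c(rows, cols, timesteps))
  structure(list(abundances = mk(), habitat = mk(), carry = mk(),
                 growrate = mk(), bevmort = mk()),
            class = "dynrange_output")
}

#' Write simulation output as one long-format TSV file
#'
#' One tab-separated row per (timestep, cell, variable) with header
#' `t  x  y  value  parameter`. Coordinates are 1-based with `x` the column
#' and `y` the row; rows are ordered parameter-major, then by `t`, `y`, `x`.
#' The abundance stack is labelled `abundance` in the `parameter` column; the
#' other stacks keep their names (`habitat`, `carry`, `growrate`, `bevmort`).
#'
#' @param output a `dynrange_output` (from [run_simulation()]).
#' @param path destination file path.
#' @return the path, invisibly.
#' @seealso [read_output_tsv()] for the inverse.
#' @export
write_output_tsv <- function(output, path) {
  dims <- dim(output$abundances)
  rows <- dims[1]; cols <- dims[2]; tn <- dims[3]
  per <- rows * cols * tn
  blocks <- lapply(output_variables, function(v) {
    vals <- as.vector(aperm(output[[v]], c(2, 1, 3))) # x fastest, then y, t
    data.frame(
      t = rep(seq_len(tn), each = rows * cols),
      x = rep(seq_len(cols), times = rows * tn),
      y = rep(rep(seq_len(rows), each = cols), times = tn),
      value = vals,
      parameter = tsv_label[[v]]
    )
  })
  tab <- do.call(rbind, blocks)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    dr_stop("dynrange_unwritable", sprintf("cannot write %s", path))
  }
  invisible(path)
}

#' Read a long-format output TSV back into stacks
#'
#' Inverse of [write_output_tsv()]: re-pivots the long table into the five
#' `[row, col, time]` output stacks.
#'
#' @param path path to a TSV written by [write_output_tsv()].
#' @return a `dynrange_output`.
#' @export
read_output_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  rows <- max(tab$y); cols <- max(tab$x); tn <- max(tab$t)
  out <- new_output(rows, cols, tn)
  label_to_var <- stats::setNames(names(tsv_label), tsv_label)
  for (lab in unique(tab$parameter)) {
    sub <- tab[tab$parameter == lab, ]
    a <- array(0, dim = c(cols, rows, tn))
    a[cbind(sub$x, sub$y, sub$t)] <- sub$value
    out[[label_to_var[[lab]]]] <- aperm(a, c(2, 1, 3))
  }
  out
}
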