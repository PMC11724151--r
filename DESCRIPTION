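Package: dynrange
Title: Process-Based Dynamic Species Range Simulation with Metabolic Rate
    Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grid-based metapopulation simulator for species range
    dynamics. Per-cell demographic rates (reproduction, mortality,
    carrying capacity) are derived from body mass and local temperature
    via the metabolic theory of ecology; habitat suitability follows a
    cardinal (minimum/optimum/maximum) tolerance curve; local populations
    follow Beverton-Holt or Ricker dynamics against suitability-scaled
    carrying capacity; seeds disperse through a truncated
    negative-exponential kernel with absorbing landscape edges;
    recruitment is deterministic or Poisson-stochastic. Ships plain-CSV
    input/output (configuration, species traits, gridded environment
    layers), a synthetic neutral-landscape demonstration, climate-trend
    scenario generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: stats, utils, grDevices, graphics, tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
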