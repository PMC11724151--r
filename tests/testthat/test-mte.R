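# Metabolic scaling of demographic rates.

test_that("normalisation constant inverts the scaling at T_ref", {
  set.seed(11)
  for (i in 1:50) {
    spec <- mte_spec(v = stats::runif(1, 0.1, 10),
                     a = stats::runif(1, -1, 0.5),
                     E = stats::runif(1, -1, 1),
                     T_ref = stats::runif(1, 260, 310))
    mass <- stats::runif(1, 0.01, 1e4)
    b0 <- normalisation_constant(spec, mass)
    expect_equal(b0 * mass^spec$a * exp(-spec$E / (boltzmann_ev * spec$T_ref)),
                 spec$v, tolerance = 1e-13)
    expect_equal(mte_rate(spec, b0, mass, spec$T_ref), spec$v,
                 tolerance = 1e-13)
  }
  # a = 0, E = 0: both factors are 1, so b0 = v
  spec0 <- mte_spec(2.5, 0, 0, 283)
  expect_identical(normalisation_constant(spec0, 100), 2.5)
})

test_that("scaled rate matches independent evaluation 10 K above T_ref", {
  spec <- mte_spec(1.15, -0.25, 0.65, 283.35)
  b0 <- normalisation_constant(spec, 23.82)
  # frozen from v * exp((E/k) * (1/T_ref - 1/T)) evaluated independently
  expect_equal(mte_rate(spec, b0, 23.82, 293.15), 2.8001891954,
               tolerance = 1e-8)
})

test_that("zero activation energy removes the temperature dependence", {
  spec <- mte_spec(1.15, -0.25, 0, 283.35)
  b0 <- normalisation_constant(spec, 23.82)
  temps <- seq(250, 320, by = 5)
  expect_equal(mte_rate(spec, b0, 23.82, temps), rep(1.15, length(temps)),
               tolerance = 1e-13)
})

test_that("rates are monotone in temperature with the sign of E", {
  set.seed(21)
  for (i in 1:100) {
    E <- stats::runif(1, 0.05, 1.2) * sample(c(-1, 1), 1)
    spec <- mte_spec(stats::runif(1, 0.1, 5), stats::runif(1, -1, 0),
                     E, stats::runif(1, 270, 300))
    b0 <- normalisation_constant(spec, 50)
    q <- mte_rate(spec, b0, 50, seq(260, 320, length.out = 25))
    if (E > 0) expect_true(all(diff(q) > 0)) else expect_true(all(diff(q) < 0))
  }
})

test_that("negative mass exponents impose a metabolic mass trade-off", {
  spec <- mte_spec(1.15, -0.25, 0.65, 283.35)
  b0 <- normalisation_constant(spec, 23.82)
  q_small <- mte_rate(spec, b0, 10, 290)
  q_large <- mte_rate(spec, b0, 1000, 290)
  expect_true(q_large < q_small)
})

test_that("demographic fields equal their reference values at the optimum", {
  sp <- test_species()
  temp <- matrix(sp$optimum_temperature, 4, 4)
  f <- scale_demography(sp, temp, use_metabolic_theory = TRUE)
  expect_equal(f$r, matrix(1.15, 4, 4), tolerance = 1e-13)
  expect_equal(f$m_mort, matrix(0.44, 4, 4), tolerance = 1e-13)
  expect_equal(f$K, matrix(1000, 4, 4), tolerance = 1e-13)
})

test_that("bypassing the metabolic theory yields constant fields", {
  sp <- test_species()
  temp <- matrix(stats::runif(16, 260, 320), 4, 4)
  f <- scale_demography(sp, temp, use_metabolic_theory = FALSE)
  expect_identical(f$r, array(1.15, c(4, 4)))
  expect_identical(f$m_mort, array(0.44, c(4, 4)))
  expect_identical(f$K, array(1000, c(4, 4)))
})

test_that("warming raises rates (E > 0) and lowers capacity (E < 0)", {
  sp <- test_species()
  temp <- matrix(c(sp$optimum_temperature, sp$optimum_temperature + 10), 1, 2)
  f <- scale_demography(sp, temp, use_metabolic_theory = TRUE)
  expect_true(f$r[1, 2] > f$r[1, 1])
  expect_true(f$K[1, 2] < f$K[1, 1])
})

test_that("mortality is clamped to 1 and missing cells are uninhabitable", {
  sp <- test_species(bevmort = 0.95)
  temp <- matrix(c(sp$optimum_temperature + 40, NA), 1, 2)
  f <- scale_demography(sp, temp, use_metabolic_theory = TRUE)
  expect_identical(f$m_mort[1, 1], 1) # scaled above 1 -> certain death
  expect_identical(f$r[1, 2], 0)
  expect_identical(f$K[1, 2], 0)
  expect_identical(f$m_mort[1, 2], 1)
})

test_that("the Allee threshold follows the carrying-capacity scaling", {
  sp <- test_species(allee = 100)
  temp <- matrix(c(sp$optimum_temperature, sp$optimum_temperature + 10), 1, 2)
  f <- scale_demography(sp, temp, use_metabolic_theory = TRUE)
  expect_equal(f$A[1, 1], 100, tolerance = 1e-12)
  expect_equal(f$A[1, 2] / f$A[1, 1], f$K[1, 2] / f$K[1, 1],
               tolerance = 1e-12)
})
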