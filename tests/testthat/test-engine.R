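# Process orchestration: initialisation, the per-timestep chain, full runs.

test_that("initialisation modes place populations as documented", {
  K <- matrix(266667, 2, 2)
  h <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  n <- initialise_abundance(K, h, "habitat")
  expect_identical(n[1, 1], 0)
  expect_identical(n[1, 2], 266667)
  expect_identical(n[2, 1], round(266667 * 0.5))
  expect_identical(initialise_abundance(K, h, "all"), round(K))
  # on an all-suitable landscape 'all' and 'habitat' coincide
  h1 <- matrix(1, 2, 2)
  expect_identical(initialise_abundance(K, h1, "habitat"),
                   initialise_abundance(K, h1, "all"))
  set.seed(1)
  occ <- replicate(200, mean(initialise_abundance(K, h1, "random") > 0))
  expect_lt(abs(mean(occ) - 0.5), 0.05)
})

test_that("a population at capacity stays within one individual of it", {
  sim <- uniform_sim(rows = 5, cols = 5, timesteps = 10)
  out <- run_simulation(sim, quiet = TRUE)
  # uniform landscape at the optimum: K_h = carry = 1000 everywhere; the
  # initial abundance equals K_h and the deterministic update holds it there
  expect_true(all(abs(out$abundances - 1000) <= 1))
  expect_equal(out$carry[, , 5], matrix(1000, 5, 5), tolerance = 1e-9)
  expect_equal(out$growrate[, , 5], matrix(1.15, 5, 5), tolerance = 1e-12)
  expect_equal(out$bevmort[, , 5], matrix(0.44, 5, 5), tolerance = 1e-12)
  expect_true(all(out$habitat >= 0 & out$habitat <= 1))
})

test_that("with vanishing dispersal a timestep equals a pure local update", {
  sim <- uniform_sim(rows = 4, cols = 4, timesteps = 1,
                     species = list(mean_dispersal_dist = 0.0005,
                                    max_dispersal_dist = 1))
  state <- initialise_state(sim)
  N0 <- state$N
  out <- run_simulation(sim, quiet = TRUE)
  dem <- scale_demography(sim$species[[1]],
                          sim$env$vars$temperature[, , 1], TRUE)
  h <- compute_suitability(sim, 1, 1)
  step <- beverton_step(N0, dem$r, dem$m_mort,
                        effective_capacity(dem$K, h))
  local_only <- floor(step$survivors_real + step$seeds)
  expect_equal(out$abundances[, , 1], local_only, tolerance = 0)
})

test_that("a run equals a scripted composition of the five process calls", {
  set.seed(404)
  stack <- array(stats::rnorm(3 * 3 * 6, mean = 293.15, sd = 1), c(3, 3, 6))
  for (stoch in c(FALSE, TRUE)) {
    sim <- uniform_sim(stack, timesteps = 6,
                       species = list(mean_dispersal_dist = 1.5,
                                      max_dispersal_dist = 2),
                       config = list(use_stoch_num = stoch, randomseed = 7L))
    out <- run_simulation(sim, quiet = TRUE)
    # straight-line oracle: the same chain written out step by step
    sp <- sim$species[[1]]
    set.seed(7L)
    kernel <- build_kernel(sp$mean_dispersal_dist, sp$max_dispersal_dist)
    h1 <- compute_suitability(sim, 1, 1)
    dem1 <- scale_demography(sp, stack[, , 1], TRUE)
    N <- initialise_abundance(dem1$K, h1, "habitat")
    for (t in 1:6) {
      h <- compute_suitability(sim, 1, t)
      dem <- scale_demography(sp, stack[, , t], TRUE)
      K_h <- effective_capacity(dem$K, h)
      step <- beverton_step(N, dem$r, dem$m_mort, K_h)
      arrivals <- disperse(step$seeds, kernel)
      rec <- if (stoch) recruit(arrivals, TRUE) else arrivals
      N <- floor(step$survivors_real + rec)
      expect_identical(out$abundances[, , t], N)
      expect_equal(out$habitat[, , t], h, tolerance = 1e-14)
      expect_equal(out$carry[, , t], K_h, tolerance = 1e-10)
    }
  }
})

test_that("fixed seeds make stochastic runs bit-identical", {
  sim <- uniform_sim(rows = 6, cols = 6, timesteps = 8,
                     species = list(mean_dispersal_dist = 1,
                                    max_dispersal_dist = 2),
                     config = list(use_stoch_num = TRUE,
                                   initialise_cells = "random"))
  a <- run_simulation(sim, quiet = TRUE)
  b <- run_simulation(sim, quiet = TRUE)
  expect_identical(a$abundances, b$abundances)
  expect_identical(a$carry, b$carry)
})

test_that("extinction is absorbing", {
  sim <- uniform_sim(rows = 3, cols = 3, timesteps = 4)
  state <- initialise_state(sim)
  state$N[] <- 0
  for (t in 1:4) state <- simulate_timestep(state)
  expect_true(all(state$output$abundances == 0))
})

test_that("mean abundance tracks the effective capacity at equilibrium", {
  # start away from equilibrium ('all' on a partially suitable landscape)
  # and let the deterministic dynamics settle
  temp <- matrix(288.45, 4, 4) # suitability 0.7791 for the test species
  sim <- uniform_sim(temp, timesteps = 200,
                     species = list(carry = 1e5),
                     config = list(initialise_cells = "all",
                                   use_metabolic_theory = FALSE))
  out <- run_simulation(sim, quiet = TRUE)
  K_h <- out$carry[1, 1, 200]
  final <- mean(out$abundances[, , 200])
  expect_lt(abs(final - K_h) / K_h, 0.005)
})

test_that("abundance change maps difference the requested timesteps", {
  sim <- uniform_sim(rows = 3, cols = 3, timesteps = 6)
  out <- run_simulation(sim, quiet = TRUE)
  expect_error(abundance_change(out, 3, 3), class = "dynrange_error")
  expect_error(abundance_change(out, 0, 5), class = "dynrange_error")
  expect_error(abundance_change(out, 2, 9), class = "dynrange_error")
  ch <- abundance_change(out, 2, 6)
  expect_identical(ch, out$abundances[, , 6] - out$abundances[, , 2])
  # static environment at equilibrium: essentially no change
  expect_true(all(abs(ch) <= 1))
  hch <- abundance_change(out, 2, 6, variable = "habitat")
  expect_equal(hch, matrix(0, 3, 3))
})

test_that("a cooling trend depresses total abundance when rates rise with T", {
  base <- matrix(293.15, 5, 5)
  stack <- climate_trend_series(base, timesteps = 15, onset = 4,
                                delta_per_step = -0.4)
  # keep the carrying capacity temperature-independent so that the niche
  # response and the reproduction-rate response drive the trend
  sim <- uniform_sim(stack, timesteps = 15,
                     species = list(activation_energy_carry = 0))
  out <- run_simulation(sim, quiet = TRUE)
  expect_lt(sum(abundance_change(out, 3, 15)), 0)
})

test_that("single-timestep runs produce a single output slice", {
  sim <- uniform_sim(rows = 2, cols = 2, timesteps = 1)
  out <- run_simulation(sim, quiet = TRUE)
  expect_identical(dim(out$abundances)[3], 1L)
})
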