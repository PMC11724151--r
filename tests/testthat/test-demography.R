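# Local population dynamics: Beverton-Holt with mortality, Ricker,
# Ricker-Allee.

test_that("effective capacity is carrying capacity times suitability", {
  expect_identical(effective_capacity(266667, 1), 266667)
  expect_identical(effective_capacity(1234, 0), 0)
  expect_identical(effective_capacity(1000, 0.25), 250)
})

test_that("Beverton step matches independent evaluation and edge cases", {
  s <- beverton_step(100, 1.15, 0.44, 1000)
  expect_identical(s$survivors, 56)
  # frozen from 100*1.15 / (1 + 100*(1.15-0.44)/(1000*0.44)), evaluated
  # independently as 50600/511
  expect_equal(s$seeds, 99.0215264188, tolerance = 1e-9)
  # extinction is absorbing
  s0 <- beverton_step(0, 1.15, 0.44, 1000)
  expect_identical(s0$survivors, 0)
  expect_identical(s0$seeds, 0)
  # at the effective capacity the real-valued dynamics are at rest:
  # seeds replace exactly the adults lost to mortality
  K_h <- 755
  s_eq <- beverton_step(K_h, 1.15, 0.44, K_h)
  expect_equal(s_eq$seeds, K_h * 0.44, tolerance = 1e-10)
  expect_equal(s_eq$survivors_real + s_eq$seeds, K_h, tolerance = 1e-10)
})

test_that("Beverton seeds vanish when r <= m or the habitat is unsuitable", {
  expect_identical(beverton_step(100, 0.4, 0.44, 1000)$seeds, 0)
  expect_identical(beverton_step(100, 1.15, 0.44, 0)$seeds, 0)
})

test_that("Ricker step matches the classic map decomposition", {
  s <- ricker_step(100, 0.5, 0.2, 500)
  expect_identical(s$survivors, 80)
  # frozen from 100*exp(0.4) - 80
  expect_equal(s$seeds, 69.1824697641, tolerance = 1e-9)
  # at K_h the raw map returns N, so seeds exactly offset mortality
  s_eq <- ricker_step(500, 0.5, 0.2, 500)
  expect_equal(s_eq$seeds, 500 * 0.2, tolerance = 1e-10)
  expect_identical(ricker_step(0, 0.5, 0.2, 500)$seeds, 0)
  expect_identical(ricker_step(100, 0.5, 0.2, 0)$seeds, 0)
})

test_that("Ricker-Allee step penalises populations below the threshold", {
  s <- ricker_allee_step(50, 0.5, 0.1, 500, 100)
  expect_identical(s$survivors, 45)
  # frozen from 50*exp(0.5*0.9*(-0.1)) - 45
  expect_equal(s$seeds, 2.7998740917, tolerance = 1e-9)
  # exponent zero at N = A and at N = K_h: raw = N
  s_a <- ricker_allee_step(100, 0.5, 0.1, 500, 100)
  expect_equal(s_a$seeds, 100 * 0.1, tolerance = 1e-10)
  s_k <- ricker_allee_step(500, 0.5, 0.1, 500, 100)
  expect_equal(s_k$seeds, 500 * 0.1, tolerance = 1e-10)
  # real-valued composite declines below A (for m > 0)
  below <- ricker_allee_step(50, 0.5, 0.1, 500, 100)
  expect_true(below$survivors_real + below$seeds < 50)
})

test_that("survivors and seeds are never negative across random inputs", {
  set.seed(33)
  for (i in 1:100) {
    N <- sample(0:2000, 1)
    r <- stats::runif(1, 0, 2)
    m <- stats::runif(1)
    K_h <- stats::runif(1, 0, 2000)
    for (fn in list(
      function() beverton_step(N, r, m, K_h),
      function() ricker_step(N, r, m, K_h),
      function() ricker_allee_step(N, r, m, K_h, K_h / 4)
    )) {
      s <- fn()
      expect_true(s$survivors >= 0)
      expect_true(s$seeds >= 0)
      expect_true(s$survivors <= N)
      expect_true(s$survivors_real + s$seeds >=
                    s$survivors + floor(s$seeds) - 1e-9)
    }
  }
})

test_that("negative abundance or invalid mortality are rejected", {
  expect_error(beverton_step(-1, 1.15, 0.44, 1000), class = "dynrange_error")
  expect_error(ricker_step(10, 0.5, 1.2, 500), class = "dynrange_error")
})

iterate_real <- function(N0, r, m, K_h, steps) {
  N <- N0
  path <- numeric(steps)
  for (i in seq_len(steps)) {
    s <- beverton_step(N, r, m, K_h)
    N <- s$survivors_real + s$seeds
    path[i] <- N
  }
  path
}

test_that("real-valued Beverton iteration converges monotonically to K_h", {
  for (N0 in c(1, 100, 2500)) {
    path <- iterate_real(N0, 1.15, 0.44, 1000, 200)
    expect_equal(path[200], 1000, tolerance = 1e-6)
    gaps <- abs(path - 1000)
    expect_true(all(diff(gaps) <= 1e-9))
  }
})

test_that("equilibrium abundance scales linearly with habitat suitability", {
  eq_full <- iterate_real(100, 1.15, 0.44, effective_capacity(1000, 1), 300)
  eq_half <- iterate_real(100, 1.15, 0.44, effective_capacity(1000, 0.5), 300)
  expect_equal(eq_half[300] / eq_full[300], 0.5, tolerance = 1e-9)
})
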