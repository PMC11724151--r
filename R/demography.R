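# Local population dynamics: one within-cell update decomposed into
# survivors (adults remaining after mortality) and seeds (pre-dispersal
# offspring). Seeds stay real-valued here; integerisation happens once,
# after dispersal and recruitment (see the engine).

#' Suitability-scaled carrying capacity
#'
#' `K_h = K * h`: the species carrying capacity scaled by local habitat
#' suitability.
#'
#' @param K carrying capacity (individuals per cell), `>= 0`.
#' @param h habitat suitability in \[0, 1\].
#' @return effective carrying capacity, shaped like the inputs.
#' @export
effective_capacity <- function(K, h) K * h

local_step_result <- function(N, m, seeds) {
  survivors_real <- N * (1 - m)
  seeds[!is.finite(seeds)] <- 0
  seeds <- pmax(seeds, 0)
  list(survivors = floor(survivors_real),
       survivors_real = survivors_real,
       seeds = seeds)
}

check_step_inputs <- function(N, m) {
  if (any(N < 0, na.rm = TRUE)) {
    dr_stop("dynrange_bad_value", "abundance must be non-negative")
  }
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    dr_stop("dynrange_bad_value", "mortality must lie in [0, 1]")
  }
}

#' Beverton-Holt local step with background mortality
#'
#' Recruitment is compensatory:
#' `seeds = N * r / (1 + N * (r - m) / (K_h * m))` for `r > m`, `m > 0` and
#' `K_h > 0`, otherwise 0, while survival removes a fraction `m` of adults.
#' Under this decomposition the real-valued closed-cell composite
#' `N' = N*(1 - m) + seeds` has its unique positive fixed point exactly at
#' `N = K_h`: habitat suitability rescales the equilibrium abundance
#' linearly.
#'
#' All arguments may be equal-shaped matrices; the step is applied cell-wise.
#'
#' @param N current abundance (non-negative).
#' @param r reproduction rate.
#' @param m mortality probability in \[0, 1\].
#' @param K_h effective carrying capacity (see [effective_capacity()]).
#' @return list with `survivors` (floored integer), `survivors_real` and
#'   real-valued `seeds`.
#' @export
beverton_step <- function(N, r, m, K_h) {
  check_step_inputs(N, m)
  r <- rep_len(r, length(N)); m_ <- rep_len(m, length(N))
  k <- rep_len(K_h, length(N))
  seeds <- numeric(length(N))
  dim(seeds) <- dim(N)
  ok <- N > 0 & r > m_ & m_ > 0 & k > 0
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    seeds[ok] <- (N[ok] * r[ok]) /
      (1 + N[ok] * (r[ok] - m_[ok]) / (k[ok] * m_[ok]))
  }
  local_step_result(N, m, seeds)
}

#' Ricker local step
#'
#' The classic Ricker map `raw = N * exp(r * (1 - N / K_h))` decomposed into
#' survivors and seeds so that the reproduce-disperse-recruit process order
#' applies uniformly: `seeds = max(0, raw - N*(1 - m))`. Whenever
#' `raw >= N*(1 - m)` the closed-cell composite equals the classic map, with
#' fixed point `K_h`.
#'
#' @inheritParams beverton_step
#' @return list with `survivors`, `survivors_real` and `seeds`.
#' @export
ricker_step <- function(N, r, m, K_h) {
  check_step_inputs(N, m)
  rr <- rep_len(r, length(N)); kk <- rep_len(K_h, length(N))
  raw <- numeric(length(N))
  dim(raw) <- dim(N)
  ok <- N > 0 & kk > 0
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    raw[ok] <- N[ok] * exp(rr[ok] * (1 - N[ok] / kk[ok]))
  }
  local_step_result(N, m, raw - N * (1 - m))
}

#' Ricker local step with an Allee threshold
#'
#' `raw = N * exp(r * (1 - N/K_h) * ((N - A)/K_h))`: populations below the
#' Allee threshold `A` decline deterministically, populations between `A`
#' and `K_h` grow. `A` must be smaller than the carrying capacity (validated
#' when species files are read).
#'
#' @inheritParams beverton_step
#' @param A Allee threshold (individuals).
#' @return list with `survivors`, `survivors_real` and `seeds`.
#' @export
ricker_allee_step <- function(N, r, m, K_h, A) {
  check_step_inputs(N, m)
  rr <- rep_len(r, length(N)); kk <- rep_len(K_h, length(N))
  aa <- rep_len(A, length(N))
  raw <- numeric(length(N))
  dim(raw) <- dim(N)
  ok <- N > 0 & kk > 0
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    raw[ok] <- N[ok] *
      exp(rr[ok] * (1 - N[ok] / kk[ok]) * ((N[ok] - aa[ok]) / kk[ok]))
  }
  local_step_result(N, m, raw - N * (1 - m))
}

local_step <- function(model, N, r, m, K_h, A = NULL) {
  switch(model,
    Beverton = beverton_step(N, r, m, K_h),
    Ricker = ricker_step(N, r, m, K_h),
    RickerAllee = ricker_allee_step(N, r, m, K_h,
                                    if (is.null(A)) 0 else A),
    dr_stop("dynrange_bad_value",
            sprintf("unknown reproduction model '%s'", model))
  )
}
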