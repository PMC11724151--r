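# Seed dispersal: truncated negative-exponential kernel, absorbing edges,
# deterministic or Poisson recruitment.

#' Build a truncated negative-exponential dispersal kernel
#'
#' The continuous kernel is \eqn{p(r) = \frac{1}{2\pi\alpha^2} e^{-r/\alpha}}
#' with \eqn{2\alpha} the species mean dispersal distance and `r` the distance
#' from the origin cell. It is discretised at cell centres: the weight of the
#' offset `(di, dj)` is proportional to `exp(-d/alpha)` with
#' `d = sqrt(di^2 + dj^2)` in cell units, truncated at the maximum dispersal
#' distance (weights beyond it are 0), and renormalised to sum to one, so the
#' truncation itself never loses seeds -- only the landscape edges do.
#'
#' The maximum dispersal distance must be at least one cell for any
#' emigration to be possible; the mean dispersal distance may be (much)
#' smaller than one, in which case essentially all seeds stay in their natal
#' cell.
#'
#' @param mean_dispersal_dist mean dispersal distance in grid cells (> 0);
#'   the kernel decay length is `alpha = mean_dispersal_dist / 2`.
#' @param max_dispersal_dist maximum dispersal distance in grid cells
#'   (integer >= 1); the kernel is a square window of side
#'   `2 * max_dispersal_dist + 1`.
#' @return an object of class `dynrange_kernel`: list with the weight matrix
#'   `weights`, window `radius` and decay length `alpha`.
#' @export
build_kernel <- function(mean_dispersal_dist, max_dispersal_dist) {
  if (!is.finite(mean_dispersal_dist) || mean_dispersal_dist <= 0) {
    dr_stop("dynrange_bad_value", "mean_dispersal_dist must be > 0")
  }
  if (!is.finite(max_dispersal_dist) || max_dispersal_dist < 1 ||
      max_dispersal_dist != round(max_dispersal_dist)) {
    dr_stop("dynrange_bad_value",
            "max_dispersal_dist must be an integer >= 1")
  }
  R <- as.integer(max_dispersal_dist)
  alpha <- mean_dispersal_dist / 2
  off <- seq(-R, R)
  d <- sqrt(outer(off^2, off^2, `+`))
  w <- exp(-d / alpha)
  w[d > R] <- 0
  # guard against total underflow for vanishing mean distances: the origin
  # weight exp(0) = 1 always survives
  w <- w / sum(w)
  structure(list(weights = w, radius = R, alpha = alpha,
                 mean_dispersal_dist = mean_dispersal_dist,
                 max_dispersal_dist = R),
            class = "dynrange_kernel")
}

#' Redistribute seeds over the landscape
#'
#' Two-dimensional correlation of the seed field with the dispersal kernel.
#' Edges are absorbing: kernel mass falling outside the grid is lost
#' permanently. For any source cell farther than the kernel radius from every
#' edge, arrivals over the whole grid sum exactly to the seeds produced
#' (deterministic dispersal is linear and mass-conserving in the interior).
#'
#' @param seeds non-negative numeric matrix of seeds produced per cell.
#' @param kernel a [build_kernel()] object.
#' @return numeric matrix of arriving seeds per cell (real-valued).
#' @export
disperse <- function(seeds, kernel) {
  if (any(seeds < 0, na.rm = TRUE)) {
    dr_stop("dynrange_bad_value", "seeds must be non-negative")
  }
  seeds[is.na(seeds)] <- 0
  R <- kernel$radius
  w <- kernel$weights
  nr <- nrow(seeds); nc <- ncol(seeds)
  out <- matrix(0, nr, nc)
  for (di in -R:R) {
    r_lo <- max(1, 1 - di); r_hi <- min(nr, nr - di)
    if (r_lo > r_hi) next
    src_r <- r_lo:r_hi
    for (dj in -R:R) {
      wt <- w[di + R + 1, dj + R + 1]
      if (wt == 0) next
      c_lo <- max(1, 1 - dj); c_hi <- min(nc, nc - dj)
      if (c_lo > c_hi) next
      src_c <- c_lo:c_hi
      dst_r <- src_r + di
      dst_c <- src_c + dj
      out[dst_r, dst_c] <- out[dst_r, dst_c] + wt * seeds[src_r, src_c]
    }
  }
  out
}

#' Recruit dispersed seeds into integer offspring
#'
#' Deterministic recruitment rounds the arriving seed mass down; stochastic
#' recruitment draws one independent Poisson variate per cell with the
#' arriving mass as its mean (demographic stochasticity), so the expected
#' stochastic recruitment equals the deterministic seed field. Draws consume
#' the R random number stream in column-major cell order; fixing the seed
#' makes runs bit-reproducible.
#'
#' @param arrivals non-negative numeric matrix of arriving seeds.
#' @param stochastic logical; Poisson draws if `TRUE`, `floor()` otherwise.
#' @return integer-valued matrix of recruits.
#' @export
recruit <- function(arrivals, stochastic = FALSE) {
  if (any(arrivals < 0, na.rm = TRUE)) {
    dr_stop("dynrange_bad_value", "arrivals must be non-negative")
  }
  arrivals[is.na(arrivals)] <- 0
  out <- if (stochastic) {
    as.numeric(stats::rpois(length(arrivals), arrivals))
  } else {
    floor(as.numeric(arrivals))
  }
  dim(out) <- dim(arrivals)
  out
}
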