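#' Cardinal tolerance curve: habitat suitability from an environmental value
#'
#' Maps an environmental value onto habitat suitability in \[0, 1\] using the
#' cardinal (minimum / optimum / maximum) response curve
#'
#' \deqn{h = \frac{v_{max} - v_{env}}{v_{max} - v_{opt}}
#'       \left(\frac{v_{env} - v_{min}}{v_{opt} - v_{min}}\right)
#'       ^{\frac{v_{opt} - v_{min}}{v_{max} - v_{opt}}}}{
#'   h = ((vmax - venv)/(vmax - vopt)) *
#'       ((venv - vmin)/(vopt - vmin))^((vopt - vmin)/(vmax - vopt))}
#'
#' The curve equals 1 exactly at `v_opt`, 0 at both cardinal limits, and is
#' unimodal in between. Values outside `(v_min, v_max)` map to exactly 0
#' (no extrapolated tolerance), missing values map to 0 (uninhabitable), and
#' the result is clamped into \[0, 1\] against floating-point overshoot.
#' Suitabilities below `1e-12` are flushed to 0 so that "suitable cell"
#' predicates are stable.
#'
#' Because the expression only involves differences of `v`, suitability is
#' invariant to expressing temperature limits and environment jointly in
#' degrees Celsius or Kelvin.
#'
#' @param v_env numeric vector/matrix of environmental values.
#' @param v_min,v_opt,v_max cardinal limits, `v_min < v_opt < v_max`.
#' @return numeric object shaped like `v_env` with values in \[0, 1\].
#' @examples
#' tolerance_suitability(10.2, -3.36, 10.2, 15.28) # 1 at the optimum
#' tolerance_suitability(5, -3.36, 10.2, 15.28)
#' @export
tolerance_suitability <- function(v_env, v_min, v_opt, v_max) {
  if (!(is.finite(v_min) && is.finite(v_opt) && is.finite(v_max)) ||
      !(v_min < v_opt && v_opt < v_max)) {
    dr_stop("dynrange_bad_value",
            "tolerance limits must satisfy v_min < v_opt < v_max")
  }
  d <- dim(v_env)
  v <- as.numeric(v_env)
  h <- numeric(length(v))
  inside <- is.finite(v) & v > v_min & v < v_max
  if (any(inside)) {
    expo <- (v_opt - v_min) / (v_max - v_opt)
    vi <- v[inside]
    hi <- ((v_max - vi) / (v_max - v_opt)) *
      ((vi - v_min) / (v_opt - v_min))^expo
    h[inside] <- pmin(pmax(hi, 0), 1)
  }
  h[h < 1e-12] <- 0
  dim(h) <- d
  h
}

#' Combine several suitability layers into one
#'
#' Multi-variable habitat suitability is the cell-wise product
#' (`"multiplication"`) or cell-wise minimum (`"minimum"`) of the per-variable
#' suitability layers. Extra layers that already arrive expressed as
#' suitability are combined in exactly the same way.
#'
#' @param fields list of numeric matrices with identical dimensions, each with
#'   values in \[0, 1\].
#' @param mode `"multiplication"` or `"minimum"` (the default mode used by the
#'   simulator configuration is `"minimum"`).
#' @return a single suitability matrix.
#' @export
combine_suitability <- function(fields, mode = c("minimum", "multiplication")) {
  mode <- match.arg(mode)
  if (!is.list(fields) || length(fields) == 0) {
    dr_stop("dynrange_bad_value", "need at least one suitability field")
  }
  dims <- lapply(fields, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    dr_stop("dynrange_shape_mismatch",
            "suitability fields have differing shapes")
  }
  out <- Reduce(if (mode == "multiplication") `*` else pmin, fields)
  pmin(pmax(out, 0), 1)
}

#' Apply a restriction layer to a suitability field
#'
#' Restriction layers (values in \[0, 1\], e.g. land-use masks) are combined
#' with the habitat suitability field by multiplication or minimum. A `NULL`
#' restriction is a no-op.
#'
#' @param field suitability matrix in \[0, 1\].
#' @param restriction matrix in \[0, 1\] with the same shape, or `NULL`.
#' @param mode `"multiplication"` or `"minimum"`.
#' @return the restricted suitability matrix.
#' @export
apply_restriction <- function(field, restriction = NULL,
                              mode = c("minimum", "multiplication")) {
  mode <- match.arg(mode)
  if (is.null(restriction)) return(field)
  if (!identical(dim(field), dim(restriction))) {
    dr_stop("dynrange_shape_mismatch",
            "restriction layer shape differs from suitability field")
  }
  r <- restriction
  r[is.na(r)] <- 0
  if (any(r < 0 | r > 1)) {
    dr_stop("dynrange_bad_value", "restriction values must lie in [0, 1]")
  }
  combine_suitability(list(field, r), mode = mode)
}
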