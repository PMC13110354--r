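#' Parameter set of the exponentiated transmuted Weibull distribution
#'
#' Bundles the four parameters of the ETWD with their box constraints:
#' scale `alpha > 0`, shape `beta > 0`, transmuting coefficient
#' `lambda` in `[-1, 1]` (quadratic rank transmutation, skews the base
#' Weibull), and exponentiation power `nu > 0`. With `lambda = 0` and
#' `nu = 1` the family collapses to the two-parameter Weibull.
#'
#' @param alpha Scale, positive.
#' @param beta Shape, positive; controls tail weight and skewness.
#' @param lambda Transmuting coefficient in `[-1, 1]`.
#' @param nu Exponentiation power, positive.
#'
#' @return An object of class `etwd_params` (a named list).
#' @examples
#' etwd_params(1, 2, 0, 1)        # Rayleigh with scale 1
#' etwd_params(3, 4, 0.5, 2)
#' @export
etwd_params <- function(alpha, beta, lambda = 0, nu = 1) {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            length(lambda) == 1, length(nu) == 1)
  if (!is.finite(alpha) || alpha <= 0)
    abort("`alpha` (scale) must be a positive finite number.")
  if (!is.finite(beta) || beta <= 0)
    abort("`beta` (shape) must be a positive finite number.")
  if (!is.finite(lambda) || abs(lambda) > 1)
    abort("`lambda` (transmuting coefficient) must lie in [-1, 1].")
  if (!is.finite(nu) || nu <= 0)
    abort("`nu` (exponentiation power) must be a positive finite number.")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         lambda = as.numeric(lambda), nu = as.numeric(nu)),
    class = "etwd_params"
  )
}

#' @export
print.etwd_params <- function(x, ...) {
  cat(sprintf(
    "<etwd_params> alpha = %.4g, beta = %.4g, lambda = %.4g, nu = %.4g\n",
    x$alpha, x$beta, x$lambda, x$nu))
  invisible(x)
}

#' @export
as.double.etwd_params <- function(x, ...) {
  c(alpha = x$alpha, beta = x$beta, lambda = x$lambda, nu = x$nu)
}

#' @rdname etwd_params
#' @param x Object to test or convert.
#' @export
is_etwd_params <- function(x) inherits(x, "etwd_params")

#' Classical sub-models of the ETWD family
#'
#' The four-parameter family contains a number of classical lifetime
#' distributions as constrained special cases. `etwd_submodel()` returns
#' the constraint set that reduces the ETWD to a named family; fixed
#' entries are numeric, free parameters are `NA`.
#'
#' Recognized names: `"weibull"`, `"exponential"`, `"rayleigh"`,
#' `"transmuted_weibull"`, `"exponentiated_weibull"`,
#' `"transmuted_exponential"`, `"transmuted_rayleigh"`,
#' `"exponentiated_exponential"`, `"exponentiated_rayleigh"`,
#' `"exponentiated_transmuted_exponential"`,
#' `"exponentiated_transmuted_rayleigh"`.
#'
#' @param name Name of the sub-family (case-insensitive).
#' @return A tibble with columns `parameter` and `value` (`NA` = free).
#' @examples
#' etwd_submodel("rayleigh")
#' @export
etwd_submodel <- function(name) {
  key <- tolower(gsub("[ -]", "_", name))
  tab <- list(
    weibull                              = c(NA, NA, 0, 1),
    exponential                          = c(NA, 1, 0, 1),
    rayleigh                             = c(NA, 2, 0, 1),
    transmuted_weibull                   = c(NA, NA, NA, 1),
    exponentiated_weibull                = c(NA, NA, 0, NA),
    transmuted_exponential               = c(NA, 1, NA, 1),
    transmuted_rayleigh                  = c(NA, 2, NA, 1),
    exponentiated_exponential            = c(NA, 1, 0, NA),
    exponentiated_rayleigh               = c(NA, 2, 0, NA),
    exponentiated_transmuted_exponential = c(NA, 1, NA, NA),
    exponentiated_transmuted_rayleigh    = c(NA, 2, NA, NA)
  )
  if (!key %in% names(tab))
    abort(sprintf("Unknown sub-model '%s'. See ?etwd_submodel for the list.",
                  name))
  tibble(parameter = c("alpha", "beta", "lambda", "nu"),
         value = tab[[key]])
}

# apply a submodel constraint set to a full parameter vector
.apply_submodel <- function(params, constraints) {
  v <- as.double(params)
  fix <- !is.na(constraints$value)
  v[fix] <- constraints$value[fix]
  etwd_params(v[1], v[2], v[3], v[4])
}
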