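#' Birth-death rate parameters
#'
#' Container for the per-lineage rates of the homogeneous birth-death model
#' of diversification. Every lineage independently speciates at rate
#' `lambda` and goes extinct at rate `mu`; both rates are per species per
#' million years (Myr).
#'
#' @param lambda Speciation rate per species per Myr. Must be finite and
#'   strictly positive.
#' @param mu Extinction rate per species per Myr. Must be finite and
#'   non-negative. `mu > lambda` (a subcritical clade) is permitted: all
#'   formulas remain valid and conditioning on survival keeps the derived
#'   distributions proper.
#' @return An object of class `"bd_params"`: a list with elements `lambda`
#'   and `mu`.
#' @seealso [bd_scenario()], [transform_a()], [survival_probability()]
#' @examples
#' bd_params(0.5107, 0.5)
#' @export
bd_params <- function(lambda, mu) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda > 0,
    is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0
  )
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu)),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf(
    "Birth-death rates: lambda = %g, mu = %g per species per Myr (net %g)\n",
    x$lambda, x$mu, x$lambda - x$mu))
  invisible(x)
}

#' Conditioning scenario: rates, elapsed time and present-day richness
#'
#' Bundles the birth-death rates with the data every conditioned quantity
#' needs: the elapsed time `T` since the origin of the total group (one
#' founding species at time 0) and the number `nT` of species extant at the
#' present, time `T`.
#'
#' @param params A [bd_params()] object.
#' @param T Elapsed time since total-group origin, Myr; `T > 0`.
#' @param nT Present-day (extant) species count; integer `>= 1`.
#' @return An object of class `"bd_scenario"`.
#' @examples
#' # the flagship worked example: 10,000 living species after 500 Myr
#' scn <- bd_scenario(bd_params(0.5107, 0.5), T = 500, nT = 10000)
#' @export
bd_scenario <- function(params, T, nT) {
  stopifnot(inherits(params, "bd_params"),
            is.numeric(T), length(T) == 1L, is.finite(T), T > 0,
            is.numeric(nT), length(nT) == 1L, is.finite(nT), nT >= 1,
            nT == round(nT))
  structure(list(params = params, T = as.numeric(T), nT = as.integer(nT)),
            class = "bd_scenario")
}

#' @export
print.bd_scenario <- function(x, ...) {
  cat(sprintf(
    "Birth-death scenario: lambda = %g, mu = %g, T = %g Myr, nT = %d\n",
    x$params$lambda, x$params$mu, x$T, x$nT))
  invisible(x)
}

# Threshold below which |lambda - mu| is treated as degenerate and the
# limiting (critical-process) forms are used; guards against catastrophic
# cancellation near lambda == mu.
.bd_degenerate_eps <- 1e-9

.check_params <- function(params) {
  if (!inherits(params, "bd_params")) stop("`params` must be a bd_params object")
  invisible(params)
}

.check_scenario <- function(scn) {
  if (!inherits(scn, "bd_scenario")) stop("`scn` must be a bd_scenario object")
  invisible(scn)
}
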