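#' Expected size of a surviving clade
#'
#' Mean of the zero-truncated geometric clade-size law at time `T`,
#' `E(n_T | survive) = 1 / (1 - a_T)`. Under a maximum-likelihood-fitted
#' scenario this equals `nT` exactly, since the ML condition is
#' `a_T = (nT - 1)/nT`.
#'
#' @param params A [bd_params()] object.
#' @param T Elapsed time since clade origin, Myr; `T > 0`.
#' @return Expected extant richness among surviving clades.
#' @examples
#' expected_surviving_size(bd_params(0.014, 0), 500) # Yule: exp(lambda T)
#' @export
expected_surviving_size <- function(params, T) {
  .check_params(params)
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T > 0)
  1 / one_minus_a(params, T)
}

#' Magnitude of the large clade effect
#'
#' A clade conditioned on being larger than its expected size shows extra
#' early lineage accumulation: the initial rate of appearance of surviving
#' lineages is elevated over the background net rate `R = lambda - mu` by
#' the factor
#' \deqn{R_0 / R = (n_T - 1)\,\frac{1 - a_T}{a_T}
#'   \;\simeq\; \frac{n_T}{E(n_T \mid \mathrm{survive})}.}
#' The default is the exact expression; `approx = TRUE` gives the large-`nT`
#' simplification `nT / E(nT | survive)` so the chained approximation is
#' itself testable. A clade of exactly its expected (ML-fitted) size has
#' ratio 1; a clade 10x its expected size has ratio ~10.
#'
#' @param scn A [bd_scenario()] object.
#' @param approx Use the asymptotic `nT / E(nT | survive)` form instead of
#'   the exact one (default `FALSE`).
#' @return The initial-to-background lineage rate ratio.
#' @examples
#' p <- bd_params(0.5107, 0.5)
#' lce_ratio(bd_scenario(p, 500, 10000))  # ~1: clade of expected size
#' lce_ratio(bd_scenario(p, 500, 100000)) # ~10: tenfold outlier
#' @export
lce_ratio <- function(scn, approx = FALSE) {
  .check_scenario(scn)
  om <- one_minus_a(scn$params, scn$T)
  if (approx) {
    scn$nT * om
  } else {
    (scn$nT - 1) * om / (1 - om)
  }
}

#' Observed lineage (surviving-ancestor) diversification rate through time
#'
#' The per-capita growth rate of the expected surviving-lineage count
#' `E(m_t | nT)`, measured like [observed_rate_curve()] but on the "red
#' line". For an oversized clade the initial value is approximately
#' `lce_ratio(scn) * (lambda - mu)` — the large clade effect — and decays
#' towards the background net rate over tens of Myr; it lasts considerably
#' longer than the push of the past although it is smaller in magnitude.
#' The `t = 0` entry is set to the analytic value
#' `lce_ratio(scn) * (lambda - mu)`.
#'
#' @inheritParams observed_rate_curve
#' @return A data frame of class `"bd_rate_curve"` with columns `t_myr`,
#'   `rate`.
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' lineage_rate_curve(scn, step = 5, window = 0.1)
#' @export
lineage_rate_curve <- function(scn, step = 2, window = 0.1, t_max = scn$T) {
  .check_scenario(scn)
  r <- scn$params$lambda - scn$params$mu
  .rate_curve(scn, step, window, t_max, .cond_m_mean,
              t0_value = lce_ratio(scn) * r)
}

#' Large-clade-effect report
#'
#' Bundles the headline quantities of the large clade effect for one
#' scenario: the initial-to-background lineage rate ratio, the expected
#' surviving clade size, and (optionally) the lineage rate curve.
#'
#' @inheritParams lineage_rate_curve
#' @param curve Also compute the lineage rate curve (default `TRUE`).
#' @return A list of class `"lce_report"` with elements `ratio`,
#'   `expected_size`, `scenario` and (if requested) `lineage_curve`.
#' @export
lce_report <- function(scn, step = 2, window = 0.1, t_max = scn$T, curve = TRUE) {
  .check_scenario(scn)
  out <- list(ratio = lce_ratio(scn),
              expected_size = expected_surviving_size(scn$params, scn$T),
              scenario = scn)
  if (curve) out$lineage_curve <- lineage_rate_curve(scn, step, window, t_max)
  structure(out, class = "lce_report")
}

#' @export
print.lce_report <- function(x, ...) {
  cat(sprintf(
    "Large clade effect: ratio %.4g (clade size %d vs expected %.4g)\n",
    x$ratio, x$scenario$nT, x$expected_size))
  invisible(x)
}
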