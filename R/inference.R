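#' Maximum-likelihood speciation rate given extinction rate, age and richness
#'
#' The likelihood of observing `nT` extant species at time `T` in a
#' surviving clade is the zero-truncated geometric clade-size law, which is
#' maximized where its mean matches the observation:
#' `a_T(lambda) = (nT - 1) / nT`. Since `a_T` is strictly increasing in
#' `lambda` for fixed `mu` and `T`, the root is found by monotone
#' bisection, to `|a_T(lambda_hat) - (nT-1)/nT| < 1e-10`.
#'
#' For `mu = 0` the closed form is `lambda_hat = log(nT) / T`.
#'
#' @param mu Extinction rate per species per Myr; `mu >= 0`.
#' @param T Elapsed time since clade origin, Myr; `T > 0`.
#' @param nT Extant species count; integer `>= 2` (`nT = 1` maximizes the
#'   likelihood only in a degenerate limit and is an error).
#' @return The ML speciation rate, per species per Myr.
#' @examples
#' mle_speciation_rate(0.5, 500, 10000) # 0.5107
#' mle_speciation_rate(0.5, 70, 10000)  # 0.6068
#' mle_speciation_rate(0, 500, 1000)    # log(1000)/500 ~= 0.014
#' @export
mle_speciation_rate <- function(mu, T, nT) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0,
            is.numeric(T), length(T) == 1L, is.finite(T), T > 0,
            is.numeric(nT), length(nT) == 1L, is.finite(nT), nT == round(nT))
  if (nT < 2) stop("`nT` must be at least 2: with nT = 1 the likelihood is maximized in a degenerate limit")
  target <- (nT - 1) / nT
  gap <- function(lam) transform_a(bd_params(lam, mu), T) - target
  lo <- 1e-12
  hi <- mu + 10 + log(nT) / T
  while (gap(hi) < 0) hi <- hi * 2 # expand bracket geometrically if needed
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (gap(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, hi)) break
  }
  lam_hat <- (lo + hi) / 2
  if (abs(gap(lam_hat)) > 1e-10)
    warning("bisection did not reach the 1e-10 tolerance on a_T")
  lam_hat
}

#' Scenario with the speciation rate fitted by maximum likelihood
#'
#' Convenience wrapper: builds a [bd_scenario()] whose `lambda` is
#' [mle_speciation_rate()] for the given `mu`, `T` and `nT`. Under this fit
#' the mean of the unconditioned clade-size law at `T` equals `nT` exactly.
#'
#' @inheritParams mle_speciation_rate
#' @return A [bd_scenario()].
#' @examples
#' mle_scenario(0.5, 500, 10000)
#' @export
mle_scenario <- function(mu, T, nT) {
  bd_scenario(bd_params(mle_speciation_rate(mu, T, nT), mu), T, nT)
}

#' Initial observed diversification rate of a surviving clade
#'
#' The "push of the past": a clade conditioned on surviving a long time `T`
#' shows an elevated observed diversification rate at its origin,
#' \deqn{R_0 = (2 - s_T)\,\lambda,}
#' which tends to `2 lambda` when the survival probability `s_T` is small
#' (old clades) and back to `lambda` as `T -> 0`.
#'
#' @param params A [bd_params()] object.
#' @param T Time(s) to the present the clade must survive, Myr. Vectorized.
#' @return Initial observed diversification rate, per species per Myr.
#' @examples
#' p <- bd_params(0.5107, 0.5)
#' potpa_initial_rate(p, 500) # ~1.02, roughly 100x the net rate 0.0107
#' @export
potpa_initial_rate <- function(params, T) {
  .check_params(params)
  stopifnot(is.numeric(T), all(is.finite(T)), all(T > 0))
  (2 - survival_probability(params, T)) * params$lambda
}

.make_grid <- function(T, step) {
  stopifnot(is.numeric(step), length(step) == 1L, is.finite(step), step > 0)
  g <- seq(0, T, by = step)
  if (g[length(g)] < T) g <- c(g, T)
  g
}

#' Diversity and surviving-lineage trajectories with 95% envelopes
#'
#' Evaluates, on a regular time grid, the mean and 2.5/97.5% quantiles of
#' both conditioned laws: standing diversity `n_t` (the "blue line" of a
#' diversity-through-time plot) and surviving-lineage count `m_t` (the
#' "red line"). The divergence of the two curves at the origin is the push
#' of the past; near the present it is the pull of the present.
#'
#' @param scn A [bd_scenario()] object.
#' @param step Reporting grid spacing, Myr (default 2).
#' @return A data frame of class `"bd_trajectory"` with columns `t_myr`,
#'   `n_mean`, `n_lo`, `n_hi`, `m_mean`, `m_lo`, `m_hi`; the scenario is
#'   attached as attribute `"scenario"`.
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' head(trajectory_summary(scn, step = 5))
#' @export
trajectory_summary <- function(scn, step = 2) {
  .check_scenario(scn)
  grid <- .make_grid(scn$T, step)
  rows <- lapply(grid, function(t) {
    dn <- conditional_size_distribution(scn, t)
    dm <- surviving_count_distribution(scn, t)
    c(t_myr = t,
      n_mean = distribution_mean(dn),
      n_lo = distribution_quantile(dn, 0.025),
      n_hi = distribution_quantile(dn, 0.975),
      m_mean = distribution_mean(dm),
      m_lo = distribution_quantile(dm, 0.025),
      m_hi = distribution_quantile(dm, 0.975))
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "scenario") <- scn
  class(out) <- c("bd_trajectory", class(out))
  out
}

# mean standing diversity at time t given nT (internal shortcut)
.cond_n_mean <- function(scn, t) distribution_mean(conditional_size_distribution(scn, t))
.cond_m_mean <- function(scn, t) distribution_mean(surviving_count_distribution(scn, t))

.rate_curve <- function(scn, step, window, t_max, mean_fun, t0_value) {
  stopifnot(window > 0, window <= step)
  grid <- .make_grid(t_max, step)
  rate <- vapply(grid, function(t) {
    if (t == 0) return(t0_value)
    # forward log-difference of the conditional mean; taken backward at T
    t2 <- min(t + window, scn$T)
    t1 <- t2 - window
    (log(mean_fun(scn, t2)) - log(mean_fun(scn, t1))) / window
  }, numeric(1))
  out <- data.frame(t_myr = grid, rate = rate)
  attr(out, "scenario") <- scn
  class(out) <- c("bd_rate_curve", class(out))
  out
}

#' Observed diversification rate through time
#'
#' The per-capita growth rate of expected standing diversity, measured as
#' the forward log-difference of the conditional mean over a short window
#' (default 0.1 Myr): `[log E(n_{t+w} | nT) - log E(n_t | nT)] / w`. The
#' `t = 0` entry is the exact initial-rate value `(2 - s_T) lambda` rather
#' than a finite difference, because the initial spike is analytic and
#' discretizing it would make the headline numbers step-size dependent.
#'
#' @param scn A [bd_scenario()] object.
#' @param step Reporting grid spacing, Myr (default 2).
#' @param window Differencing window, Myr (default 0.1); `window <= step`.
#' @param t_max Last grid time, Myr (default `scn$T`); rate plots usually
#'   focus on the first ~100 Myr where the push of the past lives.
#' @return A data frame of class `"bd_rate_curve"` with columns `t_myr`,
#'   `rate` (per species per Myr).
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' observed_rate_curve(scn, step = 5, window = 0.1)
#' @export
observed_rate_curve <- function(scn, step = 2, window = 0.1, t_max = scn$T) {
  .check_scenario(scn)
  .rate_curve(scn, step, window, t_max, .cond_n_mean,
              t0_value = potpa_initial_rate(scn$params, scn$T))
}

#' Rate-diversity correlation implied by the push of the past
#'
#' Pairs the expected standing diversity with the observed diversification
#' rate at the same time. Conditioning on survival makes high rates
#' coincide with low diversity — a purely statistical correlation that can
#' masquerade as diversity-dependent diversification.
#'
#' @inheritParams observed_rate_curve
#' @return A data frame with columns `diversity` and `rate`, sorted by
#'   increasing diversity.
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' rate_diversity_curve(scn, step = 5)
#' @export
rate_diversity_curve <- function(scn, step = 2, window = 0.1, t_max = scn$T) {
  .check_scenario(scn)
  rc <- observed_rate_curve(scn, step, window, t_max)
  div <- vapply(rc$t_myr, function(t) .cond_n_mean(scn, t), numeric(1))
  out <- data.frame(diversity = div, rate = rc$rate)
  out[order(out$diversity), , drop = FALSE]
}
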