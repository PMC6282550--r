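#' Geometric-law parameter of the clade-size distribution
#'
#' The size `n_t` of a clade that is still alive `t` Myr after originating
#' from a single species follows a zero-truncated geometric distribution
#' with success parameter `1 - a_t`, where
#' \deqn{a_t = \frac{\lambda(1 - e^{-(\lambda-\mu)t})}{\lambda - \mu e^{-(\lambda-\mu)t}}.}
#' `a_t` increases from 0 at `t = 0` towards 1 (supercritical case) or
#' towards `lambda/mu` (subcritical). Near `lambda == mu` the limiting
#' (critical) form `a_t = lambda t / (1 + lambda t)` is used.
#'
#' `1 - a_t` is computed from the cancellation-free form
#' \eqn{(\lambda-\mu)e^{-(\lambda-\mu)t} / (\lambda - \mu e^{-(\lambda-\mu)t})}
#' rather than by subtraction, because `a_t -> 1` at large `t`.
#'
#' @param params A [bd_params()] object.
#' @param t Time(s) since clade origin, Myr; non-negative. Vectorized.
#' @return `a_t` in `[0, 1)`, same length as `t`.
#' @seealso [survival_probability()]; the identity
#'   `survival_probability(p, t) / (1 - transform_a(p, t)) == exp((lambda - mu) * t)`
#'   holds exactly.
#' @examples
#' transform_a(bd_params(0.5107, 0.5), c(0, 100, 500))
#' @export
transform_a <- function(params, t) {
  .check_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) stop("`t` must be finite numeric")
  if (any(t < 0)) stop("`t` must be non-negative")
  1 - one_minus_a(params, t)
}

#' Complement of the geometric-law parameter, computed without cancellation
#'
#' @inheritParams transform_a
#' @return `1 - a_t`, in `(0, 1]`.
#' @export
one_minus_a <- function(params, t) {
  .check_params(params)
  if (!is.numeric(t) || any(!is.finite(t))) stop("`t` must be finite numeric")
  if (any(t < 0)) stop("`t` must be non-negative")
  lam <- params$lambda
  mu <- params$mu
  r <- lam - mu
  if (abs(r) < .bd_degenerate_eps) {
    1 / (1 + lam * t)
  } else if (r > 0) {
    E <- exp(-r * t)
    r * E / (lam - mu * E)
  } else {
    E <- exp(r * t) # r < 0: decays, no overflow
    (mu - lam) / (mu - lam * E)
  }
}

#' Probability that a single founding lineage survives a given duration
#'
#' \deqn{s_{\Delta t} = \frac{\lambda-\mu}{\lambda - \mu e^{-(\lambda-\mu)\Delta t}}}
#' with the critical-process limit `1 / (1 + lambda dt)` when
#' `|lambda - mu|` is degenerate. `s` decreases from 1 at `dt = 0` to
#' `(lambda - mu)/lambda` as `dt -> Inf` (supercritical) or to 0 otherwise.
#'
#' @param params A [bd_params()] object.
#' @param dt Duration(s), Myr; non-negative. Vectorized.
#' @return Survival probability in `(0, 1]`, same length as `dt`.
#' @examples
#' # only ~2.1% of clades under these rates survive 500 Myr
#' survival_probability(bd_params(0.5107, 0.5), 500)
#' @export
survival_probability <- function(params, dt) {
  .check_params(params)
  if (!is.numeric(dt) || any(!is.finite(dt))) stop("`dt` must be finite numeric")
  if (any(dt < 0)) stop("`dt` must be non-negative")
  lam <- params$lambda
  mu <- params$mu
  r <- lam - mu
  if (abs(r) < .bd_degenerate_eps) {
    1 / (1 + lam * dt)
  } else if (r > 0) {
    r / (lam - mu * exp(-r * dt))
  } else {
    E <- exp(r * dt) # r < 0: multiply through by e^{r dt} to avoid overflow
    r * E / (lam * E - mu)
  }
}

#' Median survival time of a clade founded by one species
#'
#' Solves `survival_probability(params, t) == 1/2` in closed form. Under
#' high-turnover rates this is strikingly short: a clade destined to last
#' 500 Myr is a rare outlier.
#'
#' @param params A [bd_params()] object.
#' @return Median survival time in Myr; `Inf` if the long-run survival
#'   probability `(lambda - mu)/lambda` already exceeds 1/2.
#' @examples
#' median_survival_time(bd_params(0.5107, 0.5)) # about 2 Myr
#' @export
median_survival_time <- function(params) {
  .check_params(params)
  lam <- params$lambda
  mu <- params$mu
  r <- lam - mu
  if (abs(r) < .bd_degenerate_eps) return(1 / lam) # 1/(1+lam t)=1/2
  # s = r / (lam - mu e^{-rt}) = 1/2  =>  e^{-rt} = (lam - 2r)/mu
  z <- (lam - 2 * r) / mu
  if (r > 0 && z <= 0) return(Inf) # s_infty = r/lam >= 1/2, median undefined
  -log(z) / r
}

#' Clade-size distribution of a surviving clade (unconditioned on richness)
#'
#' The zero-truncated geometric law
#' \eqn{P(n_t) = (1-a_t)\,a_t^{n_t - 1}} for `n_t >= 1`, i.e. the size of
#' a clade at time `t` given only that it is alive then. Its mean is
#' `1 / (1 - a_t)`.
#'
#' @param params A [bd_params()] object.
#' @param t Time since origin, Myr; `t > 0` (at `t = 0` the clade is its
#'   single founder and the law is a point mass at 1, which is returned).
#' @param max_mass Cumulative probability at which the support is
#'   truncated; the retained mass is at least `max_mass`.
#' @return A [bd_distribution()] whose `tail_bound` is the exact geometric
#'   tail `a_t^N` beyond the stored support.
#' @examples
#' d <- clade_size_distribution(bd_params(0.3, 0.2), 10)
#' distribution_mean(d) # ~= 1 / (1 - a_10)
#' @export
clade_size_distribution <- function(params, t, max_mass = 1 - 1e-12) {
  .check_params(params)
  stopifnot(length(t) == 1L, is.finite(t), t >= 0,
            max_mass > 0, max_mass <= 1)
  om <- one_minus_a(params, t)
  if (om >= 1) return(.point_mass(1L))
  la <- log1p(-om) # log a_t
  n_max <- max(1, ceiling(log1p(-max_mass) / la))
  lp <- log(om) + (seq_len(n_max) - 1) * la
  bd_distribution(1L, lp, tail_bound = exp(n_max * la))
}

# Relative tail tolerance for truncating the infinite sums of the
# richness-conditioned laws.
.bd_tail_tol <- 1e-12

# Log normalizer of the richness-conditioned laws. Bayes' rule here mixes
# two survival conditionings: the prior on n_t conditions on the clade
# being alive at t, while the zero-truncated geometric law of n_T
# conditions on being alive at T. The normalizer therefore carries, besides
# G(nT - 1; 1 - a_T), the probability that a clade alive at t is still
# alive at T,
#   P(survive T | survive t) = s / (s + (1 - a_t)(1 - s)),  s = s_{T-t},
# obtained by summing the extinction probability (1-s)^{n_t} over the
# geometric law of n_t. Without this factor the laws would integrate to
# P(survive T | survive t) < 1 instead of 1.
.log_cond_norm <- function(p, scn, t, om_t, s) {
  log(one_minus_a(p, scn$T)) +
    xlog(scn$nT - 1, log1p(-one_minus_a(p, scn$T))) +
    log(s) - log(s + om_t * (1 - s))
}

#' Distribution of standing diversity conditioned on present-day richness
#'
#' The law of `n_t`, the number of living species at time `t`, in a clade
#' known to have exactly `nT` species at the present `T`. Obtained by Bayes'
#' rule from the zero-truncated geometric clade-size law, a binomial for the
#' number `m_t` of time-`t` species with surviving descendants, and a
#' truncated negative binomial for `nT` given `m_t`:
#' \deqn{P(n_t \mid n_T) = \frac{G(n_t-1;\,1-a_t)}{G(n_T-1;\,1-a_T)}
#'   \sum_{m_t=1}^{n_t} B(m_t;\,n_t,\,s_{T-t})\,
#'   \mathrm{NB}(n_T-m_t;\,m_t;\,1-a_{T-t}).}
#' All pmf evaluations are done in log space with log-gamma binomial
#' coefficients; the interior sum over `m_t` runs `1..min(n_t, nT)` exactly.
#' The support is extended until either the certified zero-truncated
#' geometric tail bound or the exact residual mass (the law integrates to
#' one against the analytic normalizer) falls below 1e-12.
#'
#' @param scn A [bd_scenario()] object.
#' @param t Time in `[0, T]`, Myr. `t = 0` returns a point mass at 1 (the
#'   founder); `t = T` returns a point mass at `nT` (the conditioning
#'   boundary).
#' @return A [bd_distribution()].
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' d <- conditional_size_distribution(scn, 10)
#' distribution_mean(d)
#' @export
conditional_size_distribution <- function(scn, t) {
  .check_scenario(scn)
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  if (t > scn$T) stop("`t` must not exceed the scenario's elapsed time T")
  if (t == 0) return(.point_mass(1L))
  if (t == scn$T) return(.point_mass(scn$nT))
  p <- scn$params
  nT <- scn$nT

  om_t <- one_minus_a(p, t)
  la_t <- log1p(-om_t)          # log a_t
  l1a_t <- log(om_t)            # log (1 - a_t)
  om_Tt <- one_minus_a(p, scn$T - t)
  la_Tt <- log1p(-om_Tt)
  l1a_Tt <- log(om_Tt)
  s <- survival_probability(p, scn$T - t)
  ls <- log(s)
  l1s <- log1p(-s)
  ldenom <- .log_cond_norm(p, scn, t, om_t, s)

  lp <- numeric(256L)
  lcum <- -Inf
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > length(lp)) lp <- c(lp, numeric(length(lp)))
    m <- seq_len(min(n, nT))
    lB <- lchoose(n, m) + xlog(m, ls) + xlog(n - m, l1s)
    lNB <- lchoose(nT - 1, nT - m) + xlog(m, l1a_Tt) + xlog(nT - m, la_Tt)
    lp[n] <- l1a_t + (n - 1) * la_t + logsumexp(lB + lNB)
    lcum <- logaddexp(lcum, lp[n])
    # stop when the certified geometric tail bound, or the exact residual
    # mass under the analytic normalizer, is negligible
    tail_ok <- (n * la_t - ldenom) < log(.bd_tail_tol)
    mass_ok <- (lcum - ldenom) > log1p(-.bd_tail_tol)
    if ((tail_ok || mass_ok) && n >= 2L) break
    if (n > 5e6) stop("support truncation failed to converge")
  }
  bd_distribution(1L, lp[seq_len(n)] - ldenom,
                  tail_bound = max(0, min(1, exp(n * la_t - ldenom))))
}

#' Distribution of surviving-lineage counts conditioned on present richness
#'
#' The law of `m_t`, the number of species at time `t` that will have at
#' least one descendant at the present `T`, given `nT` extant species. This
#' is the "red line" of a lineage-through-time plot. Obtained by summing
#' the joint law over the unknown standing diversity:
#' \deqn{P(m_t \mid n_T) = \frac{\mathrm{NB}(n_T-m_t;\,m_t;\,1-a_{T-t})}
#'   {G(n_T-1;\,1-a_T)} \sum_{n_t=m_t}^{\infty}
#'   B(m_t;\,n_t,\,s_{T-t})\,G(n_t-1;\,1-a_t).}
#' The infinite interior sum is truncated when the zero-truncated-geometric
#' tail bound (valid because the binomial factor never exceeds one) falls
#' below 1e-12 of the accumulated mass; the bound is recorded in the
#' result.
#'
#' With `mu = 0` every species' lineage survives and this law coincides
#' with [conditional_size_distribution()] for all `t`.
#'
#' @inheritParams conditional_size_distribution
#' @param t Time in `[0, T]`, Myr. `t = 0` gives a point mass at 1 (one
#'   founding lineage); `t = T` a point mass at `nT`.
#' @return A [bd_distribution()].
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' distribution_mean(surviving_count_distribution(scn, 10))
#' @export
surviving_count_distribution <- function(scn, t) {
  .check_scenario(scn)
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  if (t > scn$T) stop("`t` must not exceed the scenario's elapsed time T")
  if (t == 0) return(.point_mass(1L))
  if (t == scn$T) return(.point_mass(scn$nT))
  p <- scn$params
  nT <- scn$nT

  om_t <- one_minus_a(p, t)
  la_t <- log1p(-om_t)
  l1a_t <- log(om_t)
  om_Tt <- one_minus_a(p, scn$T - t)
  la_Tt <- log1p(-om_Tt)
  l1a_Tt <- log(om_Tt)
  s <- survival_probability(p, scn$T - t)
  ls <- log(s)
  l1s <- log1p(-s)
  ldenom <- .log_cond_norm(p, scn, t, om_t, s)

  # interior sum over n >= m of B(m; n, s) G(n-1; 1-a_t), chunked; the
  # remaining summand beyond n = N is bounded by the geometric tail a_t^N
  inner_logsum <- function(m) {
    total <- -Inf
    n0 <- m
    chunk <- 256L
    repeat {
      nn <- n0:(n0 + chunk - 1L)
      lB <- lchoose(nn, m) + xlog(m, ls) + xlog(nn - m, l1s)
      total <- logaddexp(total, logsumexp(lB + l1a_t + (nn - 1) * la_t))
      n0 <- n0 + chunk
      if (is.finite(total) && ((n0 - 1L) * la_t < total + log(.bd_tail_tol)))
        break
      if (n0 > 5e7) stop("interior sum failed to converge")
    }
    total
  }

  lp <- numeric(256L)
  lcum <- -Inf
  m <- 0L
  repeat {
    m <- m + 1L
    if (m > length(lp)) lp <- c(lp, numeric(length(lp)))
    lNB <- lchoose(nT - 1, nT - m) + xlog(m, l1a_Tt) + xlog(nT - m, la_Tt)
    lp[m] <- lNB + inner_logsum(m)
    lcum <- logaddexp(lcum, lp[m])
    mass_ok <- (lcum - ldenom) > log1p(-.bd_tail_tol)
    if (m >= nT || (mass_ok && m >= 2L)) break
  }
  bd_distribution(1L, lp[seq_len(m)] - ldenom,
                  tail_bound = max(0, 1 - exp(lcum - ldenom)))
}
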