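#' Crown-group age CDF for a randomly selected pair of extant species
#'
#' Raup-style "random pair" crown groups: the probability `W(t | nT)` that
#' a second randomly selected extant species shares a common ancestor with
#' a first at time `t`. Given `m_t` surviving lineages at `t`, each of the
#' `nT - m_t` species not forced into distinct lineages joins the first
#' species' lineage with probability `1/m_t`, giving
#' `W(t | m_t, nT) = (nT - m_t) / (nT m_t)`; the returned value is this
#' summand posterior-weighted over the surviving-count law
#' [surviving_count_distribution()]. `W` decreases from `(nT-1)/nT` at
#' `t = 0` to 0 at `t = T`, so it is a (backward-time) cumulative
#' distribution for pair-crown ages.
#'
#' @param scn A [bd_scenario()] with `nT >= 2` (no pair exists otherwise).
#' @param t Time in `[0, T]`, Myr.
#' @return A probability.
#' @examples
#' scn <- bd_scenario(bd_params(0.3, 0.2), T = 20, nT = 10)
#' pair_crown_cdf(scn, 5)
#' @export
pair_crown_cdf <- function(scn, t) {
  .check_scenario(scn)
  if (scn$nT < 2) stop("`nT` must be at least 2: no pair of extant species exists")
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  if (t > scn$T) stop("`t` must not exceed the scenario's elapsed time T")
  d <- surviving_count_distribution(scn, t)
  m <- support(d)
  sum(exp(d$log_probs) * (scn$nT - m) / (scn$nT * m))
}

#' Crown-group age density for random pairs of extant species
#'
#' The density `w(t | nT) = -dW/dt` of [pair_crown_cdf()], computed by
#' central finite differences on the supplied grid (one-sided at the
#' endpoints). Densities are per Myr in forward time.
#'
#' @inheritParams pair_crown_cdf
#' @param grid Ordered vector of times in `[0, T]`, Myr.
#' @return Numeric vector of densities, one per grid point.
#' @export
pair_crown_pdf <- function(scn, grid) {
  .check_scenario(scn)
  W <- vapply(grid, function(t) pair_crown_cdf(scn, t), numeric(1))
  -.finite_diff(W, grid)
}

#' Probability density of the first crown-group origin
#'
#' The first crown group of the whole clade is born at the first instant
#' with two surviving lineages; since `m_t = 2` can only be reached from
#' `m_t = 1`, its density is the rate of decay of the one-lineage
#' probability: `u(t) = -d P(m_t = 1 | nT) / dt`, finite-differenced on
#' the grid from pointwise evaluations of the surviving-count law. It
#' integrates to 1 over `(0, T)` (up to quadrature error) because
#' `P(m_0 = 1) = 1` and `P(m_T = 1) = 0` for `nT >= 2`. The first crown
#' group typically emerges just as the push of the past decays.
#'
#' @inheritParams pair_crown_pdf
#' @return Numeric vector of densities (per Myr), one per grid point.
#' @export
first_crown_pdf <- function(scn, grid) {
  .check_scenario(scn)
  if (scn$nT < 2) stop("`nT` must be at least 2 for a crown group to exist")
  p1 <- vapply(grid, function(t) .prob_m_equals_1(scn, t), numeric(1))
  -.finite_diff(p1, grid)
}

# P(m_t = 1 | nT), a single-atom evaluation of the surviving-count law
.prob_m_equals_1 <- function(scn, t) {
  if (t == 0) return(1)
  if (t >= scn$T) return(if (scn$nT == 1L) 1 else 0)
  d <- surviving_count_distribution(scn, t)
  if (d$min_support > 1L) 0 else exp(d$log_probs[1L])
}

# central differences, one-sided at the ends
.finite_diff <- function(y, x) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n, !is.unsorted(x, strictly = TRUE))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

#' Closed-form approximation to the first crown-group origin time
#'
#' Surviving-lineage counts grow early on roughly like
#' `m_t ~ exp((lambda - mu) t)`; setting `m_t = 2` gives the expected wait
#' `ln 2 / (lambda - mu)` from total-group origin to the first crown
#' split. The value is reported in the "million years ago" frame:
#' `t_cg = T - ln2/(lambda - mu)`.
#'
#' @param scn A [bd_scenario()] with `lambda > mu` (no expected exponential
#'   lineage growth otherwise).
#' @return Expected first crown-group age, Ma.
#' @examples
#' scn <- bd_scenario(bd_params(0.5107, 0.5), T = 500, nT = 10000)
#' first_crown_time_approx(scn) # ~435 Ma, i.e. ~65 Myr after origin
#' @export
first_crown_time_approx <- function(scn) {
  .check_scenario(scn)
  r <- scn$params$lambda - scn$params$mu
  if (r <= 0) stop("requires lambda > mu: no expected exponential lineage growth")
  scn$T - log(2) / r
}

#' Net diversification rate implied by a crown-group age
#'
#' Inverse of [first_crown_time_approx()]: from the total-group age `T` and
#' the (approximate) first crown-group age `tcg`, both in consistent Ma
#' frames, the net rate is `ln 2 / (T - tcg)`.
#'
#' @param T Total-group age, Ma.
#' @param tcg First crown-group age, Ma; `0 <= tcg < T`.
#' @return Net diversification rate `lambda - mu`, per species per Myr.
#' @examples
#' diversification_rate_from_crown_age(500, 435.2) # ~0.0107
#' @export
diversification_rate_from_crown_age <- function(T, tcg) {
  stopifnot(is.numeric(T), is.numeric(tcg), length(T) == 1L, length(tcg) == 1L,
            is.finite(T), is.finite(tcg), tcg >= 0)
  if (T <= tcg) stop("`T` must exceed `tcg`")
  log(2) / (T - tcg)
}

#' Crown-group timing table on a regular grid
#'
#' Convenience evaluation of the pair-crown CDF `W`, pair-crown density `w`
#' and first-crown density `u` on one grid, ready for export.
#'
#' @inheritParams pair_crown_cdf
#' @param step Grid spacing, Myr (default 2).
#' @return A data frame with columns `t_myr`, `W`, `w`, `u`; the scenario
#'   is attached as attribute `"scenario"`.
#' @export
crown_timing_table <- function(scn, step = 2) {
  .check_scenario(scn)
  grid <- .make_grid(scn$T, step)
  W <- vapply(grid, function(t) pair_crown_cdf(scn, t), numeric(1))
  out <- data.frame(t_myr = grid,
                    W = W,
                    w = -.finite_diff(W, grid),
                    u = first_crown_pdf(scn, grid))
  attr(out, "scenario") <- scn
  out
}
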