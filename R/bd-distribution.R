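#' Discrete probability distribution over an integer support
#'
#' Light-weight container used by every analytic law in the package: a
#' probability mass function over consecutive integers, stored as
#' log-probabilities so that clade sizes of 10^4 and larger do not
#' underflow. Supports may be truncated; the certified upper bound on the
#' discarded tail mass is carried along as `tail_bound`.
#'
#' @param min_support Smallest integer with (possibly) nonzero mass.
#' @param log_probs Numeric vector of log-probabilities for the consecutive
#'   integers `min_support, min_support + 1, ...`.
#' @param tail_bound Upper bound on the probability mass beyond the stored
#'   support (default 0 for complete distributions).
#' @return An object of class `"bd_distribution"`.
#' @seealso [distribution_mean()], [distribution_quantile()]
#' @export
bd_distribution <- function(min_support, log_probs, tail_bound = 0) {
  stopifnot(length(min_support) == 1L, min_support == round(min_support),
            is.numeric(log_probs), length(log_probs) >= 1L,
            all(log_probs <= 1e-9), tail_bound >= 0)
  structure(list(min_support = as.integer(min_support),
                 log_probs = as.numeric(log_probs),
                 tail_bound = as.numeric(tail_bound)),
            class = "bd_distribution")
}

.point_mass <- function(k) bd_distribution(k, 0)

#' @export
print.bd_distribution <- function(x, ...) {
  s <- support(x)
  cat(sprintf(
    "Discrete distribution on {%d, ..., %d} (%d atoms), total mass %.12f\n",
    s[1L], s[length(s)], length(s), sum(exp(x$log_probs))))
  if (x$tail_bound > 0)
    cat(sprintf("  truncation tail bound: %.3g\n", x$tail_bound))
  invisible(x)
}

#' Support of a discrete distribution
#'
#' @param d A [bd_distribution()] object.
#' @return Integer vector of the stored support values.
#' @export
support <- function(d) {
  stopifnot(inherits(d, "bd_distribution"))
  d$min_support + seq_along(d$log_probs) - 1L
}

#' @export
as.data.frame.bd_distribution <- function(x, ...) {
  data.frame(value = support(x), prob = exp(x$log_probs))
}

#' Expectation of a discrete distribution
#'
#' Expectation over the stored (possibly truncated) support. The truncation
#' error is bounded by `tail_bound * max_support_value` in the worst case;
#' all laws in this package truncate at relative tail mass 1e-12, which
#' makes the error negligible at the scales considered.
#'
#' @param d A [bd_distribution()] object.
#' @return The mean, a real number.
#' @examples
#' distribution_mean(bd_distribution(7, 0)) # point mass at 7
#' @export
distribution_mean <- function(d) {
  stopifnot(inherits(d, "bd_distribution"))
  sum(support(d) * exp(d$log_probs))
}

#' Quantile of a discrete distribution
#'
#' Uses the standard discrete convention: the smallest support value whose
#' cumulative probability reaches `q`. This fixes the 95% envelopes of the
#' trajectory summaries reproducibly.
#'
#' @param d A [bd_distribution()] object.
#' @param q Probability in (0, 1).
#' @return An integer support value.
#' @examples
#' distribution_quantile(bd_distribution(1, log(c(0.5, 0.5))), 0.5) # -> 1
#' @export
distribution_quantile <- function(d, q) {
  stopifnot(inherits(d, "bd_distribution"),
            is.numeric(q), length(q) == 1L, q > 0, q < 1)
  if (length(d$log_probs) == 0L) stop("empty distribution")
  cdf <- cumsum(exp(d$log_probs))
  i <- which(cdf >= q - 1e-15)[1L]
  if (is.na(i)) i <- length(cdf) # q falls in the certified-negligible tail
  support(d)[i]
}

#' @export
mean.bd_distribution <- function(x, ...) distribution_mean(x)

#' @rdname distribution_quantile
#' @param x A [bd_distribution()] object (S3 method alias).
#' @param probs Probabilities passed to [distribution_quantile()].
#' @param ... Unused.
#' @export
quantile.bd_distribution <- function(x, probs = c(0.025, 0.975), ...) {
  vapply(probs, function(q) distribution_quantile(x, q), numeric(1))
}

# ---- internal log-space helpers ------------------------------------------

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logaddexp <- function(x, y) {
  m <- pmax(x, y)
  ifelse(is.finite(m), m + log1p(exp(-abs(x - y))), m)
}

# k * lx with the convention 0 * (-Inf) = 0, needed when a pmf parameter
# sits exactly on the boundary (e.g. s = 1 for a pure-birth process).
xlog <- function(k, lx) ifelse(k == 0, 0, k * lx)
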