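# Canonical scenarios used across the suite.

# Flagship example: 10,000 living species, mu = 0.5, 500 Myr; lambda at
# its published ML value.
fig1_params <- function() bd_params(0.5107, 0.5)
fig1_scenario <- function() bd_scenario(fig1_params(), T = 500, nT = 10000)

# Small, fast scenario used for all Monte Carlo oracle comparisons.
oracle_params <- function() bd_params(0.3, 0.2)
oracle_scenario <- function(nT = 10) bd_scenario(oracle_params(), T = 20, nT = nT)

# Yule scenario with lambda at its ML fit (closed form log(nT)/T).
yule_scenario <- function(T = 50, nT = 100) {
  bd_scenario(bd_params(log(nT) / T, 0), T = T, nT = nT)
}

# Chi-square goodness of fit of observed integer counts against an
# analytic bd_distribution, pooling cells so expected counts are >= 5.
chisq_pvalue <- function(counts, dist) {
  sup <- support(dist)
  probs <- exp(dist$log_probs)
  lo <- min(min(counts), sup[1])
  hi <- max(max(counts), sup[length(sup)])
  vals <- lo:hi
  p <- numeric(length(vals))
  p[match(sup, vals)] <- probs
  obs <- tabulate(counts - lo + 1L, nbins = length(vals))
  # pool from both ends until expected counts reach 5
  n <- length(counts)
  keep_lo <- 1L
  while (sum(p[1:keep_lo]) * n < 5 && keep_lo < length(vals)) keep_lo <- keep_lo + 1L
  keep_hi <- length(vals)
  while (sum(p[keep_hi:length(vals)]) * n < 5 && keep_hi > keep_lo + 1L)
    keep_hi <- keep_hi - 1L
  keep_hi <- max(keep_hi, keep_lo + 1L)
  mid <- if (keep_lo + 1L <= keep_hi - 1L) (keep_lo + 1L):(keep_hi - 1L) else integer(0)
  obs_b <- c(sum(obs[1:keep_lo]), obs[mid], sum(obs[keep_hi:length(vals)]))
  p_b <- c(sum(p[1:keep_lo]), p[mid], sum(p[keep_hi:length(vals)]))
  suppressWarnings(stats::chisq.test(obs_b, p = p_b / sum(p_b))$p.value)
}
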