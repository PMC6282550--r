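test_that("geometric parameter a_t behaves at boundaries and in the critical limit", {
  p <- fig1_params()
  expect_identical(transform_a(p, 0), 0)
  # critical process lambda == mu: a_t = lambda t / (1 + lambda t)
  expect_equal(transform_a(bd_params(0.5, 0.5), 2), 0.5)
  expect_error(transform_a(p, -1), "non-negative")
  # pure birth: a_t = 1 - exp(-lambda t)
  expect_equal(transform_a(bd_params(0.2, 0), 5), 1 - exp(-1), tolerance = 1e-12)
})

test_that("s_t / (1 - a_t) = exp((lambda - mu) t) across a parameter sweep", {
  cases <- expand.grid(lambda = c(0.014, 0.109, 0.3, 0.5107, 0.7),
                       mu = c(0, 0.1, 0.2, 0.5, 0.9),
                       t = c(0.1, 2, 50, 500))
  for (i in seq_len(nrow(cases))) {
    p <- bd_params(cases$lambda[i], cases$mu[i])
    t <- cases$t[i]
    lhs <- survival_probability(p, t) / one_minus_a(p, t)
    expect_equal(lhs, exp((p$lambda - p$mu) * t), tolerance = 1e-10,
                 label = sprintf("identity at lambda=%g mu=%g t=%g",
                                 p$lambda, p$mu, t))
  }
})

test_that("a_t increases and s_dt decreases in time, with the right long-run limits", {
  p <- bd_params(0.5107, 0.5)
  tt <- seq(0, 600, by = 5)
  a <- transform_a(p, tt)
  s <- survival_probability(p, tt)
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(s) < 0))
  expect_equal(survival_probability(p, 1e6), (p$lambda - p$mu) / p$lambda,
               tolerance = 1e-12)
  # subcritical rates are accepted and keep a_t in [0, 1)
  sub <- bd_params(0.2, 0.4)
  expect_true(all(transform_a(sub, tt) >= 0 & transform_a(sub, tt) < 1))
  expect_equal(survival_probability(sub, 0), 1)
})

test_that("published survival percentages and median survival times reproduce", {
  expect_equal(round(survival_probability(fig1_params(), 500), 3), 0.021)
  p4 <- bd_params(mle_speciation_rate(0.1, 500, 1000), 0.1)
  expect_equal(round(100 * survival_probability(p4, 500), 1), 8.2)
  expect_equal(median_survival_time(fig1_params()), 2, tolerance = 0.05)
  expect_equal(median_survival_time(p4), 10.5, tolerance = 0.05)
  # a clade whose long-run survival exceeds 1/2 has no finite median
  expect_identical(median_survival_time(bd_params(1, 0.1)), Inf)
})

test_that("clade-size law is zero-truncated geometric with mean 1/(1 - a_t)", {
  p <- oracle_params()
  d <- clade_size_distribution(p, 10)
  expect_equal(sum(exp(d$log_probs)), 1, tolerance = 1e-9)
  expect_equal(distribution_mean(d), 1 / one_minus_a(p, 10), tolerance = 1e-9)
  expect_identical(d$min_support, 1L)
  # pure birth reduces to the a_t = 1 - exp(-lambda t) geometric
  dy <- clade_size_distribution(bd_params(0.3, 0), 10)
  a <- 1 - exp(-3)
  expect_equal(exp(dy$log_probs[1:5]), (1 - a) * a^(0:4), tolerance = 1e-12)
})

test_that("richness-conditioned diversity law has exact boundaries and unit mass", {
  scn <- oracle_scenario()
  expect_identical(support(conditional_size_distribution(scn, 0)), 1L)
  d_T <- conditional_size_distribution(scn, scn$T)
  expect_identical(support(d_T), 10L)
  expect_error(conditional_size_distribution(scn, 21), "exceed")
  d <- conditional_size_distribution(scn, 10)
  expect_equal(sum(exp(d$log_probs)), 1, tolerance = 1e-9)
  # the large flagship scenario normalizes too (log-gamma arithmetic holds
  # up at nT = 10,000)
  big <- conditional_size_distribution(fig1_scenario(), 250)
  expect_equal(sum(exp(big$log_probs)), 1, tolerance = 1e-9)
})

test_that("surviving-lineage law has exact boundaries and unit mass", {
  scn <- oracle_scenario()
  expect_identical(support(surviving_count_distribution(scn, 0)), 1L)
  expect_identical(support(surviving_count_distribution(scn, scn$T)), 10L)
  dm <- surviving_count_distribution(scn, 10)
  expect_equal(sum(exp(dm$log_probs)), 1, tolerance = 1e-9)
  expect_lte(dm$tail_bound, 1e-9)
  big <- surviving_count_distribution(fig1_scenario(), 250)
  expect_equal(sum(exp(big$log_probs)), 1, tolerance = 1e-9)
})

test_that("with no extinction the diversity and lineage laws coincide", {
  scn <- yule_scenario()
  for (t in c(5, 25, 45)) {
    dn <- conditional_size_distribution(scn, t)
    dm <- surviving_count_distribution(scn, t)
    n <- min(length(dn$log_probs), length(dm$log_probs))
    expect_equal(dn$log_probs[seq_len(n)], dm$log_probs[seq_len(n)],
                 tolerance = 1e-12)
    expect_lt(abs(sum(exp(dn$log_probs)) - sum(exp(dm$log_probs))), 1e-9)
  }
})

test_that("quantiles use the smallest-value-reaching-CDF convention", {
  expect_identical(distribution_quantile(bd_distribution(7, 0), 0.5), 7L)
  two <- bd_distribution(1, log(c(0.5, 0.5)))
  expect_identical(distribution_quantile(two, 0.5), 1L)
  expect_identical(distribution_quantile(two, 0.51), 2L)
  expect_error(distribution_quantile(two, 1.5), "q")
  expect_identical(distribution_mean(bd_distribution(7, 0)), 7)
})

test_that("conditioned lineage mean is non-decreasing on a fine grid", {
  scn <- oracle_scenario()
  grid <- seq(0, scn$T, by = 0.1)
  m_mean <- vapply(grid,
                   function(t) distribution_mean(surviving_count_distribution(scn, t)),
                   numeric(1))
  expect_true(all(diff(m_mean) > -1e-9))
  # spot-check the flagship scenario at coarse spacing
  big <- fig1_scenario()
  mm <- vapply(c(0, 50, 150, 300, 450, 500),
               function(t) distribution_mean(surviving_count_distribution(big, t)),
               numeric(1))
  expect_true(all(diff(mm) > 0))
})
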