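subj <- function(L, sex = "male") subject_profile("s", sex, 1930, L)

test_that("no events means an identity ledger", {
  led <- simulate_rates(rate_schedule(0, 0), subj(40), n0 = 1000)
  expect_equal(as.numeric(led$counts[1]), 1000)
  expect_equal(sum(led$counts[-1]), 0)
  expect_true(all(led$trajectory == 1000))
})

test_that("constant replacement matches the (1-r)^L closed form exactly", {
  r <- 0.001; L <- 73
  expect_equal(surviving_original_fraction(r, L), (1 - r)^L)
  expect_equal(round(surviving_original_fraction(r, L), 5), 0.92957)
  led <- simulate_rates(rate_schedule(r, r), subj(L), n0 = 1)
  expect_equal(as.numeric(led$counts[1]), (1 - r)^L, tolerance = 1e-12)
  expect_equal(sum(led$counts), 1, tolerance = 1e-12)  # count-preserving
  expect_error(surviving_original_fraction(1.2, 10), "\\[0, 1\\]")
})

test_that("full annual replacement leaves only final-year cardiomyocytes", {
  led <- simulate_rates(rate_schedule(1, 1), subj(10), n0 = 500)
  expect_equal(as.numeric(led$counts), c(rep(0, 10), 500))
})

test_that("conservation and non-negativity hold across scenario families", {
  s <- subj(50)
  ledgers <- list(
    constant = simulate_scenario(scenario_constant(2), s, 1e6),
    by_cm_age = simulate_rates(
      rate_schedule(0.02, function(a) 0.1 / a, "by_cm_age"), s, 1e6),
    by_formation_age = simulate_rates(
      rate_schedule(0.02, function(j) 0.005 + 1e-4 * j, "by_formation_age"),
      s, 1e6),
    tvb_exp = simulate_tvb_tvdr(tvb_tvdr_params(0.1, 2.5, 0.5, 1), s, 1e6),
    tvb_bin = simulate_tvb_tvdr(tvb_tvdr_params(0.1, 2.5, 0.5, 1), s, 1e6,
                                survival = "binomial"),
    e2 = simulate_scenario(scenario_e2(0.123, 1.42), s, 1e6),
    time_dep = simulate_scenario(scenario_time_dependent(1, 0.1), s, 1e6),
    hier = simulate_hierarchical(kajstura_synthetic_params(), s),
    age_struct = simulate_age_structured(10, function(a, t) 0.001, s, 1e6))
  for (nm in names(ledgers)) {
    led <- ledgers[[nm]]
    expect_true(all(led$counts >= 0), info = nm)
    expect_equal(
      led$trajectory[led$lifespan + 1],
      led$trajectory[1] + sum(led$formed_per_year) -
        sum(led$destroyed_per_year),
      tolerance = 1e-9, info = nm)
    expect_equal(sum(led$counts), led$trajectory[led$lifespan + 1],
                 tolerance = 1e-9, info = nm)
  }
})

test_that("raising uniform destruction never increases any cohort", {
  s <- subj(40)
  lows <- simulate_rates(rate_schedule(0.03, 0.01), s, 1e6)$counts
  high <- simulate_rates(rate_schedule(0.03, 0.05), s, 1e6)$counts
  expect_true(all(high <= lows + 1e-9))
})

test_that("zero-slope TVB-TVDR reduces exactly to constant replacement", {
  r <- 1.5  # percent
  s <- subj(60)
  tvb <- simulate_tvb_tvdr(tvb_tvdr_params(0, r, 0, r), s, n0 = 1,
                           survival = "binomial")
  ref <- simulate_rates(rate_schedule(r / 100, r / 100), s, n0 = 1)
  expect_equal(as.numeric(tvb$counts), as.numeric(ref$counts),
               tolerance = 1e-12)
  expect_equal(as.numeric(tvb$counts[1]), (1 - r / 100)^60,
               tolerance = 1e-12)
  expect_equal(diff(range(tvb$trajectory)), 0, tolerance = 1e-12)
})

test_that("TVB-TVDR best-fit dynamics reproduce the printed checkpoints", {
  led <- simulate_tvb_tvdr(tvb_tvdr_params(0.10, 2.5, 0.5, 1.0),
                           subject_profile("x", "male", 1900, 70), n0 = 100)
  expect_equal(led$trajectory[21], 129.65, tolerance = 1e-3)
  expect_equal(led$trajectory[71], 87.06, tolerance = 1e-3)
  peak_age <- which.max(led$trajectory) - 1
  expect_gt(max(led$trajectory), 125)
  expect_true(peak_age >= 18 && peak_age <= 30)
})

test_that("rates outside [0,1] are clipped with a warning", {
  expect_warning(led <- simulate_rates(rate_schedule(1.5, 0), subj(1), 10),
                 "clipped")
  expect_equal(led$formed_per_year[1], 10)  # clipped to 100%/yr
})

test_that("age-structured survival honours the half-life definition", {
  s20 <- subj(20)
  huge <- simulate_age_structured(1e6, NULL, s20, n0 = 1000)
  expect_equal(sum(huge$counts), 1000, tolerance = 1e-4)

  half <- simulate_age_structured(20, NULL, s20, n0 = 1000)
  expect_equal(as.numeric(half$counts[1]), 500, tolerance = 1e-9)

  mean_age <- function(h) {
    led <- simulate_age_structured(
      function(t) h(t), NULL,
      subject_profile("m", "male", 1920, 60), n0 = 1,
      formation = function(t, total) 0.05)
    a <- 60 - (0:60)
    sum(a * led$counts) / sum(led$counts)
  }
  base_h <- function(t) 15
  expect_lt(mean_age(function(t) 0.8 * base_h(t)), mean_age(base_h))
  expect_gt(mean_age(function(t) 1.2 * base_h(t)), mean_age(base_h))
  expect_error(simulate_age_structured(-1, NULL, s20), "positive")
})

test_that("turnover series implements both denominator conventions", {
  led <- simulate_rates(rate_schedule(0, 0.01), subj(30), 1e4)
  expect_true(all(turnover_series(led, "adjusting")$turnover_pct == 0))

  led2 <- simulate_rates(rate_schedule(0.02, 0.02), subj(30), 1e4)
  ts <- turnover_series(led2, "constant", constant_value = 2e4)
  expect_equal(ts$turnover_pct, rep(100 * 0.02 * 1e4 / 2e4, 30))
  expect_error(turnover_series(led2, "constant", constant_value = 0), "zero")

  ## declining male count amplifies adjusting-denominator turnover wherever
  ## the trajectory is below the constant reference
  p <- kajstura_synthetic_params()
  ledm <- simulate_hierarchical(p, subject_profile("m", "male", 1900, 90))
  adj <- turnover_series(ledm, "adjusting")$turnover_pct
  con <- turnover_series(ledm, "constant", constant_value = p$n0)$turnover_pct
  below <- ledm$trajectory[1:90] < p$n0
  expect_true(all(adj[below] > con[below]))
})

test_that("hierarchical model reproduces the study's qualitative dynamics", {
  p <- kajstura_synthetic_params()
  ## all-zero formation and apoptosis: trajectory constant at n0
  tab0 <- p$table
  tab0$n_csc <- 0; tab0$apoptotic_frac <- 0
  p0 <- hierarchical_params(tab0, n0 = 1e4)
  led0 <- simulate_hierarchical(p0, subj(30))
  expect_true(all(led0$trajectory == 1e4))
  expect_equal(as.numeric(led0$counts[1]), 1e4)

  ## female counts rise, peak in middle age, and end above youthful levels
  ledf <- simulate_hierarchical(p, subject_profile("f", "female", 1900, 90))
  tr <- ledf$trajectory / ledf$trajectory[1]
  peak_age <- which.max(tr) - 1
  expect_gt(max(tr), 1.1)
  expect_true(peak_age > 30 && peak_age < 75)
  expect_lt(tr[91], max(tr))        # declines after the peak
  expect_gt(tr[91], tr[16])         # but not to levels of youth

  expect_error(simulate_hierarchical(p, subject_profile("o", "male", 1900,
                                                        120)),
               "covering age")
})

test_that("agent-based oracle agrees with the continuous ledger", {
  ## constant replacement on a small instance
  n0 <- 1e4; L <- 30; r <- 0.02
  led <- simulate_rates(rate_schedule(r, r), subj(L), n0)
  ag <- agent_replicates(n0, L, function(y, total) r * total, rep(r, L),
                         reps = 200, seed = 42)
  for (j in c(1, 6, 16, L + 1)) {
    se <- max(ag$se[j], 1e-9)
    expect_lt(abs(ag$mean[j] - led$counts[j]) / se, 3)
  }

  ## hierarchical kinetics scaled to 1e4 agents
  p <- kajstura_synthetic_params(n0 = 1e4)
  s <- subject_profile("a", "male", 1900, 25)
  ledh <- simulate_hierarchical(p, s)
  F_abs <- ledh$formed_per_year
  d_frac <- ledh$destroyed_per_year / ledh$trajectory[1:25]
  agh <- agent_replicates(1e4, 25, function(y, total) F_abs[y],
                          d_frac, reps = 200, seed = 7)
  for (j in c(1, 11, 26)) {
    se <- max(agh$se[j], 1e-9)
    expect_lt(abs(agh$mean[j] - ledh$counts[j]) / se, 3)
  }
})
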