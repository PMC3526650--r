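test_that("closed-form cohort weights match the simulators exactly", {
  s <- subject_profile("s", "male", 1940, 47)
  ## constant replacement
  led <- simulate_scenario(scenario_constant(3), s, 1)
  w <- cmturnover:::weights_constant(0.03, 47)
  expect_equal(as.numeric(led$counts), w, tolerance = 1e-12)
  ## TVB-TVDR, both depletion conventions
  th <- tvb_tvdr_params(0.15, 2.5, -0.3, 4)
  for (sv in c("exponential", "binomial")) {
    ledt <- suppressWarnings(simulate_tvb_tvdr(th, s, 1, survival = sv))
    expect_equal(as.numeric(ledt$counts),
                 cmturnover:::weights_tvb(th, 47, sv), tolerance = 1e-12)
  }
  ## age-varying full replacement
  ledd <- simulate_scenario(scenario_time_dependent(2, 0.05), s, 1)
  expect_equal(as.numeric(ledd$counts),
               cmturnover:::weights_time_dependent(2, 0.05, 47),
               tolerance = 1e-12)
})

test_that("predicted Lambda falls with turnover for post-peak-born subjects", {
  cv <- fixture_decay_curve()
  s <- subject_profile("y", "male", 1970, 35)
  lams <- vapply(c(0.5, 1, 2, 5, 10, 20),
                 function(r) predict_lambda(s, scenario_constant(r), cv,
                                            zero_ploidy()), numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("constant-turnover inversion recovers true rates on their branch", {
  cv <- fixture_pulse_curve()
  s <- subj_prebomb()
  grid <- grid_spec(rate_pct = c(0, 30, 0.01))
  for (r in c(0.5, 2, 10)) {
    lam <- predict_lambda(s, scenario_constant(r), cv, zero_ploidy())
    sol <- solve_constant(s, cv, zero_ploidy(), target_lambda = lam,
                          grid = grid)
    rates <- c(sol$low$rate_pct,
               if (!is.null(sol$high)) sol$high$rate_pct)
    expect_lte(min(abs(rates - r)), 0.01 + 1e-9)
    expect_true(sol$converged)
  }
})

test_that("degenerate inversion is flagged, not raised", {
  flat <- fixture_flat_curve(100)
  s <- subject_profile("d", "male", 1970, 30)
  sol <- solve_constant(s, flat, zero_ploidy(), target_lambda = 0)
  expect_true(sol$degenerate)
  expect_equal(sol$low$rate_pct, 0)
})

test_that("bifurcation appears for pre-pulse subjects only", {
  cv <- fixture_pulse_curve()
  old <- subj_prebomb()
  scan <- bifurcation_scan(old, cv, zero_ploidy(),
                           true_rates_pct = c(4, 6, 10, 15, 20),
                           grid = grid_spec(rate_pct = c(0, 30, 0.01)))
  expect_true(all(scan$bifurcation))
  ## once the bifurcation is fully apparent the high branch tracks the true
  ## input within a couple of grid steps (near the onset the two branches
  ## have not yet separated)
  full <- scan[scan$true_rate_pct >= 6, ]
  expect_true(all(abs(full$high_rate_pct - full$true_rate_pct) <= 0.02 + 1e-9))
  ## while the low branch saturates: it stops rising even as the true input
  ## multiplies
  sat <- scan[scan$true_rate_pct >= 10, ]
  expect_true(all(sat$low_rate_pct < sat$true_rate_pct / 3))
  expect_true(all(diff(sat$low_rate_pct) <= 0))

  ## monotone forward map for a post-peak-born subject: single branch
  young <- subject_profile("y", "male", 1970, 35)
  scan2 <- bifurcation_scan(young, fixture_decay_curve(), zero_ploidy(),
                            true_rates_pct = c(2, 5, 10),
                            grid = grid_spec(rate_pct = c(0, 30, 0.01)))
  expect_true(all(!scan2$bifurcation))
  expect_true(all(abs(scan2$low_rate_pct - scan2$true_rate_pct) <= 0.01 + 1e-9))
})

test_that("exhaustive grid fit equals a brute-force re-enumeration oracle", {
  cv <- fixture_pulse_curve()
  subjects <- list(subject_profile("a", "male", 1945, 55, lambda_c14 = NA),
                   subject_profile("b", "female", 1962, 40, lambda_c14 = NA))
  truth <- tvb_tvdr_params(b_s = 0.2, b_i = 2, d_s = 0.1, d_i = 1)
  for (i in seq_along(subjects))
    subjects[[i]]$lambda_c14 <- predict_lambda(
      subjects[[i]], scenario_tvb_tvdr(truth), cv)
  grid <- grid_spec(b_s = c(0, 0.4, 0.1), b_i = c(1, 3, 0.5),
                    d_s = c(0, 0.2, 0.05), d_i = c(0, 2, 0.5))
  fit <- fit_global(subjects, "tvb_tvdr", grid, cv, refine = "exhaustive")

  ## independent oracle: full enumeration through the simulator route
  pts <- expand.grid(cmturnover:::grid_points(grid))
  sse <- vapply(seq_len(nrow(pts)), function(i) {
    th <- tvb_tvdr_params(pts$b_s[i], pts$b_i[i], pts$d_s[i], pts$d_i[i])
    sum(vapply(subjects, function(su)
      (predict_lambda(su, scenario_tvb_tvdr(th), cv) - su$lambda_c14)^2,
      numeric(1)))
  }, numeric(1))
  expect_equal(fit$sse, min(sse), tolerance = 1e-9)
  best_oracle <- pts[which.min(sse), ]
  expect_equal(unlist(fit$best_params)[c("b_s", "b_i", "d_s", "d_i")],
               unlist(best_oracle)[c("b_s", "b_i", "d_s", "d_i")])
  ## the generating vector lies on the grid, so it is recovered exactly
  expect_equal(fit$best_params$b_s, 0.2)
  expect_equal(fit$best_params$b_i, 2)
  expect_equal(fit$best_params$d_s, 0.1)
  expect_equal(fit$best_params$d_i, 1)
  expect_lt(fit$sse, 1e-12)

  ## coarse-to-fine agrees with the exhaustive optimum on this fixture
  fit2 <- fit_global(subjects, "tvb_tvdr", grid, cv,
                     refine = "coarse_to_fine", coarse_factor = 2)
  expect_equal(fit2$best_params, fit$best_params)
})

test_that("fit results are self-consistent and scenarioA/e2 families fit", {
  cv <- fixture_pulse_curve()
  s <- subject_profile("a", "male", 1950, 50)
  s$lambda_c14 <- predict_lambda(s, scenario_constant(1.2), cv)
  fitA <- fit_global(list(s), "scenarioA",
                     grid_spec(rate_pct = c(0, 3, 0.05)), cv)
  expect_equal(fitA$best_params$rate_pct, 1.2, tolerance = 0.05 + 1e-9)
  recomputed <- sum((vapply(seq_len(nrow(fitA$per_subject)), function(i)
    predict_lambda(s, scenario_constant(fitA$best_params$rate_pct), cv),
    numeric(1)) - fitA$per_subject$observed)^2)
  expect_equal(fitA$sse, recomputed, tolerance = 1e-9)

  s2 <- s
  s2$lambda_c14 <- predict_lambda(s2, scenario_e2(0.1, 1.0), cv)
  fitE <- fit_global(list(s2), "e2",
                     grid_spec(gamma0 = c(0, 0.2, 0.05),
                               gamma1 = c(0, 2, 0.5)), cv)
  expect_equal(fitE$best_params$gamma0, 0.1, tolerance = 1e-9)
  expect_equal(fitE$best_params$gamma1, 1.0, tolerance = 1e-9)
  expect_error(fit_global(list(s), "scenarioA", grid_spec(rate_pct = c(0, 3, 0.05)),
                          cv, observed = NA_real_), "finite observed")
})

test_that("AIC penalizes parameters and validates inputs", {
  for (f in c("default", "per_n", "aicc"))
    expect_gt(aic(100, 12, 4, f), aic(100, 12, 1, f))
  expect_equal(aic(12, 12, 0), 0)
  expect_error(aic(0, 12, 1), "positive")
  expect_error(aic(-5, 12, 1), "positive")
})
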