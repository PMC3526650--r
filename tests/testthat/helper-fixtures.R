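## Shared fixtures: everything is generated in code, nothing downloaded.

fixture_pulse_curve <- function(resolution = "yearly")
  synthetic_bomb_curve(peak_year = 1963, peak_value = 800, rise_years = 8,
                       decay_constant = 0.04, baseline = 0,
                       start_year = 1930, end_year = 2010,
                       resolution = resolution)

## monotone-decaying over any post-peak-born subject's life
fixture_decay_curve <- function()
  synthetic_bomb_curve(peak_year = 1963, peak_value = 600,
                       decay_constant = 0.05, end_year = 2010)

fixture_flat_curve <- function(value = 120) {
  yrs <- 1930:2010
  bomb_curve(yrs, ifelse(yrs < 1955, 0, value))
}

subj_prebomb <- function() subject_profile("old", "male", 1933, 73)
subj_postpeak <- function() subject_profile("young", "male", 1970, 36)

## Discrete agent oracle: Bernoulli deaths, Poisson-rounded births, applied
## simultaneously from the start-of-year state (mirrors the continuous
## bookkeeping in expectation).
agent_replicates <- function(n0, L, formed_abs, death_frac, reps = 200,
                             seed = 42) {
  withr_seed <- function(expr) expr
  set.seed(seed)
  sims <- replicate(reps, {
    counts <- c(n0, integer(L))
    for (y in 1:L) {
      total <- sum(counts)
      dead <- stats::rbinom(y, counts[1:y], death_frac[y])
      formed <- stats::rpois(1, formed_abs(y, total))
      counts[1:y] <- counts[1:y] - dead
      counts[y + 1] <- formed
    }
    counts
  })
  list(mean = rowMeans(sims),
       se = apply(sims, 1, stats::sd) / sqrt(reps))
}
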