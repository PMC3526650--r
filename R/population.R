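## Year-stepped cohort bookkeeping.
##
## One engine drives every scenario family: cohort counts are real-valued
## (the deterministic expectation of the agent process), the time step is one
## year, and each year's formation and destruction are computed from the
## start-of-year state and applied simultaneously. Cohorts are indexed by
## formation offset 0..lifespan, offset 0 being the perinatal pool; the
## cohort formed during event year y (y = 1..lifespan) gets offset y and is
## first exposed to destruction the following year.

HOURS_PER_YEAR <- 8766

clip_rate <- function(x, what = "rate") {
  bad <- x < 0 | x > 1
  if (any(bad, na.rm = TRUE))
    warning(sprintf("%s outside [0,1] per year clipped (%d value%s)",
                    what, sum(bad), if (sum(bad) > 1) "s" else ""),
            call. = FALSE)
  pmin(pmax(x, 0), 1)
}

## formation_fn(y, total, n0, deaths)  -> CM count formed during year y
## survival_fn(y, offsets)            -> per-cohort surviving fraction
run_cohort_engine <- function(n0, lifespan, formation_fn, survival_fn) {
  if (n0 < 0) stop("negative initial count")
  L <- lifespan
  counts <- numeric(L + 1L)
  counts[1L] <- n0
  trajectory <- numeric(L + 1L)
  trajectory[1L] <- n0
  formed_per_year <- destroyed_per_year <- numeric(L)
  if (L > 0) for (y in 1:L) {
    total <- sum(counts)
    s <- survival_fn(y, 0:(y - 1L))
    dead <- counts[1:y] * (1 - s)
    formed <- formation_fn(y, total, n0, sum(dead))
    if (formed < 0) stop("negative computed formation in year ", y)
    counts[1:y] <- counts[1:y] - dead
    if (any(counts[1:y] < 0)) stop("negative cohort count in year ", y)
    counts[y + 1L] <- formed
    formed_per_year[y] <- formed
    destroyed_per_year[y] <- sum(dead)
    trajectory[y + 1L] <- sum(counts)
  }
  new_cohort_ledger(counts, trajectory, formed_per_year, destroyed_per_year)
}

new_cohort_ledger <- function(counts, trajectory, formed, destroyed) {
  L <- length(counts) - 1L
  names(counts) <- 0:L
  x <- structure(list(counts = counts, trajectory = trajectory,
                      formed_per_year = formed,
                      destroyed_per_year = destroyed,
                      lifespan = L),
                 class = "cohort_ledger")
  validate_ledger(x)
  x
}

validate_ledger <- function(x) {
  if (any(x$counts < 0)) stop("negative cohort count in ledger")
  tol <- 1e-9 * max(1, abs(x$trajectory[1]))
  if (abs(sum(x$counts) - x$trajectory[length(x$trajectory)]) > tol)
    stop("ledger counts do not sum to final trajectory value")
  bal <- x$trajectory[1] + sum(x$formed_per_year) - sum(x$destroyed_per_year)
  if (abs(bal - x$trajectory[length(x$trajectory)]) > tol)
    stop("ledger violates conservation identity")
  invisible(x)
}

#' @export
print.cohort_ledger <- function(x, ...) {
  cat(sprintf(
    "<cohort_ledger> lifespan %d y: initial %.4g, final %.4g (%.1f%% of initial), %d surviving cohorts\n",
    x$lifespan, x$trajectory[1], sum(x$counts),
    if (x$trajectory[1] > 0) 100 * sum(x$counts) / x$trajectory[1] else NA,
    sum(x$counts > 0)))
  invisible(x)
}

#' Direct annual formation/destruction schedule (Mode B)
#'
#' Rates are fractions per year. `formation(t)` is evaluated at the
#' start-of-year subject age t = 0..lifespan-1 and applied to the
#' start-of-year total. Destruction is targeted per `targeting`:
#' `"uniform"` applies `destruction(t)` to every cohort; `"by_formation_age"`
#' evaluates `destruction(j)` once at each cohort's formation offset j and
#' applies that fixed rate in every subsequent year; `"by_cm_age"` evaluates
#' `destruction(a)` at the cohort's current cell age a >= 1.
#'
#' @param formation Function of subject age, or a single constant fraction.
#' @param destruction Function per the targeting mode, or a constant.
#' @param targeting Destruction targeting mode.
#' @return An object of class `rate_schedule`.
#' @export
rate_schedule <- function(formation, destruction,
                          targeting = c("uniform", "by_formation_age",
                                        "by_cm_age")) {
  targeting <- match.arg(targeting)
  as_fn <- function(f) if (is.function(f)) f else function(x) rep(f, length(x))
  structure(list(formation = as_fn(formation),
                 destruction = as_fn(destruction), targeting = targeting),
            class = "rate_schedule")
}

#' Simulate a subject under a direct rate schedule
#'
#' @param schedule A [rate_schedule()].
#' @param subject A [subject_profile()].
#' @param n0 Initial CM count (default 5e8 per 10 g tissue).
#' @return A `cohort_ledger`.
#' @export
simulate_rates <- function(schedule, subject, n0 = 5e8) {
  stopifnot(inherits(schedule, "rate_schedule"),
            inherits(subject, "subject_profile"))
  L <- subject$lifespan
  dr <- switch(schedule$targeting,
    uniform = NULL,
    by_formation_age = clip_rate(schedule$destruction(0:L), "destruction rate"),
    by_cm_age = clip_rate(schedule$destruction(seq_len(max(L, 1))),
                          "destruction rate"))
  run_cohort_engine(n0, L,
    formation_fn = function(y, total, n0, deaths)
      clip_rate(schedule$formation(y - 1L), "formation rate") * total,
    survival_fn = function(y, offsets) {
      switch(schedule$targeting,
        uniform = rep(1 - clip_rate(schedule$destruction(y - 1L),
                                    "destruction rate"), length(offsets)),
        by_formation_age = 1 - dr[offsets + 1L],
        by_cm_age = 1 - dr[y - offsets])
    })
}

#' Parameters of the time-varying birth / time-varying death-rate model
#'
#' The four-parameter linear model: the annual formation rate in year y of
#' life is `b_i + b_s * y` and the cohort formed that year is permanently
#' assigned the annual death rate `d_i + d_s * y` (the perinatal cohort,
#' offset 0, gets `d_i`). All values are in the printed units: percent per
#' year for intercepts, percent per year squared for slopes; negative slopes
#' are permitted.
#'
#' @param b_s Formation-rate slope (%/year^2).
#' @param b_i Formation rate at birth (%/year).
#' @param d_s Cohort death-rate slope with subject age at formation (%/year^2).
#' @param d_i Death rate of the birth cohort (%/year).
#' @return An object of class `tvb_tvdr_params`.
#' @export
tvb_tvdr_params <- function(b_s, b_i, d_s, d_i) {
  stopifnot(is.finite(b_s), is.finite(b_i), is.finite(d_s), is.finite(d_i))
  structure(list(b_s = b_s, b_i = b_i, d_s = d_s, d_i = d_i),
            class = "tvb_tvdr_params")
}

#' Simulate the TVB-TVDR model
#'
#' Formation in year y is `(b_i + b_s*y)/100` of the formation basis
#' (default: the count at birth, the full-replacement bookkeeping under
#' which the published trajectory checkpoints are reproduced). Each cohort
#' is depleted every subsequent year at its assigned rate; the default
#' depletion treats the annual death rate as an exponential hazard
#' (`exp(-d)` surviving), `"binomial"` uses `1 - d`.
#'
#' @param theta A [tvb_tvdr_params()].
#' @param subject A [subject_profile()].
#' @param n0 Initial CM count.
#' @param survival Within-year depletion convention.
#' @param formation_basis Count the formation rate multiplies.
#' @return A `cohort_ledger`.
#' @export
simulate_tvb_tvdr <- function(theta, subject, n0 = 5e8,
                              survival = c("exponential", "binomial"),
                              formation_basis = c("initial", "current")) {
  stopifnot(inherits(theta, "tvb_tvdr_params"),
            inherits(subject, "subject_profile"))
  survival <- match.arg(survival)
  formation_basis <- match.arg(formation_basis)
  L <- subject$lifespan
  delta <- (theta$d_i + theta$d_s * (0:L)) / 100
  surv <- if (survival == "exponential") exp(-pmax(delta, 0))
          else 1 - clip_rate(delta, "death rate")
  run_cohort_engine(n0, L,
    formation_fn = function(y, total, n0, deaths) {
      b <- clip_rate((theta$b_i + theta$b_s * y) / 100, "formation rate")
      b * if (formation_basis == "initial") n0 else total
    },
    survival_fn = function(y, offsets) surv[offsets + 1L])
}

#' Simulate the hierarchical stem-cell kinetics model (Mode A)
#'
#' Annual formation is computed from the stem-cell compartment: the number
#' of cycling stem cells times the number of mitosis cycles fitting in a
#' year (8766 h / mitosis duration), amplified by `2^E` transit
#' amplification, where all parameters are age- and sex-specific table
#' lookups. Annual destruction is the instantaneous apoptotic fraction
#' times the apoptosis events per year (8766 h / apoptosis duration),
#' applied uniformly across cohorts. The formation formula is pluggable via
#' `formation_fn(p)` receiving the named parameter list for the year.
#'
#' @param params A [hierarchical_params()] table.
#' @param subject A [subject_profile()].
#' @param n0 Initial CM count; defaults to the table's `n0`.
#' @param formation_fn Optional replacement formation formula.
#' @return A `cohort_ledger`.
#' @export
simulate_hierarchical <- function(params, subject, n0 = NULL,
                                  formation_fn = NULL) {
  stopifnot(inherits(params, "hierarchical_params"),
            inherits(subject, "subject_profile"))
  if (is.null(n0)) n0 <- params$n0
  L <- subject$lifespan
  if (is.null(formation_fn))
    formation_fn <- function(p)
      p$n_csc * p$cyc_frac * (HOURS_PER_YEAR / p$mitosis_hours) *
        2^p$expansion_exponent
  pget <- function(age) param_at(params, age, subject$sex)
  run_cohort_engine(n0, L,
    formation_fn = function(y, total, n0, deaths) {
      f <- formation_fn(pget(y - 1L))
      if (!is.finite(f) || f < 0) stop("invalid formation at age ", y - 1L)
      f
    },
    survival_fn = function(y, offsets) {
      p <- pget(y - 1L)
      d <- clip_rate(p$apoptotic_frac * (HOURS_PER_YEAR / p$apoptosis_hours),
                     "apoptotic destruction rate")
      rep(1 - d, length(offsets))
    })
}

#' Simulate the age-structured survival model
#'
#' End-of-life CM age distributions driven by an exponential half-life and
#' an optional additional mortality deduction: in each year at subject age
#' t, every cohort retains the fraction `2^(-1/h(t))` and additionally loses
#' the fraction `mortality(a, t)` (cell age a). New CM formation is off by
#' default; supply `formation(t, total)` (a count) to enable it.
#'
#' @param halflife CM half-life in years: a constant or function of subject
#'   age; must be positive everywhere.
#' @param mortality Optional function `(a, t) -> fraction destroyed`.
#' @param subject A [subject_profile()].
#' @param n0 Initial CM count.
#' @param formation Optional function `(t, total) -> count formed`.
#' @return A `cohort_ledger`.
#' @export
simulate_age_structured <- function(halflife, mortality = NULL, subject,
                                    n0 = 5e8, formation = NULL) {
  stopifnot(inherits(subject, "subject_profile"))
  hfun <- if (is.function(halflife)) halflife else function(t) halflife
  L <- subject$lifespan
  if (L > 0 && any(vapply(0:(L - 1), hfun, numeric(1)) <= 0))
    stop("half-life must be positive at every age")
  run_cohort_engine(n0, L,
    formation_fn = function(y, total, n0, deaths)
      if (is.null(formation)) 0 else formation(y - 1L, total),
    survival_fn = function(y, offsets) {
      t <- y - 1L
      s <- rep(2^(-1 / hfun(t)), length(offsets))
      if (!is.null(mortality))
        s <- s * (1 - clip_rate(mortality(y - offsets, t), "mortality"))
      s
    })
}

#' Annual turnover series from a ledger
#'
#' Turnover in year y is the number of newly formed CM divided by the number
#' of CM present that year, in percent. The denominator is either a fixed
#' constant count or the adjusting start-of-year total from the trajectory.
#'
#' @param ledger A `cohort_ledger`.
#' @param denominator `"adjusting"` or `"constant"`.
#' @param constant_value The fixed count when `denominator = "constant"`.
#' @return A data frame with columns `age` (1..lifespan, the year of life)
#'   and `turnover_pct`.
#' @export
turnover_series <- function(ledger, denominator = c("adjusting", "constant"),
                            constant_value = NULL) {
  stopifnot(inherits(ledger, "cohort_ledger"))
  denominator <- match.arg(denominator)
  L <- ledger$lifespan
  if (L == 0) return(data.frame(age = integer(), turnover_pct = numeric()))
  denom <- if (denominator == "constant") {
    if (is.null(constant_value)) stop("constant denominator needs a value")
    rep(constant_value, L)
  } else {
    ledger$trajectory[1:L]
  }
  if (any(denom == 0)) stop("zero denominator in turnover series")
  data.frame(age = 1:L,
             turnover_pct = 100 * ledger$formed_per_year / denom)
}

#' Surviving fraction of the original cohort under constant replacement
#'
#' Closed form `(1 - rate)^years`; the oracle against which the
#' constant-replacement simulations are checked.
#'
#' @param rate Annual replacement fraction in `[0, 1]`.
#' @param years Non-negative integer.
#' @return The surviving fraction.
#' @export
surviving_original_fraction <- function(rate, years) {
  if (any(rate < 0 | rate > 1)) stop("rate must be in [0, 1]")
  if (any(years < 0)) stop("years must be non-negative")
  (1 - rate)^years
}

#' Write / read a cohort ledger
#'
#' The TSV holds `formation_offset,surviving_count`; the JSON sidecar (same
#' path with extension `.json`) holds the trajectory and per-year tallies.
#'
#' @param ledger A `cohort_ledger`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "cohort_ledger"))
  utils::write.table(
    data.frame(formation_offset = 0:ledger$lifespan,
               surviving_count = as.numeric(ledger$counts)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(lifespan = ledger$lifespan, trajectory = ledger$trajectory,
         formed_per_year = ledger$formed_per_year,
         destroyed_per_year = ledger$destroyed_per_year),
    paste0(sub("\\.tsv$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
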