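#' Age- and sex-specific hierarchical kinetics parameter table
#'
#' Wraps a parameter table with columns
#' `age,sex,n_csc,cyc_frac,mitosis_hours,expansion_exponent,apoptotic_frac,
#' apoptosis_hours,halflife_years` (stem-cell count per 10 g, instantaneous
#' cycling fraction, mitosis duration, transit-amplification exponent,
#' instantaneous apoptotic CM fraction, apoptosis duration, CM half-life).
#' Lookups linearly interpolate between the listed ages, per sex.
#' `multipliers` scale a parameter uniformly across all ages, the mechanism
#' used for sensitivity sweeps.
#'
#' @param table The parameter data frame.
#' @param n0 Initial CM count per 10 g tissue (default 5e8).
#' @param multipliers Named list of per-parameter scaling factors.
#' @return An object of class `hierarchical_params`.
#' @export
hierarchical_params <- function(table, n0 = 5e8, multipliers = list()) {
  need <- c("age", "sex", "n_csc", "cyc_frac", "mitosis_hours",
            "expansion_exponent", "apoptotic_frac", "apoptosis_hours",
            "halflife_years")
  if (!all(need %in% names(table)))
    stop("parameter table missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (any(table$cyc_frac < 0 | table$cyc_frac > 1) ||
      any(table$apoptotic_frac < 0 | table$apoptotic_frac > 1))
    stop("fractions must lie in [0, 1]")
  if (any(table$mitosis_hours <= 0 | table$apoptosis_hours <= 0 |
          table$halflife_years <= 0))
    stop("durations must be positive")
  if (any(table$expansion_exponent < 0))
    stop("expansion exponent must be >= 0")
  if (length(multipliers) && any(unlist(multipliers) < 0))
    stop("multipliers must be >= 0")
  structure(list(table = table, n0 = n0, multipliers = multipliers,
                 apoptosis_override = NULL),
            class = "hierarchical_params")
}

#' @export
print.hierarchical_params <- function(x, ...) {
  cat(sprintf("<hierarchical_params> %d rows, sexes {%s}, ages %g-%g, n0 %.3g\n",
              nrow(x$table), paste(unique(x$table$sex), collapse = ","),
              min(x$table$age), max(x$table$age), x$n0))
  if (length(x$multipliers))
    cat("  multipliers:", paste(sprintf("%s x%g", names(x$multipliers),
        unlist(x$multipliers)), collapse = ", "), "\n")
  invisible(x)
}

#' Interpolated parameter values at one age and sex
#'
#' @param params A [hierarchical_params()].
#' @param age Subject age in years.
#' @param sex `"male"` or `"female"`.
#' @return A named list with one value per kinetic parameter, multipliers
#'   applied.
#' @export
param_at <- function(params, age, sex) {
  tab <- params$table[params$table$sex == sex, ]
  if (nrow(tab) == 0)
    stop("no parameter rows for sex '", sex, "'")
  if (age < min(tab$age) || age > max(tab$age))
    stop("no parameter rows for sex '", sex, "' covering age ", age)
  cols <- c("n_csc", "cyc_frac", "mitosis_hours", "expansion_exponent",
            "apoptotic_frac", "apoptosis_hours", "halflife_years")
  out <- lapply(cols, function(cl)
    stats::approx(tab$age, tab[[cl]], xout = age)$y)
  names(out) <- cols
  for (nm in names(params$multipliers))
    out[[nm]] <- out[[nm]] * params$multipliers[[nm]]
  if (!is.null(params$apoptosis_override))
    out$apoptotic_frac <- params$apoptosis_override(age)
  out
}

#' Synthetic hierarchical parameter table
#'
#' A deterministic stand-in for the age/sex regression outputs of the
#' histology-based stem-cell kinetics literature, calibrated once to the
#' qualitative conditions those studies report: young-adult male turnover
#' near 7%/year rising roughly three-fold by old age with a slowly
#' declining total count; higher female turnover with a total count that
#' rises, peaks in middle age and then declines without falling below
#' youthful levels; a transit-amplification exponent near 5 (so a 20%
#' change in the exponent doubles or halves formation); mitosis 26 h,
#' apoptosis 4 h; CM half-life declining with age.
#'
#' @param ages Ages at which table rows are produced.
#' @param n0 Initial CM count per 10 g tissue.
#' @return A [hierarchical_params()].
#' @export
kajstura_synthetic_params <- function(ages = seq(0, 100, by = 10), n0 = 5e8) {
  E <- 5
  amp <- (HOURS_PER_YEAR / 26) * 2^E          # CM per cycling CSC per year
  cyc <- 0.05
  rows <- lapply(c("male", "female"), function(sex) {
    ## formation is calibrated as a fraction of n0 per year; the implied
    ## destruction fraction is chosen so the count trajectory relaxes to a
    ## target excess x*(t): slow monotone loss in males, a middle-age bump
    ## in females.
    if (sex == "male") {
      form_frac <- 0.07 + 0.0022 * (ages - 20)
      x_target <- -0.0015 * ages
    } else {
      form_frac <- 0.09 + 0.0030 * (ages - 20)
      x_target <- 0.18 * (ages / 55) * exp(1 - ages / 55)
    }
    form_frac <- pmax(form_frac, 0.005)
    net <- x_target * form_frac / (1 + x_target)
    dest_frac <- pmax(form_frac - net, 0.001)        # fraction of total/year
    data.frame(age = ages, sex = sex,
               n_csc = form_frac * n0 / (cyc * amp),
               cyc_frac = cyc, mitosis_hours = 26,
               expansion_exponent = E,
               apoptotic_frac = dest_frac / (HOURS_PER_YEAR / 4),
               apoptosis_hours = 4,
               halflife_years = pmax(18 - 0.1 * ages, 4))
  })
  hierarchical_params(do.call(rbind, rows), n0 = n0)
}

#' Read a hierarchical parameter table from CSV
#' @param path CSV with the columns documented in [hierarchical_params()].
#' @param n0,multipliers Passed through.
#' @return A [hierarchical_params()].
#' @export
read_param_table <- function(path, n0 = 5e8, multipliers = list()) {
  hierarchical_params(utils::read.csv(path, stringsAsFactors = FALSE),
                      n0 = n0, multipliers = multipliers)
}

#' Sweep specification for sensitivity analyses
#'
#' @param parameter One of the kinetic parameter names (e.g.
#'   `"expansion_exponent"`, `"apoptotic_frac"`, `"halflife_years"`,
#'   `"mitosis_hours"`, `"apoptosis_hours"`).
#' @param multipliers Non-negative multipliers; 1.0 is the central run.
#' @param sex Subject sex for the sweep.
#' @param denominator Turnover denominator mode (see [turnover_series()]).
#' @param constant_value Denominator count when `denominator = "constant"`
#'   (default: the table's `n0`).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, multipliers = c(0.8, 1.0, 1.2),
                       sex = c("male", "female"),
                       denominator = c("constant", "adjusting"),
                       constant_value = NULL) {
  ok <- c("n_csc", "cyc_frac", "mitosis_hours", "expansion_exponent",
          "apoptotic_frac", "apoptosis_hours", "halflife_years")
  if (!parameter %in% ok)
    stop("unknown parameter '", parameter, "'; expected one of: ",
         paste(ok, collapse = ", "))
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  structure(list(parameter = parameter, multipliers = multipliers,
                 sex = match.arg(sex), denominator = match.arg(denominator),
                 constant_value = constant_value), class = "sweep_spec")
}

sweep_subject <- function(sex, max_age) {
  subject_profile(paste0("sweep_", sex), sex, 1900L, max_age)
}

#' Parameter sensitivity sweep of the hierarchical model
#'
#' Re-runs the hierarchical simulation and annual-turnover computation with
#' one parameter scaled by each multiplier, leaving everything else at the
#' tabulated values.
#'
#' @param params A [hierarchical_params()].
#' @param spec A [sweep_spec()].
#' @param max_age Final subject age of the simulated trajectory.
#' @return A data frame `age, multiplier, turnover_pct`; the rows with
#'   `multiplier == 1` are the central trajectory.
#' @export
sensitivity_sweep <- function(params, spec, max_age = 90) {
  stopifnot(inherits(params, "hierarchical_params"),
            inherits(spec, "sweep_spec"))
  subj <- sweep_subject(spec$sex, max_age)
  cv <- if (is.null(spec$constant_value)) params$n0 else spec$constant_value
  out <- lapply(spec$multipliers, function(m) {
    p <- params
    p$multipliers[[spec$parameter]] <-
      m * (if (is.null(params$multipliers[[spec$parameter]])) 1
           else params$multipliers[[spec$parameter]])
    led <- simulate_hierarchical(p, subj)
    ts <- turnover_series(led, spec$denominator, constant_value = cv)
    data.frame(age = ts$age, multiplier = m, turnover_pct = ts$turnover_pct)
  })
  do.call(rbind, out)
}

#' Turnover with an alternative apoptosis function
#'
#' Reruns the hierarchical model with the tabulated instantaneous apoptotic
#' fraction replaced by `alternative(age)` (same units), under the
#' adjusting-count turnover definition.
#'
#' @param params A [hierarchical_params()].
#' @param alternative Function age -> instantaneous apoptotic fraction.
#' @param sex Subject sex.
#' @param max_age Final subject age.
#' @param denominator Turnover denominator mode.
#' @return A data frame `age, turnover_pct`.
#' @export
substitute_apoptosis <- function(params, alternative,
                                 sex = c("male", "female"), max_age = 90,
                                 denominator = c("adjusting", "constant")) {
  stopifnot(is.function(alternative))
  denominator <- match.arg(denominator)
  sex <- match.arg(sex)
  p <- params
  p$apoptosis_override <- alternative
  led <- simulate_hierarchical(p, sweep_subject(sex, max_age))
  ts <- turnover_series(led, denominator, constant_value = params$n0)
  data.frame(age = ts$age, turnover_pct = ts$turnover_pct)
}

#' Gender-weighted composite turnover trajectory
#'
#' @param male_traj,female_traj Data frames with columns `age` and a value
#'   column (`turnover_pct`), on identical age supports.
#' @param weights Two non-negative weights (male, female) summing to 1.
#' @return A data frame `age, turnover_pct`.
#' @export
gender_composite <- function(male_traj, female_traj,
                             weights = c(0.75, 0.25)) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("weights must be non-negative and sum to 1")
  if (!identical(male_traj$age, female_traj$age))
    stop("trajectories have mismatched age supports")
  data.frame(age = male_traj$age,
             turnover_pct = weights[1] * male_traj$turnover_pct +
                            weights[2] * female_traj$turnover_pct)
}

#' Turnover uncertainty band
#'
#' @param age Ages.
#' @param lower,central,upper Per-age turnover in percent/year, with
#'   `lower <= central <= upper` everywhere.
#' @return A data frame of class `turnover_band`.
#' @export
turnover_band <- function(age, lower, central, upper) {
  if (any(lower > central + 1e-12) || any(central > upper + 1e-12))
    stop("band must satisfy lower <= central <= upper at every age")
  structure(data.frame(age = age, lower = lower, central = central,
                       upper = upper),
            class = c("turnover_band", "data.frame"))
}

#' Envelope band over a family of trajectories
#'
#' @param trajectories List of data frames `age, turnover_pct` on a common
#'   age support.
#' @param central Index of the central trajectory (default: first).
#' @return A [turnover_band()] with pointwise min/max envelopes.
#' @export
envelope_band <- function(trajectories, central = 1L) {
  ages <- trajectories[[1]]$age
  for (tr in trajectories)
    if (!identical(tr$age, ages)) stop("mismatched age supports")
  m <- vapply(trajectories, `[[`, numeric(length(ages)), "turnover_pct")
  m <- matrix(m, nrow = length(ages))
  turnover_band(ages, apply(m, 1, min), m[, central], apply(m, 1, max))
}

#' Scenario-envelope band for the hierarchical model
#'
#' Varies the instantaneous apoptotic fraction and the expansion exponent
#' simultaneously by the given fraction (envelope over the four corner
#' combinations plus the central run), computes adjusting-denominator
#' turnover per sex, and gender-weights the trajectories.
#'
#' @param params A [hierarchical_params()].
#' @param max_age Final subject age.
#' @param frac Fractional variation of the two parameters (default 0.2).
#' @param weights Male/female composite weights.
#' @return A [turnover_band()].
#' @export
kajstura_band <- function(params, max_age = 90, frac = 0.2,
                          weights = c(0.75, 0.25)) {
  corners <- rbind(data.frame(a = 1, e = 1),
                   expand.grid(a = c(1 - frac, 1 + frac),
                               e = c(1 - frac, 1 + frac)))
  per_corner <- lapply(seq_len(nrow(corners)), function(i) {
    p <- params
    p$multipliers$apoptotic_frac <- corners[i, 1]
    p$multipliers$expansion_exponent <- corners[i, 2]
    trajs <- lapply(c("male", "female"), function(sx) {
      led <- simulate_hierarchical(p, sweep_subject(sx, max_age))
      ts <- turnover_series(led, "adjusting")
      data.frame(age = ts$age, turnover_pct = ts$turnover_pct)
    })
    gender_composite(trajs[[1]], trajs[[2]], weights)
  })
  envelope_band(per_corner, central = 1L)
}

#' Per-age overlap of two turnover bands
#'
#' The pointwise intersection `[max(lowers), min(uppers)]`, empty where the
#' bands do not meet. Commutative and idempotent.
#'
#' @param band_a,band_b [turnover_band()] objects on a common age support.
#' @return A data frame `age, lower, upper, empty`.
#' @export
overlap_region <- function(band_a, band_b) {
  common <- intersect(band_a$age, band_b$age)
  if (length(common) == 0) stop("bands share no age support")
  a <- band_a[match(common, band_a$age), ]
  b <- band_b[match(common, band_b$age), ]
  lo <- pmax(a$lower, b$lower)
  hi <- pmin(a$upper, b$upper)
  empty <- lo > hi
  data.frame(age = common, lower = ifelse(empty, NA_real_, lo),
             upper = ifelse(empty, NA_real_, hi), empty = empty)
}
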