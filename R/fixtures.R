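#' Specification for a synthetic subject cohort
#'
#' Defines a reproducible cohort of modeled subjects with ground-truth
#' Lambda-14C computed through the forward model under a generating
#' scenario, emulating the schema of the pulse-chase subject tables.
#'
#' @param n_subjects Number of subjects.
#' @param birth_range Inclusive calendar-year range for births.
#' @param lifespan_range Inclusive range of lifespans (years).
#' @param male_fraction Probability a subject is male.
#' @param seed Integer seed fixing the cohort exactly.
#' @param scenario Generating `turnover_scenario` for ground-truth values.
#' @param max_death_year Subjects are truncated so death does not exceed
#'   this year (keeps them inside curve coverage).
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_subjects = 12,
                                  birth_range = c(1933, 1980),
                                  lifespan_range = c(19, 73),
                                  male_fraction = 0.75, seed = 1L,
                                  scenario = scenario_constant(1),
                                  max_death_year = 2006) {
  stopifnot(n_subjects >= 1, birth_range[1] <= birth_range[2],
            lifespan_range[1] >= 0, lifespan_range[1] <= lifespan_range[2],
            male_fraction >= 0, male_fraction <= 1,
            inherits(scenario, "turnover_scenario"))
  structure(list(n_subjects = n_subjects, birth_range = birth_range,
                 lifespan_range = lifespan_range,
                 male_fraction = male_fraction, seed = as.integer(seed),
                 scenario = scenario, max_death_year = max_death_year),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic subject cohort with ground-truth Lambda-14C
#'
#' Deterministic under `(spec, seed)`: the same spec always yields the same
#' table. Ground-truth `lambda_c14` (and `end_c14`) are computed by running
#' the generating scenario through [predict_lambda()].
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param curve A [bomb_curve()] covering all subjects' lifetimes.
#' @param ploidy A [ploidy_model()].
#' @param policy An [incorporation_policy()].
#' @param n0 Initial CM count.
#' @return A list of [subject_profile()] objects carrying `lambda_c14`.
#' @export
generate_subjects <- function(spec, curve, ploidy = ploidy_model(),
                              policy = incorporation_policy(), n0 = 5e8) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  births <- sample(seq(spec$birth_range[1], spec$birth_range[2]),
                   spec$n_subjects, replace = TRUE)
  spans <- sample(seq(spec$lifespan_range[1], spec$lifespan_range[2]),
                  spec$n_subjects, replace = TRUE)
  spans <- pmin(spans, spec$max_death_year - births)
  sexes <- ifelse(stats::runif(spec$n_subjects) < spec$male_fraction,
                  "male", "female")
  lapply(seq_len(spec$n_subjects), function(i) {
    s <- subject_profile(sprintf("SYN%02d", i), sexes[i], births[i],
                         spans[i])
    lam <- predict_lambda(s, spec$scenario, curve, ploidy, policy, n0)
    s$lambda_c14 <- lam
    s$end_c14 <- lam + initial_c14(curve, s$birth_year, policy$initial_mode)
    s
  })
}

#' Write the bundled fixture set to a directory
#'
#' Produces the plain-text inputs every analysis needs: a synthetic bomb
#' curve CSV, a synthetic hierarchical parameter table CSV, and a synthetic
#' subject cohort CSV with ground-truth Lambda-14C. Deterministic under
#' `seed`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed for the cohort.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curve <- synthetic_bomb_curve()
  f1 <- file.path(dir, "bomb_curve.csv")
  write_bomb_curve(curve, f1)
  f2 <- file.path(dir, "kajstura_params_synthetic.csv")
  utils::write.csv(kajstura_synthetic_params()$table, f2, row.names = FALSE,
                   quote = FALSE)
  spec <- synthetic_cohort_spec(seed = seed)
  subj <- generate_subjects(spec, curve)
  f3 <- file.path(dir, "subjects_synthetic.csv")
  write_subjects(subj, f3)
  invisible(c(f1, f2, f3))
}
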