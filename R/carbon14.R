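#' Incorporation policy for atmospheric 14C
#'
#' Controls how atmospheric 14C enters newly formed DNA: an incorporation
#' delay in whole years (0 assumes instantaneous equilibration; 2 reflects
#' the reported lag of the food chain and solid tissue), and the rule used
#' for the subject's initial 14C (smoothed value at birth, or the extreme
#' raw reading within 12 months of birth).
#'
#' @param delay_years Non-negative integer delay; cohort DNA starts from the
#'   atmospheric value `delay_years` before formation.
#' @param initial_mode Passed to [initial_c14()].
#' @return An object of class `incorporation_policy`.
#' @export
incorporation_policy <- function(delay_years = 0,
                                 initial_mode = c("smoothed",
                                                  "min_within_12mo",
                                                  "max_within_12mo")) {
  if (delay_years < 0 || delay_years != round(delay_years))
    stop("delay_years must be a non-negative integer")
  structure(list(delay_years = as.integer(delay_years),
                 initial_mode = match.arg(initial_mode)),
            class = "incorporation_policy")
}

#' DNA 14C of one formation cohort at subject death
#'
#' A cohort formed at offset j starts from the atmospheric value at
#' (formation year - delay). For every subsequent year of subject life the
#' value is updated for that year's polyploidization event: with incremental
#' polyploidizing fraction p, the default (`"weighted"`) update replaces the
#' value v by `(v + atm * p) / (1 + p)`; the `"normalized"` strategy uses
#' the convex form `(1 - p) * v + p * atm`.
#'
#' @param formation_offset Cohort formation offset(s), 0..lifespan.
#' @param subject A [subject_profile()].
#' @param curve A [bomb_curve()].
#' @param ploidy A [ploidy_model()].
#' @param policy An [incorporation_policy()].
#' @param update Polyploidization update strategy.
#' @return Per-mil DNA 14C at death, one value per offset.
#' @export
cohort_c14_at_death <- function(formation_offset, subject, curve,
                                ploidy = ploidy_model(),
                                policy = incorporation_policy(),
                                update = c("weighted", "normalized")) {
  v <- assign_c14(subject, curve, ploidy, policy, update)
  if (any(formation_offset < 0 | formation_offset > subject$lifespan))
    stop("formation offset outside subject lifespan")
  v[formation_offset + 1L]
}

#' Per-cohort DNA 14C assignments for a whole subject
#'
#' @inheritParams cohort_c14_at_death
#' @return Numeric vector of length `lifespan + 1`, indexed by formation
#'   offset 0..lifespan.
#' @export
assign_c14 <- function(subject, curve, ploidy = ploidy_model(),
                       policy = incorporation_policy(),
                       update = c("weighted", "normalized")) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(curve, "bomb_curve"),
            inherits(ploidy, "ploidy_model"),
            inherits(policy, "incorporation_policy"))
  update <- match.arg(update)
  sm <- smooth_curve(curve)
  L <- subject$lifespan
  atm <- curve_value(sm, subject$birth_year + 0:L)          # during life
  base <- curve_value(sm, subject$birth_year + 0:L - policy$delay_years)
  p <- ploidy_incremental(ploidy, 0:L)                      # p[age + 1]
  v <- base
  if (L > 0) for (j in 0:(L - 1)) {
    val <- base[j + 1L]
    for (y in (j + 1):L) {
      py <- p[y + 1L]
      val <- if (update == "weighted") (val + atm[y + 1L] * py) / (1 + py)
             else (1 - py) * val + py * atm[y + 1L]
    }
    v[j + 1L] <- val
  }
  v
}

#' Count-weighted end-of-life average 14C
#'
#' @param ledger A `cohort_ledger`.
#' @param assignments Per-cohort per-mil values covering every cohort with
#'   nonzero surviving count (length `lifespan + 1`).
#' @return Per-mil weighted mean.
#' @export
end_c14 <- function(ledger, assignments) {
  stopifnot(inherits(ledger, "cohort_ledger"))
  if (length(assignments) != ledger$lifespan + 1L)
    stop("assignments must cover offsets 0..lifespan")
  w <- as.numeric(ledger$counts)
  if (sum(w) <= 0) stop("empty ledger: no surviving cardiomyocytes")
  if (any(w > 0 & !is.finite(assignments)))
    stop("missing assignment for a surviving cohort")
  sum(w * ifelse(w > 0, assignments, 0)) / sum(w)
}

#' Lambda-14C: end-average minus initial 14C
#'
#' @param end,initial Per-mil values.
#' @return `end - initial`, per mil.
#' @export
lambda_c14 <- function(end, initial) end - initial

#' End 14C predicted for a subject and ledger
#'
#' Convenience composition of [assign_c14()] and [end_c14()].
#'
#' @inheritParams assign_c14
#' @param ledger A `cohort_ledger` for the same subject.
#' @return Per-mil end-average 14C.
#' @export
predict_end_c14 <- function(subject, ledger, curve, ploidy = ploidy_model(),
                            policy = incorporation_policy()) {
  end_c14(ledger, assign_c14(subject, curve, ploidy, policy))
}
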