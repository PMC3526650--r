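#' Turnover scenario constructors
#'
#' A `turnover_scenario` is a tagged description of one scenario family,
#' simulable for any subject via [simulate_scenario()]:
#' * `scenario_constant(rate_pct)` — constant annual turnover with random
#'   replacement (formation and uniform destruction at the same rate).
#' * `scenario_rates(schedule)` — any direct [rate_schedule()].
#' * `scenario_tvb_tvdr(theta, ...)` — the four-parameter linear
#'   birth/death-rate model ([simulate_tvb_tvdr()]).
#' * `scenario_e2(gamma0, gamma1)` — cell-age-dependent destruction with
#'   hazard `gamma0 * a^(-gamma1)` at CM age `a`, balanced by formation that
#'   keeps the total count constant.
#' * `scenario_time_dependent(b_i, b_s)` — full replacement at a rate linear
#'   in subject age, `(b_i + b_s*t)` percent/year.
#' * `scenario_hierarchical(params)` — the stem-cell kinetics model
#'   ([simulate_hierarchical()]).
#'
#' @param rate_pct Constant annual turnover in percent/year.
#' @return An object of class `turnover_scenario`.
#' @export
scenario_constant <- function(rate_pct) {
  stopifnot(is.finite(rate_pct), rate_pct >= 0)
  structure(list(family = "constant", rate_pct = rate_pct),
            class = "turnover_scenario")
}

#' @rdname scenario_constant
#' @param schedule A [rate_schedule()].
#' @export
scenario_rates <- function(schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  structure(list(family = "rates", schedule = schedule),
            class = "turnover_scenario")
}

#' @rdname scenario_constant
#' @param theta A [tvb_tvdr_params()].
#' @param survival,formation_basis Passed to [simulate_tvb_tvdr()].
#' @export
scenario_tvb_tvdr <- function(theta, survival = "exponential",
                              formation_basis = "initial") {
  stopifnot(inherits(theta, "tvb_tvdr_params"))
  structure(list(family = "tvb_tvdr", theta = theta, survival = survival,
                 formation_basis = formation_basis),
            class = "turnover_scenario")
}

#' @rdname scenario_constant
#' @param gamma0,gamma1 Hazard coefficients of the cell-age-dependent
#'   destruction model.
#' @export
scenario_e2 <- function(gamma0, gamma1) {
  stopifnot(gamma0 >= 0, is.finite(gamma1))
  structure(list(family = "e2", gamma0 = gamma0, gamma1 = gamma1),
            class = "turnover_scenario")
}

#' @rdname scenario_constant
#' @param b_i,b_s Intercept (%/year) and slope (%/year^2) of the
#'   age-varying full-replacement turnover rate.
#' @export
scenario_time_dependent <- function(b_i, b_s) {
  structure(list(family = "time_dependent", b_i = b_i, b_s = b_s),
            class = "turnover_scenario")
}

#' @rdname scenario_constant
#' @param params A [hierarchical_params()] table.
#' @export
scenario_hierarchical <- function(params) {
  stopifnot(inherits(params, "hierarchical_params"))
  structure(list(family = "hierarchical", params = params),
            class = "turnover_scenario")
}

#' @export
print.turnover_scenario <- function(x, ...) {
  cat("<turnover_scenario>", x$family, "\n")
  invisible(x)
}

#' Simulate any scenario family for a subject
#'
#' @param scenario A `turnover_scenario`.
#' @param subject A [subject_profile()].
#' @param n0 Initial CM count.
#' @return A `cohort_ledger`.
#' @export
simulate_scenario <- function(scenario, subject, n0 = 5e8) {
  stopifnot(inherits(scenario, "turnover_scenario"))
  switch(scenario$family,
    constant = {
      r <- scenario$rate_pct / 100
      simulate_rates(rate_schedule(r, r, "uniform"), subject, n0)
    },
    rates = simulate_rates(scenario$schedule, subject, n0),
    tvb_tvdr = simulate_tvb_tvdr(scenario$theta, subject, n0,
                                 survival = scenario$survival,
                                 formation_basis = scenario$formation_basis),
    e2 = run_cohort_engine(n0, subject$lifespan,
      formation_fn = function(y, total, n0, deaths) deaths,
      survival_fn = function(y, offsets) {
        a <- y - offsets
        1 - pmin(scenario$gamma0 * a^(-scenario$gamma1), 1)
      }),
    time_dependent = {
      f <- function(t) pmin(pmax((scenario$b_i + scenario$b_s * t) / 100, 0), 1)
      simulate_rates(rate_schedule(f, f, "uniform"), subject, n0)
    },
    hierarchical = simulate_hierarchical(scenario$params, subject, n0),
    stop("unknown scenario family: ", scenario$family))
}

#' Predicted Lambda-14C for a subject under a scenario
#'
#' Composes the cohort simulation with the 14C forward model: simulate the
#' end-of-life age distribution, assign each surviving cohort its
#' polyploidization-corrected DNA 14C, take the count-weighted mean and
#' subtract the subject's initial 14C.
#'
#' @param subject A [subject_profile()].
#' @param scenario A `turnover_scenario`.
#' @param curve A [bomb_curve()].
#' @param ploidy A [ploidy_model()].
#' @param policy An [incorporation_policy()].
#' @param n0 Initial CM count.
#' @return Predicted Lambda-14C in per mil.
#' @export
predict_lambda <- function(subject, scenario, curve,
                           ploidy = ploidy_model(),
                           policy = incorporation_policy(), n0 = 5e8) {
  ledger <- simulate_scenario(scenario, subject, n0)
  v <- assign_c14(subject, curve, ploidy, policy)
  lambda_c14(end_c14(ledger, v),
             initial_c14(curve, subject$birth_year, policy$initial_mode))
}

## ---- closed-form cohort weights (exactly the simulator's survivors) ----

weights_constant <- function(r_frac, L) {
  if (L == 0) return(1)
  c((1 - r_frac)^L, r_frac * (1 - r_frac)^(L - seq_len(L)))
}

weights_tvb <- function(theta, L, survival = "exponential") {
  if (L == 0) return(1)
  j <- 0:L
  delta <- pmax((theta$d_i + theta$d_s * j) / 100, 0)
  s <- if (survival == "exponential") exp(-delta)
       else 1 - pmin(delta, 1)
  beta <- pmin(pmax((theta$b_i + theta$b_s * seq_len(L)) / 100, 0), 1)
  c(s[1]^L, beta * s[-1]^(L - seq_len(L)))
}

weights_time_dependent <- function(b_i, b_s, L) {
  if (L == 0) return(1)
  f <- pmin(pmax((b_i + b_s * (0:(L - 1))) / 100, 0), 1)  # year y uses f[y]
  tail_keep <- rev(cumprod(rev(c(1 - f[-1], 1))))          # prod over years > y
  c(prod(1 - f), f * tail_keep)
}

## Lambda predictions over a vector of constant rates (percent), one subject
lambda_constant_grid <- function(rates_pct, L, v, init) {
  r <- rates_pct / 100
  W <- vapply(0:L, function(j) {
    if (j == 0) (1 - r)^L else r * (1 - r)^(L - j)
  }, numeric(length(r)))
  W <- matrix(W, nrow = length(r))
  as.numeric(W %*% v) / rowSums(W) - init
}

#' Grid specification for exhaustive solvers
#'
#' @param ... Named parameters, each `c(min, max, step)` with `step > 0` and
#'   `min <= max`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(...) {
  spec <- list(...)
  if (length(spec) == 0 || is.null(names(spec)) || any(names(spec) == ""))
    stop("grid_spec needs named parameters")
  for (nm in names(spec)) {
    p <- spec[[nm]]
    if (length(p) != 3 || p[3] <= 0 || p[1] > p[2])
      stop("parameter ", nm, " must be c(min, max, step) with step > 0, min <= max")
  }
  structure(spec, class = "grid_spec")
}

grid_points <- function(gs) {
  lapply(unclass(gs), function(p) seq(p[1], p[2], by = p[3]))
}

#' @export
print.grid_spec <- function(x, ...) {
  pts <- grid_points(x)
  cat("<grid_spec>", paste(sprintf("%s: [%g, %g] step %g (%d)", names(x),
      vapply(unclass(x), `[`, 0, 1), vapply(unclass(x), `[`, 0, 2),
      vapply(unclass(x), `[`, 0, 3), lengths(pts)), collapse = "; "),
      "=>", prod(lengths(pts)), "combinations\n")
  invisible(x)
}

#' Branch-aware constant-turnover solver
#'
#' Scans predicted Lambda-14C over a grid of constant annual turnover rates
#' and locates the rates whose prediction matches `target_lambda`. For
#' subjects born before the bomb pulse the forward map rate -> Lambda-14C
#' is unimodal, so past a threshold two rates (a low and a high branch)
#' reproduce the same measurement; both are reported.
#'
#' @param subject A [subject_profile()].
#' @param curve A [bomb_curve()].
#' @param ploidy A [ploidy_model()].
#' @param policy An [incorporation_policy()].
#' @param target_lambda Measured Lambda-14C (per mil).
#' @param grid A [grid_spec()] with parameter `rate_pct`
#'   (default 0-50 %/year in steps of 0.01).
#' @param tol_permil Residual (per mil) under which a branch counts as
#'   converged.
#' @return An object of class `branched_solution`: `low` and optionally
#'   `high` branches (each rate in %/year, predicted Lambda-14C, residual),
#'   `bifurcation_exists`, `threshold_lambda` (the Lambda above which the
#'   high branch is viable, per mil), and `converged`/`degenerate` flags.
#' @export
solve_constant <- function(subject, curve, ploidy = ploidy_model(),
                           policy = incorporation_policy(), target_lambda,
                           grid = grid_spec(rate_pct = c(0, 50, 0.01)),
                           tol_permil = 1) {
  stopifnot(inherits(grid, "grid_spec"), "rate_pct" %in% names(grid))
  rates <- grid_points(grid)$rate_pct
  L <- subject$lifespan
  v <- assign_c14(subject, curve, ploidy, policy)
  init <- initial_c14(curve, subject$birth_year, policy$initial_mode)
  lam <- lambda_constant_grid(rates, L, v, init)
  resid <- lam - target_lambda
  absr <- abs(resid)

  degenerate <- diff(range(lam)) < 1e-12
  if (degenerate) {
    k <- 1L
    cand <- k
  } else {
    sgn <- sign(resid)
    cross <- which(sgn[-length(sgn)] * sgn[-1] <= 0 &
                   (sgn[-length(sgn)] != 0 | sgn[-1] != 0))
    cand <- unique(c(
      vapply(cross, function(i) if (absr[i] <= absr[i + 1]) i else i + 1L,
             integer(1)),
      which(resid == 0)))
    if (length(cand) == 0) cand <- which.min(absr)
    cand <- sort(cand)
  }
  branch <- function(i) list(rate_pct = rates[i], predicted = lam[i],
                             residual = absr[i])
  low_i <- cand[1]
  high_i <- cand[length(cand)]
  step <- if (length(rates) > 1) rates[2] - rates[1] else 0
  distinct <- (rates[high_i] - rates[low_i]) > step
  imax <- which.max(lam)
  structure(list(
    low = branch(low_i),
    high = if (distinct) branch(high_i) else NULL,
    bifurcation_exists = distinct,
    threshold_lambda = if (!degenerate && imax > 1 && imax < length(lam))
      lam[length(lam)] else NA_real_,
    converged = degenerate || absr[low_i] <= tol_permil,
    degenerate = degenerate,
    target_lambda = target_lambda,
    grid = grid), class = "branched_solution")
}

#' @export
print.branched_solution <- function(x, ...) {
  cat(sprintf("<branched_solution> target %.2f per mil: low %.3f%%/yr (resid %.3g)",
              x$target_lambda, x$low$rate_pct, x$low$residual))
  if (!is.null(x$high))
    cat(sprintf(", high %.3f%%/yr (resid %.3g)", x$high$rate_pct,
                x$high$residual))
  cat(if (x$degenerate) " [degenerate]" else if (!x$converged)
    " [non-converged]" else "", "\n")
  invisible(x)
}

#' Forward-then-invert bifurcation scan
#'
#' For each true constant turnover rate, forward-simulates the subject's
#' Lambda-14C and inverts it with [solve_constant()], exposing low-branch
#' saturation and high-branch fidelity.
#'
#' @inheritParams solve_constant
#' @param true_rates_pct True annual turnover rates (%/year).
#' @return A data frame with one row per true rate: `true_rate_pct`,
#'   `lambda`, `low_rate_pct`, `high_rate_pct` (NA when single-branched),
#'   `bifurcation`.
#' @export
bifurcation_scan <- function(subject, curve, ploidy = ploidy_model(),
                             policy = incorporation_policy(), true_rates_pct,
                             grid = grid_spec(rate_pct = c(0, 50, 0.01))) {
  v <- assign_c14(subject, curve, ploidy, policy)
  init <- initial_c14(curve, subject$birth_year, policy$initial_mode)
  L <- subject$lifespan
  rows <- lapply(true_rates_pct, function(r) {
    lam <- lambda_constant_grid(r, L, v, init)
    sol <- solve_constant(subject, curve, ploidy, policy, lam, grid)
    data.frame(true_rate_pct = r, lambda = lam,
               low_rate_pct = sol$low$rate_pct,
               high_rate_pct = if (is.null(sol$high)) NA_real_
                               else sol$high$rate_pct,
               bifurcation = sol$bifurcation_exists)
  })
  do.call(rbind, rows)
}

## ---- global grid fitting ----

default_grid <- function(family) {
  switch(family,
    scenarioA = grid_spec(rate_pct = c(0, 10, 0.01)),
    tvb_tvdr = grid_spec(b_s = c(-1, 1, 0.05), b_i = c(0, 10, 0.1),
                         d_s = c(-1, 1, 0.05), d_i = c(0, 10, 0.1)),
    e2 = grid_spec(gamma0 = c(0, 0.5, 0.01), gamma1 = c(0, 2, 0.05)),
    time_dependent = grid_spec(b_i = c(0, 10, 0.1), b_s = c(-1, 1, 0.05)),
    stop("no default grid for family ", family))
}

## subjects -> list(v = assignments, init, L, obs) per subject
prepare_subjects <- function(subjects, observed, curve, ploidy, policy) {
  if (inherits(subjects, "subject_profile")) subjects <- list(subjects)
  if (is.null(observed))
    observed <- vapply(subjects, function(s) s$lambda_c14, numeric(1))
  if (length(observed) != length(subjects) || any(!is.finite(observed)))
    stop("need one finite observed Lambda-14C per subject")
  list(data = lapply(subjects, function(s) list(
         id = s$id, L = s$lifespan,
         v = assign_c14(s, curve, ploidy, policy),
         init = initial_c14(curve, s$birth_year, policy$initial_mode))),
       obs = observed)
}

predict_for_params <- function(family, par, prep) {
  vapply(prep$data, function(d) {
    w <- switch(family,
      scenarioA = weights_constant(par[["rate_pct"]] / 100, d$L),
      tvb_tvdr = weights_tvb(tvb_tvdr_params(par[["b_s"]], par[["b_i"]],
                                             par[["d_s"]], par[["d_i"]]), d$L),
      time_dependent = weights_time_dependent(par[["b_i"]], par[["b_s"]], d$L),
      e2 = NULL)
    if (is.null(w)) {
      led <- simulate_scenario(scenario_e2(par[["gamma0"]], par[["gamma1"]]),
                               subject_profile("tmp", "male", 1900, d$L), 1)
      w <- as.numeric(led$counts)
    }
    sum(w * d$v) / sum(w) - d$init
  }, numeric(1))
}

sse_for_params <- function(family, par, prep) {
  sum((predict_for_params(family, par, prep) - prep$obs)^2)
}

## exhaustive enumeration over a small named grid (generic path)
enumerate_sse <- function(family, pts, prep) {
  combos <- expand.grid(pts, KEEP.OUT.ATTRS = FALSE)
  sse <- vapply(seq_len(nrow(combos)), function(i)
    sse_for_params(family, as.list(combos[i, , drop = FALSE]), prep),
    numeric(1))
  cbind(combos, sse = sse)
}

## fast exact TVB-TVDR evaluator: loops (d_i, d_s), vectorized over (b_i, b_s)
tvb_grid_sse <- function(pts, prep) {
  bs <- pts$b_s; bi <- pts$b_i; ds <- pts$d_s; di <- pts$d_i
  if (max(bi) + max(abs(bs)) * max(vapply(prep$data, `[[`, 0L, "L")) > 100)
    stop("formation-rate grid exceeds 100%/year; use the generic path")
  nb <- length(bi) * length(bs)
  BI <- rep(bi, times = length(bs)); BS <- rep(bs, each = length(bi))
  best <- list(sse = Inf)
  out_sse <- NULL; out_par <- NULL
  for (dii in di) for (dsi in ds) {
    sse_acc <- numeric(nb)
    for (si in seq_along(prep$data)) {
      d <- prep$data[[si]]
      L <- d$L; j <- seq_len(L)
      delta <- pmax((dii + dsi * (0:L)) / 100, 0)
      A <- exp(-delta[-1] * (L - j))
      w0 <- exp(-delta[1] * L)
      P1 <- c(0, cumsum(A)); P2 <- c(0, cumsum(j * A))
      Q1 <- c(0, cumsum(A * d$v[-1])); Q2 <- c(0, cumsum(j * A * d$v[-1]))
      m <- ifelse(BS >= 0, L, pmin(L, pmax(0, floor(-BI / BS))))
      idx <- m + 1L
      num <- w0 * d$v[1] + (BI / 100) * Q1[idx] + (BS / 100) * Q2[idx]
      den <- w0 + (BI / 100) * P1[idx] + (BS / 100) * P2[idx]
      sse_acc <- sse_acc + ((num / den - d$init) - prep$obs[si])^2
    }
    k <- which.min(sse_acc)
    if (sse_acc[k] < best$sse)
      best <- list(sse = sse_acc[k],
                   par = list(b_s = BS[k], b_i = BI[k], d_s = dsi, d_i = dii))
    keep <- which(sse_acc <= best$sse + 1e-9)
    if (length(keep)) {
      out_sse <- c(out_sse, sse_acc[keep])
      out_par <- rbind(out_par, data.frame(b_s = BS[keep], b_i = BI[keep],
                                           d_s = dsi, d_i = dii))
    }
  }
  list(best = best, near = cbind(out_par, sse = out_sse))
}

#' Exhaustive grid global fit
#'
#' Evaluates every parameter combination of the chosen scenario family on a
#' grid, scoring each by the sum of squared errors between predicted and
#' observed Lambda-14C over the subjects, and returns the minimum together
#' with its AIC. The four-parameter linear birth/death model uses an exact
#' closed-form evaluator; its default `refine = "coarse_to_fine"` scans a
#' coarser grid (4x steps) and then refines locally at full resolution.
#'
#' @param subjects A list of [subject_profile()] (or a single one).
#' @param family One of `"scenarioA"`, `"e2"`, `"tvb_tvdr"`,
#'   `"time_dependent"`.
#' @param grid A [grid_spec()]; defaults to the family's published ranges.
#' @param curve,ploidy,policy Forward-model inputs.
#' @param observed Observed Lambda-14C per subject (default: taken from the
#'   subjects' `lambda_c14` fields).
#' @param refine `"coarse_to_fine"` or `"exhaustive"` (tvb_tvdr only).
#' @param coarse_factor Step multiplier for the coarse pass.
#' @param aic_formula Passed to [aic()].
#' @return An object of class `fit_result`: `family`, `best_params`, `sse`,
#'   `aic`, `k`, `n`, `per_subject` (predicted vs observed), `ties` (all
#'   grid vectors within 1e-9 of the minimum), `grid`.
#' @export
fit_global <- function(subjects, family = c("tvb_tvdr", "scenarioA", "e2",
                                            "time_dependent"),
                       grid = NULL, curve, ploidy = ploidy_model(),
                       policy = incorporation_policy(), observed = NULL,
                       refine = c("coarse_to_fine", "exhaustive"),
                       coarse_factor = 4, aic_formula = "default") {
  family <- match.arg(family)
  refine <- match.arg(refine)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(inherits(grid, "grid_spec"))
  pts <- grid_points(grid)
  if (prod(lengths(pts)) == 0) stop("empty grid")
  prep <- prepare_subjects(subjects, observed, curve, ploidy, policy)

  if (family == "tvb_tvdr") {
    if (refine == "coarse_to_fine") {
      gs <- unclass(grid)
      coarse <- lapply(gs, function(p) seq(p[1], p[2], by = p[3] * coarse_factor))
      res1 <- tvb_grid_sse(coarse, prep)
      b <- res1$best$par
      loc <- lapply(names(gs), function(nm) {
        p <- gs[[nm]]
        lo <- max(p[1], b[[nm]] - p[3] * coarse_factor)
        hi <- min(p[2], b[[nm]] + p[3] * coarse_factor)
        seq(lo, hi, by = p[3])
      })
      names(loc) <- names(gs)
      res <- tvb_grid_sse(loc, prep)
      if (res1$best$sse < res$best$sse) res <- res1
    } else {
      res <- tvb_grid_sse(pts, prep)
    }
    near <- res$near[res$near$sse <= res$best$sse + 1e-9, , drop = FALSE]
    tab <- near[do.call(order, near[setdiff(names(near), "sse")]), ,
                drop = FALSE]
    best_par <- as.list(tab[1, setdiff(names(tab), "sse"), drop = FALSE])
    best_sse <- tab$sse[1]
    ties <- tab
  } else {
    tab <- enumerate_sse(family, pts, prep)
    best_sse <- min(tab$sse)
    near <- tab[tab$sse <= best_sse + 1e-9, , drop = FALSE]
    near <- near[do.call(order, near[setdiff(names(near), "sse")]), ,
                 drop = FALSE]
    best_par <- as.list(near[1, setdiff(names(near), "sse"), drop = FALSE])
    ties <- near
  }
  pred <- predict_for_params(family, best_par, prep)
  sse_check <- sum((pred - prep$obs)^2)
  k <- length(best_par)
  n <- length(prep$obs)
  structure(list(
    family = family, best_params = best_par, sse = sse_check,
    aic = if (sse_check > 0) aic(sse_check, n, k, aic_formula) else -Inf,
    k = k, n = n,
    per_subject = data.frame(
      id = vapply(prep$data, `[[`, "", "id"),
      observed = prep$obs, predicted = pred, residual = pred - prep$obs),
    ties = ties, grid = grid), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> family %s: SSE %.4g, AIC %.3f (n=%d, k=%d)\n",
              x$family, x$sse, x$aic, x$n, x$k))
  cat("  best:", paste(sprintf("%s=%g", names(x$best_params),
                               unlist(x$best_params)), collapse = ", "), "\n")
  invisible(x)
}

#' Akaike information criterion from an SSE
#'
#' The default is the least-squares form `n*log(sse/n) + 2k`. Alternative
#' formulas are selectable: `"per_n"` divides through by `n`
#' (`log(sse/n) + 2k/n`), `"aicc"` adds the small-sample correction. Because
#' different conventions shift AIC by constants, printed AIC values from
#' other sources should be compared only as rankings within one convention.
#'
#' @param sse Sum of squared errors (> 0).
#' @param n_subjects Number of observations (> 0).
#' @param k_params Number of fitted parameters (>= 0).
#' @param formula One of `"default"`, `"per_n"`, `"aicc"`.
#' @return The AIC value.
#' @export
aic <- function(sse, n_subjects, k_params,
                formula = c("default", "per_n", "aicc")) {
  formula <- match.arg(formula)
  if (sse <= 0) stop("sse must be positive")
  if (n_subjects <= 0 || k_params < 0) stop("invalid n or k")
  base <- n_subjects * log(sse / n_subjects) + 2 * k_params
  switch(formula,
    default = base,
    per_n = base / n_subjects,
    aicc = base + 2 * k_params * (k_params + 1) /
      max(n_subjects - k_params - 1, 1e-9))
}
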