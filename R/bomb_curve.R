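#' Atmospheric bomb-pulse Delta-14C curves
#'
#' A `bomb_curve` holds a calendar-indexed series of atmospheric Delta-14C
#' values, expressed in per mil as differentials to the 1955 pre-bomb
#' baseline. Values for calendar years before 1955 are null by convention
#' (no anthropogenic nuclear activity), and the loader enforces or repairs
#' this depending on `strict`.
#'
#' @param year Integer calendar years (repeated per month for monthly data).
#' @param delta_c14 Per-mil Delta-14C values, one per timestamp.
#' @param month Optional integer months 1-12; when supplied the curve has
#'   monthly resolution.
#' @param smoothed Logical flag marking a curve that has already been through
#'   [smooth_curve()].
#' @param strict When `TRUE` (default), nonzero values before 1955 are an
#'   error; when `FALSE` they are zero-filled with a warning.
#' @return An object of class `bomb_curve`: a data frame with columns
#'   `year`, optionally `month`, and `delta_c14`, plus `resolution` and
#'   `smoothed` attributes.
#' @export
bomb_curve <- function(year, delta_c14, month = NULL, smoothed = FALSE,
                       strict = TRUE) {
  if (length(year) == 0L) stop("empty bomb curve")
  if (length(year) != length(delta_c14))
    stop("`year` and `delta_c14` must have the same length")
  if (!all(is.finite(delta_c14))) stop("non-finite Delta-14C values")
  monthly <- !is.null(month)
  if (monthly) {
    if (length(month) != length(year)) stop("`month` length mismatch")
    if (!all(month %in% 1:12)) stop("months must be integers in 1..12")
    key <- year + (month - 0.5) / 12
  } else {
    key <- year
  }
  if (anyDuplicated(key)) {
    stop("duplicate timestamps at rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  o <- order(key)
  year <- as.integer(year[o]); delta_c14 <- as.numeric(delta_c14[o])
  if (monthly) month <- as.integer(month[o])
  pre <- year < 1955L
  if (any(pre & delta_c14 != 0)) {
    if (strict) {
      stop("nonzero Delta-14C before 1955 at rows: ",
           paste(which(pre & delta_c14 != 0), collapse = ", "),
           " (pre-bomb values must be null; use strict = FALSE to zero-fill)")
    }
    warning("zero-filling ", sum(pre & delta_c14 != 0),
            " nonzero pre-1955 values")
    delta_c14[pre] <- 0
  }
  out <- if (monthly) data.frame(year = year, month = month,
                                 delta_c14 = delta_c14)
         else data.frame(year = year, delta_c14 = delta_c14)
  structure(out,
            resolution = if (monthly) "monthly" else "yearly",
            smoothed = isTRUE(smoothed),
            class = c("bomb_curve", "data.frame"))
}

#' @export
print.bomb_curve <- function(x, ...) {
  cat(sprintf("<bomb_curve> %s, %s, %d samples, %d-%d, peak %.1f per mil\n",
              attr(x, "resolution"),
              if (attr(x, "smoothed")) "smoothed" else "raw",
              nrow(x), min(x$year), max(x$year), max(x$delta_c14)))
  invisible(x)
}

#' Synthetic bomb-pulse curve
#'
#' Deterministic fixture emulating the shape of the historical Northern
#' Hemisphere record: flat at zero before 1955, a monotone rise to a
#' 1963-64-style peak, then exponential decay towards a baseline.
#'
#' @param peak_year Calendar year of the peak (must be >= 1955).
#' @param peak_value Peak Delta-14C in per mil (>= baseline >= 0).
#' @param rise_years Years over which the pulse rises to the peak (>= 1).
#' @param decay_constant Exponential decay rate after the peak (1/years, >= 0).
#' @param baseline Long-run value the decay relaxes to (per mil, >= 0).
#' @param start_year,end_year Coverage of the returned curve.
#' @param resolution `"yearly"` or `"monthly"` (monthly values are linear
#'   interpolations of the yearly anchors, giving deterministic within-year
#'   variation for the min/max initial-14C modes).
#' @return A raw [bomb_curve()].
#' @export
synthetic_bomb_curve <- function(peak_year = 1963, peak_value = 800,
                                 rise_years = 8, decay_constant = 0.04,
                                 baseline = 0, start_year = 1930,
                                 end_year = 2010,
                                 resolution = c("yearly", "monthly")) {
  resolution <- match.arg(resolution)
  if (peak_year < 1955) stop("peak_year must be >= 1955")
  if (peak_value < 0 || baseline < 0 || peak_value < baseline)
    stop("need peak_value >= baseline >= 0")
  if (rise_years < 1 || decay_constant < 0) stop("non-physical pulse shape")
  if (end_year < peak_year || start_year > 1955) stop("bad coverage window")
  yearly_value <- function(y) {
    rise_start <- max(1955, peak_year - rise_years)
    ifelse(y < 1955, 0,
    ifelse(y < rise_start, 0,
    ifelse(y <= peak_year,
           peak_value * ((y - rise_start) / max(peak_year - rise_start, 1))^2,
           baseline + (peak_value - baseline) *
             exp(-decay_constant * (y - peak_year)))))
  }
  yrs <- start_year:end_year
  if (resolution == "yearly") {
    bomb_curve(yrs, yearly_value(yrs))
  } else {
    t <- rep(yrs, each = 12) + (rep(1:12, length(yrs)) - 0.5) / 12
    v <- stats::approx(yrs, yearly_value(yrs), xout = pmin(pmax(t, min(yrs)),
                                                           max(yrs)))$y
    v[t < 1955] <- 0
    bomb_curve(rep(yrs, each = 12), v, month = rep(1:12, length(yrs)))
  }
}

#' One-year smoothing of a bomb curve
#'
#' Resamples a curve to yearly resolution by averaging the raw samples in
#' each calendar year (a 12-month window centred on mid-year). Yearly input
#' is returned unchanged apart from the `smoothed` flag. Pre-1955 years stay
#' exactly zero.
#'
#' @param raw A [bomb_curve()].
#' @return A yearly, smoothed `bomb_curve`.
#' @export
smooth_curve <- function(raw) {
  stopifnot(inherits(raw, "bomb_curve"))
  if (nrow(raw) == 0L) stop("empty bomb curve")
  if (attr(raw, "resolution") == "yearly") {
    out <- bomb_curve(raw$year, raw$delta_c14, smoothed = TRUE)
    return(out)
  }
  agg <- tapply(raw$delta_c14, raw$year, mean)
  bomb_curve(as.integer(names(agg)), as.numeric(agg), smoothed = TRUE)
}

#' Look up atmospheric Delta-14C at given calendar years
#'
#' Years before 1955 return 0 regardless of curve coverage; years inside the
#' covered range are linearly interpolated; years beyond coverage are an
#' error (a curve gap).
#'
#' @param curve A [bomb_curve()] (monthly curves are smoothed first).
#' @param year Numeric vector of calendar years.
#' @return Per-mil values, one per year.
#' @export
curve_value <- function(curve, year) {
  stopifnot(inherits(curve, "bomb_curve"))
  if (attr(curve, "resolution") == "monthly") curve <- smooth_curve(curve)
  out <- numeric(length(year))
  post <- year >= 1955
  if (any(post)) {
    y <- year[post]
    if (any(y > max(curve$year)) || any(y < min(pmax(curve$year, 1955))))
      stop("curve gap: years ", paste(unique(y[y > max(curve$year) |
           y < min(pmax(curve$year, 1955))]), collapse = ", "),
           " outside curve coverage ", min(curve$year), "-", max(curve$year))
    out[post] <- stats::approx(curve$year, curve$delta_c14, xout = y)$y
  }
  out
}

#' Initial DNA 14C at subject birth
#'
#' The smoothed atmospheric value at the birth year, or the minimum/maximum
#' raw reading within 12 months of birth, reflecting alternative assumptions
#' about the 14C actually incorporated perinatally.
#'
#' @param curve A [bomb_curve()].
#' @param birth_year Calendar birth year.
#' @param mode One of `"smoothed"`, `"min_within_12mo"`, `"max_within_12mo"`.
#' @return Per-mil value.
#' @export
initial_c14 <- function(curve, birth_year,
                        mode = c("smoothed", "min_within_12mo",
                                 "max_within_12mo")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "bomb_curve"))
  if (birth_year + 1 < 1955) return(0)
  if (mode == "smoothed") return(curve_value(curve, birth_year))
  if (attr(curve, "resolution") == "monthly") {
    t <- curve$year + (curve$month - 0.5) / 12
    win <- t >= birth_year - 0.5 & t <= birth_year + 1.5
  } else {
    win <- curve$year >= birth_year - 1 & curve$year <= birth_year + 1
  }
  if (!any(win)) stop("birth year ", birth_year, " outside curve coverage")
  v <- curve$delta_c14[win]
  v[curve$year[win] < 1955] <- 0
  if (mode == "min_within_12mo") min(v) else max(v)
}

#' Read a bomb curve from CSV
#'
#' Expects columns `year[,month],delta_c14_permil` (header required).
#'
#' @param path CSV file path.
#' @param strict Passed to [bomb_curve()]: error on nonzero pre-1955 values
#'   (`TRUE`) or zero-fill with a warning (`FALSE`).
#' @return A [bomb_curve()].
#' @export
load_bomb_curve <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  vcol <- intersect(c("delta_c14_permil", "delta_c14"), names(df))
  if (!"year" %in% names(df) || length(vcol) == 0L)
    stop("bomb curve CSV needs columns year[,month],delta_c14_permil: ", path)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df[[vcol[1]]]))) |
               !is.finite(suppressWarnings(as.numeric(df$year))))
  if (length(bad))
    stop("malformed rows in ", path, " at lines: ",
         paste(bad + 1L, collapse = ", "))
  bomb_curve(as.integer(df$year), as.numeric(df[[vcol[1]]]),
             month = if ("month" %in% names(df)) as.integer(df$month),
             strict = strict)
}

#' Write a bomb curve to CSV
#' @param curve A [bomb_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bomb_curve <- function(curve, path) {
  stopifnot(inherits(curve, "bomb_curve"))
  df <- as.data.frame(curve)
  names(df)[names(df) == "delta_c14"] <- "delta_c14_permil"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled synthetic reconstruction of the historical bomb curve
#'
#' A yearly 1930-2010 reconstruction of the Northern Hemisphere atmospheric
#' Delta-14C record in per mil relative to 1955, shipped as plain text under
#' `inst/extdata`. It is a synthetic stand-in with the documented pulse
#' shape (null before 1955, peak in the mid-1960s, exponential decline), not
#' a measured dataset.
#'
#' @return A [bomb_curve()].
#' @export
bundled_bomb_curve <- function() {
  load_bomb_curve(system.file("extdata", "bomb_curve_synthetic.csv",
                              package = "cmturnover", mustWork = TRUE))
}
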