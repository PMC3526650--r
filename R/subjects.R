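#' Modeled subject
#'
#' A subject is defined by a birth year and an integer lifespan; the death
#' (autopsy) year is derived. Measured end-of-life DNA 14C values, when
#' available, ride along for fitting.
#'
#' @param id Subject label.
#' @param sex `"male"` or `"female"`.
#' @param birth_year Integer calendar year of birth.
#' @param lifespan Non-negative integer lifespan in years.
#' @param end_c14,lambda_c14 Optional measured end 14C and Lambda-14C
#'   (end minus initial) in per mil.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(id, sex = c("male", "female"), birth_year,
                            lifespan, end_c14 = NA_real_,
                            lambda_c14 = NA_real_) {
  sex <- match.arg(sex)
  if (!is.numeric(birth_year) || birth_year != round(birth_year))
    stop("birth_year must be an integer calendar year")
  if (!is.numeric(lifespan) || lifespan < 0 || lifespan != round(lifespan))
    stop("lifespan must be a non-negative integer")
  structure(list(id = as.character(id), sex = sex,
                 birth_year = as.integer(birth_year),
                 lifespan = as.integer(lifespan),
                 death_year = as.integer(birth_year + lifespan),
                 end_c14 = as.numeric(end_c14),
                 lambda_c14 = as.numeric(lambda_c14)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject> %s (%s), born %d, lifespan %d y (death %d)",
              x$id, x$sex, x$birth_year, x$lifespan, x$death_year))
  if (!is.na(x$lambda_c14))
    cat(sprintf(", Lambda-14C %.2f per mil", x$lambda_c14))
  cat("\n")
  invisible(x)
}

#' Read a subject table from CSV
#'
#' Expects columns `id,sex,birth_year,lifespan[,end_c14,lambda_c14]`.
#'
#' @param path CSV path.
#' @return A list of [subject_profile()] objects.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "birth_year", "lifespan")
  if (!all(need %in% names(df)))
    stop("subject CSV needs columns ", paste(need, collapse = ","), ": ", path)
  lapply(seq_len(nrow(df)), function(i) {
    subject_profile(df$id[i], df$sex[i], df$birth_year[i], df$lifespan[i],
                    end_c14 = if ("end_c14" %in% names(df)) df$end_c14[i] else NA,
                    lambda_c14 = if ("lambda_c14" %in% names(df))
                      df$lambda_c14[i] else NA)
  })
}

#' Write a subject table to CSV
#' @param subjects A list of [subject_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  df <- do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, sex = s$sex, birth_year = s$birth_year,
               lifespan = s$lifespan, end_c14 = s$end_c14,
               lambda_c14 = s$lambda_c14)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The three eldest pre-bomb subjects printed in the source dataset
#'
#' Birth years and Lambda-14C measurements for the three oldest subjects of
#' the 12-subject pulse-chase dataset (born 1933, 1939 and 1944; measured
#' Lambda-14C 21.30, 18.84 and 3.65 per mil). The 1933-born subject has the
#' printed 73-year lifespan; the other two lifespans place death in the same
#' autopsy year and are a synthetic assumption.
#'
#' @return A list of three [subject_profile()] objects.
#' @export
oldest_printed_subjects <- function() {
  list(subject_profile("ND60", "male", 1933, 73, lambda_c14 = 21.30),
       subject_profile("ND67", "male", 1939, 67, lambda_c14 = 18.84),
       subject_profile("ND73", "male", 1944, 62, lambda_c14 = 3.65))
}
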