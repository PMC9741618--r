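# Small shared numerical helpers.

#' Evaluate a right-continuous step function
#'
#' Step functions throughout the package are stored as a vector of jump
#' times (strictly increasing) and the function value at/after each jump;
#' the value before the first jump is `v0`.
#'
#' @param time strictly increasing jump times.
#' @param value function value at and after each jump time.
#' @param at evaluation points.
#' @param v0 value before the first jump (default 0).
#' @return numeric vector, `value` evaluated right-continuously at `at`.
#' @export
step_eval <- function(time, value, at, v0 = 0) {
  stopifnot(length(time) == length(value))
  if (length(time) == 0L) return(rep(v0, length(at)))
  idx <- findInterval(at, time)
  c(v0, value)[idx + 1L]
}

# reverse cumulative sum: out[i] = sum(x[i:n])
revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x[rev(seq_len(nrow(x))), , drop = FALSE], 2L, cumsum)[rev(seq_len(nrow(x))), , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

days_per_year <- 365.25

# calendar-date difference in years (days / 365.25)
years_between <- function(from, to) as.numeric(as.Date(to) - as.Date(from)) / days_per_year

# age in completed years at a reference date
age_at <- function(birth_date, at_date) {
  floor(years_between(birth_date, at_date))
}

parse_dates <- function(x, what = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop(sprintf("unparseable %s at row(s): %s", what,
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
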