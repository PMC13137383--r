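#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats median qt quantile predict rlnorm runif sd
#' @importFrom utils combn
NULL

# error classes used across the package:
#   lakesmoke_config_error   invalid configuration value (names the field)
#   lakesmoke_format_error   malformed input file / missing column
#   lakesmoke_validation_error  out-of-range data value (cites rows)
#   lakesmoke_contract_error called outside an operation's precondition
abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "lakesmoke_config_error", field = field)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "lakesmoke_format_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "lakesmoke_validation_error", ...)
}

abort_contract <- function(msg, ...) {
  abort(msg, class = "lakesmoke_contract_error", ...)
}

# Derive a reproducible sub-seed (kept inside 32-bit integer range) for the
# i-th independent stream of a run.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647L)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_range <- function(x) {
  is.numeric(x) && length(x) == 2L && all(is.finite(x)) && x[1] <= x[2]
}

#' Week-bin conventions
#'
#' Weeks are consecutive 7-day bins counted from an origin date (default
#' 2018-01-01, giving 52 complete bins through 2018-12-30). `week_start()`
#' returns the first calendar day of a bin; `week_index()` maps a date into
#' its bin.
#'
#' @param index Integer week index (1-based).
#' @param date A `Date` (or coercible) vector.
#' @param origin First day of week 1.
#' @return `week_start()` a `Date` vector; `week_index()` an integer vector.
#' @examples
#' week_start(1)                      # "2018-01-01"
#' week_index(as.Date("2018-01-08"))  # 2
#' @export
week_start <- function(index, origin = as.Date("2018-01-01")) {
  origin + (as.integer(index) - 1L) * 7L
}

#' @rdname week_start
#' @export
week_index <- function(date, origin = as.Date("2018-01-01")) {
  as.integer(floor(as.numeric(as.Date(date) - origin) / 7)) + 1L
}

# mean, SE and t-based 95% CI of a numeric vector; NA CI when n < 2
t_ci <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- if (n > 0) mean(x) else NA_real_
  se <- if (n > 1) sd(x) / sqrt(n) else NA_real_
  half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * se else NA_real_
  list(n = n, mean = m, se = se, lo = m - half, hi = m + half)
}
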