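#' @importFrom rlang .data .env
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Round half-up to `digits` decimals (round-to-even would turn e.g. a
# time-allocation PAL of 1.75 into 1.7; reported values use half-up).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge compensates for decimals like 4.605 stored just below their
  # nominal value
  floor(x * p + 0.5 + 1e-9) / p
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    rlang::abort(paste0("`", name, "` must be > 0"))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    rlang::abort(paste0("`", name, "` must be >= 0"))
  }
  invisible(x)
}

check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1 || !sex %in% c("male", "female")) {
    rlang::abort('`sex` must be "male" or "female"')
  }
  sex
}

# denominator guard for relative errors: |actual - target| / max(target, eps)
rel_err <- function(actual, target, eps = 1e-9) {
  abs(actual - target) / pmax(target, eps)
}
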