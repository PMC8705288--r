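#' Survival class boundaries in days
#'
#' The three survival classes are day intervals: short-term (class 1) up to
#' 299 days, mid-term (class 2) from 300 to 450 days, long-term (class 3)
#' from 451 days. The 300-day (10-month) boundary separates classes 1 and 2,
#' the 450-day (15-month) boundary separates classes 2 and 3, using the
#' 30-day month convention.
#'
#' @return Named integer vector with elements `short_max`, `mid_min`,
#'   `mid_max`, `long_min`.
#' @export
#' @examples
#' class_boundaries()
class_boundaries <- function() {
  c(short_max = 299L, mid_min = 300L, mid_max = 450L, long_min = 451L)
}

#' Survival class labels
#'
#' @return Character vector `c("short", "mid", "long")`; the position of a
#'   label is its class index (1, 2, 3).
#' @export
survival_class_levels <- function() c("short", "mid", "long")

#' Bin survival time in days into the three survival classes
#'
#' Maps survival in days to a factor with levels `short` (<= 299 days),
#' `mid` (300--450 days) and `long` (>= 451 days). Censored (alive) subjects
#' carry no survival class and must be excluded before calling.
#'
#' @param days Positive integer vector of survival times in days.
#' @return Factor with levels `short`, `mid`, `long`.
#' @export
#' @examples
#' bin_survival_days(c(296, 300, 448, 453))
bin_survival_days <- function(days) {
  if (length(days) == 0L) {
    return(factor(character(), levels = survival_class_levels()))
  }
  if (anyNA(days)) {
    stop("bin_survival_days: censored or missing survival times cannot be binned",
         call. = FALSE)
  }
  days <- as.numeric(days)
  if (any(days <= 0) || any(days != floor(days))) {
    stop("bin_survival_days: survival times must be positive integers (days)",
         call. = FALSE)
  }
  b <- class_boundaries()
  idx <- ifelse(days <= b[["short_max"]], 1L,
                ifelse(days <= b[["mid_max"]], 2L, 3L))
  factor(survival_class_levels()[idx], levels = survival_class_levels())
}
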