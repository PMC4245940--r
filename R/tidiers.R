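#' Tidy a deamination fit
#'
#' @param x A `deamination_fit`.
#' @param ... Unused.
#' @return A tibble with one row per regression term (`intercept`, `slope`):
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.deamination_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(co[, "Estimate"]),
    std.error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "t value"]),
    p.value = unname(co[, "Pr(>|t|)"])
  )
}

#' One-row summary of a deamination fit
#'
#' @param x A `deamination_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `site_id`, `k`, `k_se`, `half_life_h`,
#'   `half_life_se_h`, `yield_percent`, `intercept`, `r_squared`,
#'   `n_points`, `n_excluded`, `valid`.
#' @exportS3Method generics::glance
glance.deamination_fit <- function(x, ...) {
  tibble::tibble(
    site_id = x$site_id,
    k = x$k,
    k_se = x$k_se,
    half_life_h = x$half_life_h,
    half_life_se_h = x$half_life_se_h,
    yield_percent = 100 * x$yield,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_points = x$n_points,
    n_excluded = x$n_excluded,
    valid = x$valid
  )
}

#' Tidy a periodicity fit
#'
#' @param x A `phasing_fit`.
#' @param ... Unused.
#' @return The per-position tibble with `position`, `intensity`, `fitted`.
#' @exportS3Method generics::tidy
tidy.phasing_fit <- function(x, ...) {
  x$data
}

#' One-row summary of a periodicity fit
#'
#' @param x A `phasing_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `period_bp`, `phase_bp`, `amplitude`,
#'   `baseline`, `r_squared`, `n`, `degenerate`.
#' @exportS3Method generics::glance
glance.phasing_fit <- function(x, ...) {
  tibble::tibble(
    period_bp = x$period_bp,
    phase_bp = x$phase_bp,
    amplitude = x$amplitude,
    baseline = x$baseline,
    r_squared = x$r_squared,
    n = x$n,
    degenerate = x$degenerate
  )
}
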