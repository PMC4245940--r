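#' Deaminated fraction from band intensities
#'
#' Converts a pair of band intensities from one gel aliquot into the fraction
#' of label found in the thymine band, `T / (T + mC)`. In the tandem-gel
#' deamination assay this is the fraction of labelled 5-methyl-dC that has
#' deaminated to dT at the time the aliquot was taken.
#'
#' @param intensity_mC Nonnegative band intensity of the
#'   \eqn{^{32}}P-5-methyl-dC band (arbitrary units).
#' @param intensity_T Nonnegative band intensity of the \eqn{^{32}}P-dT band
#'   (arbitrary units).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' deaminated_fraction(75, 25) # 0.25
#' @family kinetics
#' @export
deaminated_fraction <- function(intensity_mC, intensity_T) {
  if (any(intensity_mC < 0, na.rm = TRUE) || any(intensity_T < 0, na.rm = TRUE)) {
    stop("band intensities must be nonnegative", call. = FALSE)
  }
  total <- intensity_mC + intensity_T
  if (any(total <= 0, na.rm = TRUE)) {
    stop("degenerate measurement: both band intensities are zero", call. = FALSE)
  }
  intensity_T / total
}

#' Fraction of CPD remaining undeaminated
#'
#' Normalizes a timed deaminated fraction by the terminal (complete
#' deamination) fraction and returns the fraction of photoproduct that has not
#' yet deaminated, `1 - f_t / f_inf`. Under first-order kinetics this decays
#' exponentially, so its log is linear in time.
#'
#' Noise can push `f_t` above `f_inf`, giving a nonpositive remaining
#' fraction; such values are returned as-is and are excluded by
#' [fit_deamination()].
#'
#' @param f_t Deaminated fraction at time t (from [deaminated_fraction()]).
#' @param f_inf Deaminated fraction of the fully deaminated terminal aliquot;
#'   must be positive.
#' @return Numeric vector; `1 - f_t / f_inf` (may be `<= 0` under noise).
#' @family kinetics
#' @export
cpd_remaining_fraction <- function(f_t, f_inf) {
  if (any(f_inf <= 0, na.rm = TRUE)) {
    stop("unusable terminal aliquot: terminal deaminated fraction must be > 0",
         call. = FALSE)
  }
  if (any(f_t < 0, na.rm = TRUE)) {
    stop("f_t must be nonnegative", call. = FALSE)
  }
  1 - f_t / f_inf
}

#' Photoproduct yield from the terminal aliquot
#'
#' The CPD photoproduct yield is the deaminated fraction of the fully
#' deaminated terminal aliquot, `T_inf / (T_inf + mC_inf)`: after complete
#' deamination only label that was in a photoproduct appears in the dT band.
#'
#' @inheritParams deaminated_fraction
#' @return Yield as a fraction in `[0, 1]`.
#' @examples
#' photoproduct_yield(88, 12) # 0.12, a 12% yield
#' @family kinetics
#' @export
photoproduct_yield <- function(intensity_mC, intensity_T) {
  deaminated_fraction(intensity_mC, intensity_T)
}

#' Convert between first-order half-life and rate constant
#'
#' Standard first-order relations `k = ln(2) / t_half` and
#' `t_half = ln(2) / k`.
#'
#' @param half_life_h Half-life in hours; must be positive.
#' @param k Rate constant in h^-1; must be positive.
#' @return Rate constant in h^-1, or half-life in hours.
#' @examples
#' half_life_to_rate(13) # 0.0533 h^-1
#' @family kinetics
#' @export
half_life_to_rate <- function(half_life_h) {
  if (any(half_life_h <= 0, na.rm = TRUE)) {
    stop("half_life_h must be positive", call. = FALSE)
  }
  log(2) / half_life_h
}

#' @rdname half_life_to_rate
#' @export
rate_to_half_life <- function(k) {
  if (any(k <= 0, na.rm = TRUE)) stop("k must be positive", call. = FALSE)
  log(2) / k
}

#' Fold change relative to a reference
#'
#' @param test_value Numeric value(s) to compare.
#' @param reference_value Positive reference value.
#' @return `test_value / reference_value`.
#' @examples
#' fold_change(41, 13) # 3.15, printed as 3.1
#' @family kinetics
#' @export
fold_change <- function(test_value, reference_value) {
  if (any(reference_value <= 0, na.rm = TRUE)) {
    stop("reference_value must be positive", call. = FALSE)
  }
  test_value / reference_value
}

# validate and split a single-site time-course data frame into timed
# measurements and the terminal aliquot
validate_time_course <- function(data, site = NULL) {
  required <- c("time_h", "intensity_mC", "intensity_T", "is_terminal")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("time-course data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(site) && "site_id" %in% names(data)) {
    data <- data[data$site_id == site, , drop = FALSE]
  }
  if ("site_id" %in% names(data) && length(unique(data$site_id)) > 1) {
    stop("data contains multiple sites; supply `site` or use deamination_rates()",
         call. = FALSE)
  }
  term <- data[data$is_terminal != 0, , drop = FALSE]
  timed <- data[data$is_terminal == 0, , drop = FALSE]
  if (nrow(term) == 0) {
    stop("no terminal (complete deamination) aliquot for site ",
         if (nrow(data)) unique(data$site_id)[1] else "<empty>", call. = FALSE)
  }
  if (nrow(timed) < 3) {
    stop("need at least 3 timed measurements, got ", nrow(timed), call. = FALSE)
  }
  timed <- timed[order(timed$time_h), , drop = FALSE]
  if (any(duplicated(timed$time_h))) {
    stop("measurement times must be strictly increasing", call. = FALSE)
  }
  if (any(timed$time_h < 0)) stop("time_h must be >= 0", call. = FALSE)
  list(timed = timed, terminal = term)
}

#' Fit a first-order deamination time course
#'
#' Estimates the deamination rate constant of a CPD from one site's band
#' intensity time course by ordinary least squares on the log of the
#' remaining-CPD fraction versus time: `ln(1 - f_t/f_inf) = a - k t`. The
#' intercept is left free because the initial amount of deamination is
#' nonzero and varies between samples. Points whose measured remaining
#' fraction is nonpositive (noise can push `f_t >= f_inf`) are excluded with a
#' warning; at least 3 points must survive.
#'
#' @param data Data frame with columns `time_h`, `intensity_mC`,
#'   `intensity_T`, `is_terminal` (0/1) and optionally `site_id`. Exactly one
#'   site; at least one row with `is_terminal = 1` (the fully deaminated
#'   aliquot) and at least three timed rows.
#' @param site Optional site id to select when `data` carries a `site_id`
#'   column with several sites.
#' @return An object of class `deamination_fit`: a list with elements
#'   `site_id`, `k` (h^-1), `k_se`, `half_life_h`, `half_life_se_h`, `yield`
#'   (fraction), `intercept` (fitted `ln` remaining fraction at t = 0),
#'   `r_squared`, `n_points`, `n_excluded`, `valid`, the underlying `lm`
#'   `model` and the per-point `data`. The half-life standard error is
#'   propagated as `ln(2) * k_se / k^2`. If the fitted slope is nonnegative
#'   (no detectable deamination) `valid` is `FALSE`, `k` is reported
#'   nonpositive and the half-life columns are `NA`.
#' @seealso [deamination_rates()] for many sites at once; [tidy()] and
#'   [glance()] methods; [autoplot()] for the log-linear diagnostic plot.
#' @examples
#' tc <- generate_time_course(k = log(2) / 13, cpd_yield = 0.12, noise_sigma = 0)
#' fit <- fit_deamination(tc)
#' fit$half_life_h # 13
#' @family kinetics
#' @export
fit_deamination <- function(data, site = NULL) {
  parts <- validate_time_course(data, site = site)
  timed <- parts$timed
  term <- parts$terminal
  site_id <- if ("site_id" %in% names(data) && nrow(timed)) timed$site_id[1] else NA_character_

  f_inf <- mean(deaminated_fraction(term$intensity_mC, term$intensity_T))
  cpd_yield <- f_inf
  f_t <- deaminated_fraction(timed$intensity_mC, timed$intensity_T)
  remaining <- cpd_remaining_fraction(f_t, f_inf)

  keep <- remaining > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warning(sprintf("excluded %d point(s) with nonpositive remaining fraction%s",
                    n_excluded,
                    if (!is.na(site_id)) paste0(" for site ", site_id) else ""),
            call. = FALSE)
  }
  if (sum(keep) < 3) {
    stop("fewer than 3 usable points after excluding nonpositive remaining fractions",
         call. = FALSE)
  }

  df <- data.frame(time_h = timed$time_h[keep], log_remaining = log(remaining[keep]))
  model <- stats::lm(log_remaining ~ time_h, data = df)
  sm <- summary(model)
  slope <- coef(model)[["time_h"]]
  slope_se <- sm$coefficients["time_h", "Std. Error"]
  k <- -slope
  valid <- is.finite(k) && k > 0
  if (!valid) {
    warning("fitted slope is nonnegative: no detectable deamination",
            call. = FALSE)
  }

  out <- list(
    site_id = site_id,
    k = k,
    k_se = slope_se,
    half_life_h = if (valid) log(2) / k else NA_real_,
    half_life_se_h = if (valid) log(2) * slope_se / k^2 else NA_real_,
    yield = cpd_yield,
    intercept = coef(model)[["(Intercept)"]],
    r_squared = sm$r.squared,
    n_points = sum(keep),
    n_excluded = n_excluded,
    valid = valid,
    model = model,
    data = tibble::tibble(
      time_h = timed$time_h,
      deaminated_fraction = f_t,
      remaining_fraction = remaining,
      used = keep
    )
  )
  class(out) <- "deamination_fit"
  out
}

#' @export
print.deamination_fit <- function(x, ...) {
  cat("First-order deamination fit",
      if (!is.na(x$site_id)) paste0(" [", x$site_id, "]"), "\n", sep = "")
  if (x$valid) {
    cat(sprintf("  k = %.4g +/- %.3g h^-1  (t1/2 = %.4g +/- %.3g h)\n",
                x$k, x$k_se, x$half_life_h, x$half_life_se_h))
  } else {
    cat("  invalid fit: no detectable deamination (slope >= 0)\n")
  }
  cat(sprintf("  yield = %.3g%%, r^2 = %.4f, %d point(s) used, %d excluded\n",
              100 * x$yield, x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Deamination rates for every site in a time-course table
#'
#' Applies [fit_deamination()] to each `site_id` group and binds the per-site
#' summaries into one tibble. With a `reference_site`, fold-change columns
#' (half-life, yield and rate constant relative to that site) are appended.
#' Sites whose fit fails (e.g. a missing terminal aliquot) are dropped from
#' the result with a warning and reported in the `"failures"` attribute.
#'
#' @param data Data frame with columns `site_id`, `time_h`, `intensity_mC`,
#'   `intensity_T`, `is_terminal`.
#' @param reference_site Optional `site_id` used as the fold-change reference
#'   (e.g. the free-DNA control).
#' @return A tibble with one row per site: `site_id`, `k`, `k_se`,
#'   `half_life_h`, `half_life_se_h`, `yield_percent`, `intercept`,
#'   `r_squared`, `n_points`, `n_excluded`, and, when `reference_site` is
#'   given, `half_life_fold`, `yield_fold`, `rate_fold`.
#' @family kinetics
#' @export
deamination_rates <- function(data, reference_site = NULL) {
  if (!"site_id" %in% names(data)) {
    stop("`data` must have a site_id column", call. = FALSE)
  }
  if (nrow(data) == 0) stop("`data` has no rows", call. = FALSE)
  sites <- unique(data$site_id)
  fits <- vector("list", length(sites))
  failures <- list()
  for (i in seq_along(sites)) {
    res <- tryCatch(
      fit_deamination(data[data$site_id == sites[i], , drop = FALSE]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(site_id = sites[i], error = conditionMessage(res))
    } else {
      fits[[i]] <- glance(res)
    }
  }
  out <- dplyr::bind_rows(fits)
  if (length(failures) > 0) {
    fail <- dplyr::bind_rows(failures)
    warning("fit failed for site(s): ", paste(fail$site_id, collapse = ", "),
            call. = FALSE)
    attr(out, "failures") <- fail
  }
  if (!is.null(reference_site)) {
    if (!reference_site %in% out$site_id) {
      stop("reference site ", reference_site, " not among fitted sites",
           call. = FALSE)
    }
    ref <- out[out$site_id == reference_site, ]
    out <- dplyr::mutate(
      out,
      half_life_fold = fold_change(.data$half_life_h, ref$half_life_h),
      yield_fold = fold_change(.data$yield_percent, ref$yield_percent),
      rate_fold = fold_change(.data$k, ref$k)
    )
  }
  out
}

#' Read a band-intensity time-course table
#'
#' Reads a CSV or TSV file (by extension) with columns `site_id`, `time_h`,
#' `intensity_mC`, `intensity_T`, `is_terminal`.
#'
#' @param path File path.
#' @return A tibble.
#' @family kinetics
#' @export
read_time_courses <- function(path) {
  reader <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  data <- reader(path, show_col_types = FALSE)
  required <- c("site_id", "time_h", "intensity_mC", "intensity_T", "is_terminal")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("time-course file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data
}

#' Write a per-site rate report
#'
#' Writes the tibble produced by [deamination_rates()] (or any result tibble)
#' as TSV or JSON depending on the file extension.
#'
#' @param x A data frame.
#' @param path Output path ending in `.tsv` or `.json`.
#' @return `x`, invisibly.
#' @family kinetics
#' @export
write_rate_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(x)
}
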