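#' Transition-state free-energy difference from a rate ratio
#'
#' Converts a ratio of first-order rate constants into the difference in
#' activation free energy between the two conditions,
#' \eqn{\Delta\Delta G^\ddagger = R T \ln(k_{fast}/k_{slow})}, with
#' R = 1.9872e-3 kcal mol^-1 K^-1. The sign carries the direction: positive
#' when `k_fast > k_slow`. Yields may be used in place of rates as a proxy
#' for relative photoproduct-formation rates.
#'
#' @param k_fast,k_slow Positive rate constants (or rate proxies such as
#'   yields) in matching units.
#' @param temperature_K Absolute temperature in kelvin. The deamination assay
#'   runs at 37 degrees C (310.15 K); irradiation for photoproduct formation
#'   at 4 degrees C (277.15 K).
#' @return A tibble with columns `ddg_kcal_mol`, `ratio`, `temperature_K`.
#' @examples
#' # innermost vs outermost deamination, half-lives 41 h and 3.5 h:
#' ddg_from_rates(log(2) / 3.5, log(2) / 41) # about 1.5 kcal/mol
#' @family energetics
#' @export
ddg_from_rates <- function(k_fast, k_slow, temperature_K = 310.15) {
  if (any(k_fast <= 0, na.rm = TRUE) || any(k_slow <= 0, na.rm = TRUE)) {
    stop("rate constants must be positive", call. = FALSE)
  }
  if (any(temperature_K <= 0, na.rm = TRUE)) {
    stop("temperature_K must be positive", call. = FALSE)
  }
  ratio <- k_fast / k_slow
  tibble::tibble(
    ddg_kcal_mol = .R_KCAL * temperature_K * log(ratio),
    ratio = ratio,
    temperature_K = temperature_K
  )
}

#' Per-position free-energy profile relative to a reference
#'
#' Computes \eqn{R T \ln(\mathrm{value}/\mathrm{reference})} for each row of
#' a per-site table, giving the transition-state free-energy difference of
#' each rotational position relative to a reference condition (free DNA by
#' default usage).
#'
#' @param data Data frame of per-site values (rate constants or yields).
#' @param value Column of `data` holding the positive per-site values
#'   (tidy-eval).
#' @param reference Positive scalar reference value (e.g. the free-DNA rate
#'   constant).
#' @param temperature_K Absolute temperature in kelvin; see
#'   [ddg_from_rates()] for the defaults appropriate to each assay.
#' @return `data` with columns `ratio`, `ddg_kcal_mol` and `temperature_K`
#'   appended.
#' @examples
#' site_table <- deamination_site_data()
#' ncp <- dplyr::filter(site_table, dna == "ncp", context == "TmCG")
#' ncp$k <- half_life_to_rate(ncp$half_life_h)
#' ddg_profile(ncp, k, reference = half_life_to_rate(13))
#' @family energetics
#' @export
ddg_profile <- function(data, value, reference, temperature_K = 310.15) {
  if (nrow(data) == 0) stop("`data` has no rows", call. = FALSE)
  vals <- dplyr::pull(data, {{ value }})
  if (any(vals <= 0, na.rm = TRUE) || reference <= 0) {
    stop("values and reference must be positive", call. = FALSE)
  }
  dplyr::mutate(
    data,
    ratio = vals / reference,
    ddg_kcal_mol = .R_KCAL * temperature_K * log(.data$ratio),
    temperature_K = temperature_K
  )
}
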