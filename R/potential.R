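#' Mutagenic potential of one rotational position
#'
#' The C-to-T mutagenic potential of a site in a nucleosome, relative to free
#' DNA, is the product of its relative CPD formation (yield fold) and its
#' relative CPD deamination rate (rate fold):
#' `potential = (yield_ncp / yield_free) * (k_ncp / k_free)`. A potential
#' above 1 marks a position more mutagenic than free DNA.
#'
#' @param yield_ncp,yield_free Positive photoproduct yields (any common
#'   units: fractions or percentages).
#' @param k_ncp,k_free Positive deamination rate constants (h^-1), or
#'   half-life reciprocals in any common units.
#' @return A tibble with columns `yield_fold`, `rate_fold`, `potential` and
#'   `reciprocal` (`1 / potential`, the "x-fold lower" reading when the
#'   potential is below 1).
#' @examples
#' # outermost position: yields 22% vs 12%, half-lives 3.5 h vs 13 h
#' relative_potential(22, 12, log(2) / 3.5, log(2) / 13) # potential 6.81
#' @family mutagenic potential
#' @export
relative_potential <- function(yield_ncp, yield_free, k_ncp, k_free) {
  vals <- c(yield_ncp, yield_free, k_ncp, k_free)
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("yields and rate constants must be positive", call. = FALSE)
  }
  yield_fold <- yield_ncp / yield_free
  rate_fold <- k_ncp / k_free
  potential <- yield_fold * rate_fold
  tibble::tibble(
    yield_fold = yield_fold,
    rate_fold = rate_fold,
    potential = potential,
    reciprocal = 1 / potential
  )
}

#' Mutagenic-potential profile for a table of sites
#'
#' Computes [relative_potential()] for every site in a per-site table
#' against a named reference site (typically the free-DNA control). Rate
#' folds are taken from rate constants (`ln 2 / t_half`), not from rounded
#' fold-change columns, to avoid compounding rounding error.
#'
#' @param data Data frame with one row per site carrying a site identifier
#'   (`site_id` or `site`), yields (`yield_percent` or `yield`), and rates
#'   (`k`) or half-lives (`half_life_h`). The output of
#'   [deamination_rates()] and the packaged [deamination_site_data()] table
#'   both qualify.
#' @param reference_site Site identifier of the reference row.
#' @return A tibble with the identifying columns of `data` plus
#'   `yield_fold`, `rate_fold`, `potential`, `reciprocal`, for every
#'   non-reference row.
#' @examples
#' sites <- dplyr::filter(deamination_site_data(), context == "TmCG")
#' pot <- mutagenic_potential(sites, reference_site = "Free ds1-10")
#' average_potential(pot) # 2.28: mean enhancement over the ten positions
#' @family mutagenic potential
#' @export
mutagenic_potential <- function(data, reference_site) {
  id_col <- intersect(c("site_id", "site"), names(data))[1]
  if (is.na(id_col)) stop("`data` needs a site or site_id column", call. = FALSE)
  yield_col <- intersect(c("yield_percent", "yield"), names(data))[1]
  if (is.na(yield_col)) {
    stop("`data` needs a yield or yield_percent column", call. = FALSE)
  }
  if ("k" %in% names(data)) {
    k <- data$k
  } else if ("half_life_h" %in% names(data)) {
    k <- half_life_to_rate(data$half_life_h)
  } else {
    stop("`data` needs a k or half_life_h column", call. = FALSE)
  }
  ref_idx <- which(data[[id_col]] == reference_site)
  if (length(ref_idx) != 1) {
    stop("reference site ", reference_site, " must match exactly one row",
         call. = FALSE)
  }
  rows <- setdiff(seq_len(nrow(data)), ref_idx)
  comp <- relative_potential(
    yield_ncp = data[[yield_col]][rows],
    yield_free = data[[yield_col]][ref_idx],
    k_ncp = k[rows],
    k_free = k[ref_idx]
  )
  keep_cols <- intersect(c(id_col, "position"), names(data))
  dplyr::bind_cols(data[rows, keep_cols, drop = FALSE], comp)
}

#' Average mutagenic potential across positions
#'
#' Unweighted arithmetic mean of the per-position potentials, the summary a
#' weakly rotationally positioned nucleosome would express.
#'
#' @param x Numeric vector of potentials, or a data frame with a `potential`
#'   column (e.g. from [mutagenic_potential()]).
#' @return A single number.
#' @family mutagenic potential
#' @export
average_potential <- function(x) {
  if (is.data.frame(x)) {
    if (!"potential" %in% names(x)) {
      stop("data frame must have a potential column", call. = FALSE)
    }
    x <- x$potential
  }
  if (length(x) == 0) stop("empty input", call. = FALSE)
  mean(x)
}
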