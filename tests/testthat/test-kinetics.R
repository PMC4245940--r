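test_that("band fractions follow T/(T+mC)", {
  expect_equal(deaminated_fraction(100, 0), 0)
  expect_equal(deaminated_fraction(0, 50), 1)
  expect_equal(deaminated_fraction(75, 25), 0.25)
  expect_equal(deaminated_fraction(c(100, 0), c(0, 50)), c(0, 1))
  expect_error(deaminated_fraction(0, 0), "degenerate")
  expect_error(deaminated_fraction(-1, 5), "nonnegative")
})

test_that("remaining fraction normalizes by the terminal fraction", {
  expect_equal(cpd_remaining_fraction(0, 0.12), 1)
  expect_equal(cpd_remaining_fraction(0.12, 0.12), 0)
  expect_equal(cpd_remaining_fraction(0.06, 0.12), 0.5)
  # noise can push the timed fraction past the terminal one
  expect_lt(cpd_remaining_fraction(0.15, 0.12), 0)
  expect_error(cpd_remaining_fraction(0.1, 0), "terminal")
})

test_that("photoproduct yield is the terminal deaminated fraction", {
  expect_equal(photoproduct_yield(88, 12), 0.12)
  expect_equal(photoproduct_yield(78, 22), 0.22)
  expect_equal(photoproduct_yield(0, 1), 1)
})

test_that("half-life and rate constant interconvert as ln2 / x", {
  expect_equal(half_life_to_rate(13), log(2) / 13, tolerance = 1e-12)
  expect_equal(half_life_to_rate(log(2)), 1)
  expect_equal(rate_to_half_life(half_life_to_rate(41)), 41)
  expect_error(half_life_to_rate(0), "positive")
  expect_error(rate_to_half_life(-1), "positive")
})

test_that("noiseless time courses are recovered exactly, whatever the intercept", {
  for (k_true in c(log(2) / 13, 0.2, 0.017)) {
    for (f0 in c(0, 0.1)) {
      tc <- generate_time_course(k = k_true, cpd_yield = 0.12,
                                 initial_deaminated = f0,
                                 times_h = c(0, 6, 12, 24, 48),
                                 noise_sigma = 0)
      fit <- suppressWarnings(fit_deamination(tc))
      expect_equal(fit$k, k_true, tolerance = 1e-9)
      expect_equal(fit$half_life_h * fit$k, log(2), tolerance = 1e-12)
      expect_equal(fit$intercept, log(1 - f0), tolerance = 1e-9)
      expect_equal(fit$yield, 0.12, tolerance = 1e-12)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    }
  }
  # the canonical round trip: k = ln2/13 gives a 13 h half-life
  tc <- generate_time_course(k = log(2) / 13, cpd_yield = 0.12,
                             initial_deaminated = 0,
                             times_h = c(0, 6, 12, 24, 48), noise_sigma = 0)
  expect_equal(suppressWarnings(fit_deamination(tc))$half_life_h, 13,
               tolerance = 1e-9)
})

test_that("fits are invariant to rescaling the intensities of an aliquot", {
  tc <- generate_time_course(k = 0.1, cpd_yield = 0.2, noise_sigma = 0.05,
                             seed = 11)
  fit1 <- fit_deamination(tc)
  tc2 <- tc
  # common per-aliquot factor (e.g. loading differences) cancels in fractions
  scale <- c(7.3, 0.2, 1, 5, 11, 0.9, 2, 3)[seq_len(nrow(tc2))]
  tc2$intensity_mC <- tc2$intensity_mC * scale
  tc2$intensity_T <- tc2$intensity_T * scale
  fit2 <- fit_deamination(tc2)
  expect_equal(fit1$k, fit2$k, tolerance = 1e-12)
  expect_equal(fit1$yield, fit2$yield, tolerance = 1e-12)
  expect_equal(fit1$r_squared, fit2$r_squared, tolerance = 1e-12)
})

test_that("nonpositive remaining fractions are excluded and counted", {
  tc <- tibble::tibble(
    site_id = "s",
    time_h = c(0, 2, 4, 8, 16, Inf),
    intensity_mC = c(95, 90, 80, 70, 40, 50),
    intensity_T = c(5, 10, 20, 30, 60, 50), # t=16 exceeds the terminal fraction
    is_terminal = c(0, 0, 0, 0, 0, 1)
  )
  expect_warning(fit <- fit_deamination(tc), "nonpositive")
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$n_points, 4)
  expect_true(fit$valid)
})

test_that("unusable courses are refused with informative errors", {
  base <- generate_time_course(k = 0.1, cpd_yield = 0.2, noise_sigma = 0)
  expect_error(fit_deamination(base[base$is_terminal == 0, ]), "terminal")
  expect_error(fit_deamination(base[c(1, 2, nrow(base)), ]), "at least 3")
  dup <- base
  dup$time_h[2] <- dup$time_h[3]
  expect_error(fit_deamination(dup), "strictly increasing")
  # no decay at all: slope >= 0 is flagged invalid
  flat <- tibble::tibble(
    site_id = "s", time_h = c(0, 2, 4, 8, Inf),
    intensity_mC = c(90, 89, 91, 90, 50),
    intensity_T = c(10, 11, 9, 10, 50),
    is_terminal = c(0, 0, 0, 0, 1)
  )
  expect_warning(fit <- fit_deamination(flat), "no detectable")
  expect_false(fit$valid)
  expect_true(is.na(fit$half_life_h))
})

test_that("stochastic courses in the fast-deamination regime are recovered", {
  fits <- withr::with_seed(1, {
    replicate(500, {
      tc <- generate_time_course(k = 0.198, cpd_yield = 0.22, noise_sigma = 0.05)
      suppressWarnings(fit_deamination(tc))$half_life_h
    })
  })
  expect_lt(abs(mean(fits) - 3.5) / 3.5, 0.10)
})

test_that("median bias of the rate estimate stays within 2% across the rate range", {
  for (k_true in c(0.017, 0.0533, 0.198)) {
    ks <- withr::with_seed(7, {
      replicate(200, {
        tc <- generate_time_course(k = k_true, cpd_yield = 0.15,
                                   noise_sigma = 0.05)
        suppressWarnings(fit_deamination(tc))$k
      })
    })
    expect_lt(abs(median((ks - k_true) / k_true)), 0.02)
  }
})

test_that("fold changes divide by the reference", {
  expect_equal(fold_change(41, 13), 41 / 13)
  expect_equal(round(fold_change(41, 13), 2), 3.15)
  expect_equal(fold_change(22, 12), 22 / 12)
  expect_equal(fold_change(4.2, 4.2), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("rate constants rank exactly opposite to half-lives on the site table", {
  tab <- deamination_site_data()
  k <- half_life_to_rate(tab$half_life_h)
  expect_equal(order(k), rev(order(tab$half_life_h)))
  expect_equal(rank(k), length(k) + 1 - rank(tab$half_life_h))
})

test_that("deamination_rates fits every site and appends fold columns", {
  courses <- dplyr::bind_rows(
    generate_time_course(k = log(2) / 13, cpd_yield = 0.12, site_id = "free",
                         noise_sigma = 0, initial_deaminated = 0.05),
    generate_time_course(k = log(2) / 3.5, cpd_yield = 0.22, site_id = "outer",
                         noise_sigma = 0, initial_deaminated = 0.05),
    generate_time_course(k = log(2) / 41, cpd_yield = 0.069, site_id = "inner",
                         noise_sigma = 0, initial_deaminated = 0.05)
  )
  rates <- suppressWarnings(deamination_rates(courses, reference_site = "free"))
  expect_equal(nrow(rates), 3)
  expect_equal(rates$half_life_h, c(13, 3.5, 41), tolerance = 1e-9)
  expect_equal(rates$half_life_fold, c(1, 3.5 / 13, 41 / 13), tolerance = 1e-9)
  expect_equal(rates$yield_fold, c(1, 22 / 12, 6.9 / 12), tolerance = 1e-9)
  expect_equal(rates$rate_fold, c(1, 13 / 3.5, 13 / 41), tolerance = 1e-9)
})

test_that("time-course tables round-trip through disk in both formats", {
  courses <- generate_time_course(k = 0.05, cpd_yield = 0.15, noise_sigma = 0.05,
                                  seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(courses, tsv)
  expect_equal(as.data.frame(read_time_courses(tsv)), as.data.frame(courses),
               tolerance = 1e-12)
  fit <- glance(fit_deamination(courses))
  json <- withr::local_tempfile(fileext = ".json")
  write_rate_report(fit, json)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$k, fit$k, tolerance = 1e-9)
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_rate_report(fit, out_tsv)
  expect_equal(readr::read_tsv(out_tsv, show_col_types = FALSE)$half_life_h,
               fit$half_life_h, tolerance = 1e-9)
})
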