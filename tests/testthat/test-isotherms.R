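test_that("isotherm construction applies the mass balance", {
  iso <- build_isotherm(50, 4.46)
  expect_equal(iso$ce_mg_per_L, 4.46)
  expect_equal(iso$qe_mg_per_g, 45.54)

  expect_equal(build_isotherm(50, 50)$qe_mg_per_g, 0)
  expect_equal(build_isotherm(50, 10, biomass = 2)$qe_mg_per_g,
               build_isotherm(50, 10, biomass = 1)$qe_mg_per_g / 2)
  expect_warning(build_isotherm(10, 12),
                 class = "biosorb_negative_adsorption")
  expect_error(build_isotherm(c(1, 2), 1), class = "biosorb_invalid_input")
})

test_that("through-origin fit: exact proportional data and hand oracle", {
  exact <- build_isotherm(4 * c(1, 2, 5), c(1, 2, 5))  # qe = 3 * Ce
  fit <- fit_linear_origin(exact)
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # hand points (1,2),(2,3),(3,7): slope = 29/14
  hand <- tibble::tibble(ce_mg_per_L = c(1, 2, 3), qe_mg_per_g = c(2, 3, 7))
  expect_equal(fit_linear_origin(hand)$slope, 29 / 14)

  expect_error(
    fit_linear_origin(tibble::tibble(ce_mg_per_L = c(0, 0),
                                     qe_mg_per_g = c(1, 2))),
    class = "biosorb_degenerate_input"
  )
})

test_that("closed-form slope, SE and p agree with lm(qe ~ Ce + 0)", {
  iso <- generate_isotherm(23, b_o = 3.104, temperature_C = 40)
  fit <- fit_linear_origin(iso)
  lfit <- summary(lm(qe_mg_per_g ~ ce_mg_per_L + 0, data = iso))
  expect_equal(fit$slope, lfit$coefficients[1, "Estimate"], tolerance = 1e-10)
  expect_equal(fit$slope_se, lfit$coefficients[1, "Std. Error"],
               tolerance = 1e-10)
  expect_equal(fit$p_value, lfit$coefficients[1, "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_equal(fit$r_squared, lfit$r.squared, tolerance = 1e-10)
})

test_that("slope is scale-equivariant in qe", {
  iso <- generate_isotherm(41, b_o = 10.22)
  scaled <- iso
  scaled$qe_mg_per_g <- 3 * iso$qe_mg_per_g
  expect_equal(fit_linear_origin(scaled)$slope,
               3 * fit_linear_origin(iso)$slope)
})

test_that("implied removal fraction: worked values, limits, monotonicity", {
  expect_equal(implied_removal_fraction(10.22, 1), 10.22 / 11.22)
  expect_equal(implied_removal_fraction(10.22, 1), 0.9109, tolerance = 1e-4)
  expect_equal(implied_removal_fraction(0), 0)
  expect_gt(implied_removal_fraction(1e9), 0.999999)
  b <- seq(0, 20, by = 0.5)
  expect_true(all(diff(implied_removal_fraction(b)) > 0))
})

test_that("noiseless generate -> build -> fit -> implied fraction round-trips", {
  for (b_o in c(0.26, 3.104, 10.22)) {
    iso <- generate_isotherm(1, b_o = b_o, noise_sd = 0)
    fit <- fit_linear_origin(iso)
    expect_equal(fit$slope, b_o, tolerance = 1e-10)
    f <- b_o / (1 + b_o)
    expect_equal(implied_removal_fraction(fit$slope), f, tolerance = 1e-10)
  }
})

test_that("temperature ordering of slopes is reproduced on synthetic data", {
  est <- study_isotherm_estimates()
  slopes <- purrr::map2_dbl(est$temperature_C, est$b_o, function(temp, b) {
    fit_linear_origin(generate_isotherm(77, b_o = b, temperature_C = temp,
                                        stream = paste0("T", temp)))$slope
  })
  expect_true(all(diff(slopes) > 0))  # 30 < 40 < 50 degC
})

test_that("isotherm CSV round-trips losslessly", {
  sets <- list(
    `40` = generate_isotherm(5, b_o = 3.104, temperature_C = 40),
    `50` = generate_isotherm(5, b_o = 10.22, temperature_C = 50)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(sets, path)
  back <- read_isotherm_csv(path)
  expect_equal(names(back), c("40", "50"))
  expect_equal(back$`50`$qe_mg_per_g, sets$`50`$qe_mg_per_g, tolerance = 1e-9)
  expect_equal(attr(back$`40`, "temperature_C"), 40)
})
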