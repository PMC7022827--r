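test_that("MSC reproduces worked values", {
  # model predicting the observed mean: log(1) - 2*lambda/d
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(msc(obs, rep(mean(obs), 5), n_params = 1), -0.4)
  # hand arithmetic: TSS = 200, RSS = 3
  expect_equal(msc(c(10, 20, 30), c(11, 19, 31), n_params = 1),
               log(200 / 3) - 2 / 3)
})

test_that("MSC weight invariance and penalty monotonicity", {
  withr::with_seed(5, {
    obs <- rnorm(12, 10, 3)
    mod <- obs + rnorm(12, 0, 0.5)
    w <- runif(12, 0.5, 2)
    expect_equal(msc(obs, mod, 1, weights = w),
                 msc(obs, mod, 1, weights = 2 * w))
    vals <- vapply(1:4, function(l) msc(obs, mod, n_params = l), numeric(1))
    expect_true(all(diff(vals) < 0))
  })
})

test_that("MSC edge cases: perfect fit errors, constant series is -Inf", {
  expect_error(msc(c(1, 2, 3), c(1, 2, 3), 1), class = "biosorb_perfect_fit")
  expect_warning(out <- msc(c(2, 2, 2), c(1, 2, 3), 1),
                 class = "biosorb_constant_series")
  expect_identical(out, -Inf)
  expect_error(msc(1, 1, 1), class = "biosorb_invalid_input")
  expect_error(msc(c(1, 2), c(1, 3), 1, weights = c(-1, 1)),
               class = "biosorb_invalid_input")
})

test_that("RMSE and RSE reproduce worked values and their inequality", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  withr::with_seed(6, {
    obs <- rnorm(10)
    mod <- obs + rnorm(10, 0, 0.3)
    expect_gte(rse(obs, mod, 1), rmse(obs, mod))
    # identical ranking as MSC when lambda and d match
    mod2 <- obs + rnorm(10, 0, 0.6)
    expect_equal(rmse(obs, mod) < rmse(obs, mod2),
                 msc(obs, mod, 1) > msc(obs, mod2, 1))
  })
  expect_error(rse(c(1, 2), c(1, 3), 2), class = "biosorb_degenerate_input")
})

test_that("comparison prefers the generating model (near-noiseless)", {
  tc_fo <- generate_time_course(3, ci = 50, rate = 0.052, noise_sd = 1e-6)
  cmp_fo <- compare_kinetic_models(tc_fo, fit_first_order(tc_fo),
                                   fit_second_order(tc_fo))
  expect_equal(preferred_model(cmp_fo), "first_order")

  tc_so <- generate_time_course(3, ci = 50, model = "second_order",
                                rate = 0.0018, noise_sd = 1e-6)
  cmp_so <- compare_kinetic_models(tc_so, fit_first_order(tc_so),
                                   fit_second_order(tc_so))
  expect_equal(preferred_model(cmp_so), "second_order")
})

test_that("noiseless data yields an overwhelming preference for the
           generating model", {
  # the refitted curve matches to optimizer precision, not exactly, so
  # the residual sum of squares stays positive and MSC is finite but huge
  tc0 <- generate_time_course(3, ci = 50, rate = 0.052, noise_sd = 0)
  cmp <- compare_kinetic_models(tc0, fit_first_order(tc0),
                                fit_second_order(tc0))
  expect_equal(preferred_model(cmp), "first_order")
  expect_gt(cmp$msc[1], cmp$msc[2] + 5)
})

test_that("MSC selects the generating model in most noisy replications", {
  tally <- function(model, rate, sd) {
    wins <- 0L
    ties <- 0L
    for (i in 1:100) {
      tc <- generate_time_course(4000 + i, ci = 50, model = model,
                                 rate = rate, noise_sd = sd,
                                 stream = paste0("sel-", model))
      cmp <- suppressWarnings(compare_kinetic_models(
        tc, fit_first_order(tc), fit_second_order(tc)
      ))
      pref <- preferred_model(cmp)
      if (is.na(pref)) ties <- ties + 1L
      else if (pref == model) wins <- wins + 1L
    }
    wins / (100 - ties)
  }
  expect_gt(tally("first_order", 0.052, 1.0), 0.5)
  expect_gt(tally("second_order", 0.0018, 1.1), 0.5)
})

test_that("comparison table carries both models and flags mismatched fits", {
  tc <- generate_time_course(9, ci = 50, rate = 0.052)
  fo <- fit_first_order(tc)
  so <- fit_second_order(tc)
  cmp <- compare_kinetic_models(tc, fo, so)
  expect_equal(cmp$model, c("first_order", "second_order"))
  expect_true(all(cmp$rse >= cmp$rmse))
  expect_equal(cmp$n_params, c(1L, 1L))

  other <- generate_time_course(9, ci = 75, rate = 0.047)
  expect_error(compare_kinetic_models(other, fo, so),
               class = "biosorb_invalid_input")
})
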