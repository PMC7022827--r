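test_that("kinetic model laws reproduce worked values", {
  expect_equal(first_order_remaining(50, 0.052, 0), 50)
  expect_equal(first_order_remaining(50, 0.052, 24), 50 * exp(-1.248))
  expect_equal(first_order_remaining(50, 0.052, 24), 14.354, tolerance = 1e-4)
  expect_equal(first_order_remaining(50, 0, c(0, 24, 96)), rep(50, 3))

  expect_equal(first_order_adsorbed(50, 0.052, 0), 0)
  expect_equal(first_order_adsorbed(50, 0.5, 1e6), 45.5)  # asymptote 0.91*Ci
  expect_equal(first_order_adsorbed(25, 0.046, 48), 20.249, tolerance = 1e-3)

  expect_equal(second_order_remaining(50, 0.0018, 0), 50)
  expect_equal(second_order_remaining(50, 0.0018, 24), 1 / 0.0632)
  expect_equal(second_order_remaining(50, 0.0018, 24), 15.823, tolerance = 1e-3)
  expect_equal(second_order_remaining(50, 0, c(0, 48)), rep(50, 2))

  expect_error(first_order_remaining(50, 0.05, -1),
               class = "biosorb_invalid_input")
  expect_error(first_order_adsorbed(50, 0.05, 1, equilibrium_fraction = 1.2),
               class = "biosorb_invalid_input")
})

test_that("mass balance and shape properties hold on a grid", {
  t <- seq(0, 96, by = 4)
  for (ci in c(25, 50, 75, 100)) {
    # remaining + pure-exponential adsorbed complement == Ci at every t
    expect_equal(first_order_remaining(ci, 0.05, t) + ci * (1 - exp(-0.05 * t)),
                 rep(ci, length(t)))
    # monotone decreasing remaining concentration, both models
    expect_true(all(diff(first_order_remaining(ci, 0.05, t)) < 0))
    so <- second_order_remaining(ci, 0.002, t)
    expect_true(all(diff(so) < 0))
    # second-order remaining is convex in t
    expect_true(all(diff(diff(so)) > 0))
  }
})

make_tc <- function(ci, values_by_time, times = c(0, 24, 48, 72, 96),
                    kind = "adsorbed", reps = 1) {
  grid <- tidyr::expand_grid(time_h = times, replicate = seq_len(reps))
  grid$value <- values_by_time[match(grid$time_h, times)]
  time_course(grid, ci = ci, value_kind = kind)
}

test_that("noiseless self-consistency: fits recover generating rates to 1e-8", {
  times <- c(0, 24, 48, 72, 96)
  tc_fo <- make_tc(50, first_order_adsorbed(50, 0.05, times))
  expect_equal(fit_first_order(tc_fo)$rate_constant, 0.05, tolerance = 1e-8)

  tc_so <- make_tc(50, second_order_remaining(50, 0.002, times),
                   kind = "remaining")
  expect_equal(fit_second_order(tc_so)$rate_constant, 0.002, tolerance = 1e-8)
  expect_equal(fit_second_order(tc_so, method = "linearized")$rate_constant,
               0.002, tolerance = 1e-8)
})

test_that("fits operate identically from remaining-space time courses", {
  times <- c(0, 24, 48, 72, 96)
  q <- first_order_adsorbed(50, 0.06, times)
  tc_rem <- make_tc(50, 50 - q, kind = "remaining")
  expect_equal(fit_first_order(tc_rem)$rate_constant, 0.06, tolerance = 1e-8)
})

test_that("optimizer agrees with a brute-force grid oracle, including under
           model misspecification", {
  tc <- generate_time_course(31, ci = 50, model = "second_order",
                             rate = 0.0018, noise_sd = 1.1)
  fit <- fit_first_order(tc)  # wrong model on purpose
  expect_gt(fit$residual_rmse, 0)
  qe <- 0.91 * 50
  q_obs <- 50 - tc$value
  ssr <- function(k1) sum((q_obs - qe * (1 - exp(-k1 * tc$time_h)))^2)
  expect_equal(fit$rate_constant, grid_argmin(ssr, 0.001, 1),
               tolerance = 1e-3)

  fit2 <- fit_second_order(tc)
  ct_obs <- tc$value
  ssr2 <- function(k2) sum((ct_obs - 1 / (k2 * tc$time_h + 1 / 50))^2)
  expect_equal(fit2$rate_constant, grid_argmin(ssr2, 1e-5, 0.01),
               tolerance = 1e-3)
})

test_that("rate estimate and SE match nls with fixed Qe (independent route)", {
  tc <- generate_time_course(17, ci = 50, rate = 0.052, noise_sd = 1)
  fit <- fit_first_order(tc)
  d <- data.frame(t = tc$time_h, q = tc$value)
  nfit <- nls(q ~ 45.5 * (1 - exp(-k1 * t)), data = d,
              start = list(k1 = 0.05))
  expect_equal(fit$rate_constant, coef(nfit)[["k1"]], tolerance = 1e-6)
  expect_equal(fit$rate_constant_se,
               summary(nfit)$coefficients["k1", "Std. Error"],
               tolerance = 0.05)
})

test_that("parameter recovery is unbiased within Monte-Carlo error", {
  nrep <- 60
  for (ci in c(25, 50, 75, 100)) {
    k1s <- vapply(seq_len(nrep), function(i) {
      fit_first_order(generate_time_course(500 + i, ci = ci, rate = 0.05,
                                           stream = paste0("mc", ci)))$rate_constant
    }, numeric(1))
    expect_lt(abs(mean(k1s) - 0.05), 3 * sd(k1s) / sqrt(nrep))

    k2s <- vapply(seq_len(nrep), function(i) {
      fit_second_order(generate_time_course(900 + i, ci = ci,
                                            model = "second_order",
                                            rate = 0.002,
                                            stream = paste0("mc", ci)))$rate_constant
    }, numeric(1))
    expect_lt(abs(mean(k2s) - 0.002), 3 * sd(k2s) / sqrt(nrep))
  }
})

test_that("fit preconditions are enforced", {
  short <- time_course(
    tibble::tibble(time_h = c(0, 24), replicate = 1, value = c(0, 10)),
    ci = 50, value_kind = "adsorbed"
  )
  expect_error(fit_first_order(short), class = "biosorb_invalid_input")
  expect_error(fit_second_order(short), class = "biosorb_invalid_input")

  flat <- make_tc(50, rep(0, 5))
  expect_error(fit_first_order(flat), class = "biosorb_degenerate_data")

  exhausted <- make_tc(50, c(50, 20, 5, 1, 0), kind = "remaining")
  expect_error(fit_second_order(exhausted), class = "biosorb_invalid_data")
})

test_that("time_course validates structure and flags negatives", {
  expect_error(
    time_course(tibble::tibble(time_h = c(24, 48, 96), replicate = 1,
                               value = 1:3),
                ci = 50, value_kind = "adsorbed"),
    class = "biosorb_invalid_input"
  )
  expect_warning(
    time_course(tibble::tibble(time_h = c(0, 24), replicate = 1,
                               value = c(-1, 5)),
                ci = 50, value_kind = "adsorbed"),
    class = "biosorb_negative_values"
  )
})
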