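test_that("generators are deterministic per seed and stream", {
  a <- generate_time_course(42)
  b <- generate_time_course(42)
  expect_identical(a, b)
  expect_false(identical(a$value, generate_time_course(43)$value))
  expect_false(identical(a$value,
                         generate_time_course(42, stream = "x")$value))

  expect_identical(generate_isotherm(42), generate_isotherm(42))
  expect_identical(generate_ph_screen(42), generate_ph_screen(42))
  expect_identical(generate_calibration(42), generate_calibration(42))

  # streams are independent: generating one design does not perturb another
  iso_alone <- generate_isotherm(42)
  invisible(generate_time_course(42))
  expect_identical(generate_isotherm(42), iso_alone)
})

test_that("noiseless generation reproduces the model curves exactly", {
  tc <- generate_time_course(1, ci = 50, rate = 0.052, noise_sd = 0)
  truth <- first_order_adsorbed(50, 0.052, tc$time_h)
  expect_equal(tc$value, truth, tolerance = 1e-12)

  tc2 <- generate_time_course(1, ci = 50, model = "second_order",
                              rate = 0.0018, noise_sd = 0)
  expect_equal(tc2$value, second_order_remaining(50, 0.0018, tc2$time_h),
               tolerance = 1e-12)

  cal <- generate_calibration(1, noise_sd = 0)
  fit <- fit_calibration(cal)
  expect_equal(fit$slope, 0.003, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0348, tolerance = 1e-12)
})

test_that("time-course replicate mean at t = 96 matches the generator's
           closed-form mean", {
  truth96 <- 0.91 * 50 * (1 - exp(-0.052 * 96))
  tc <- generate_time_course(8, ci = 50, rate = 0.052, noise_sd = 1)
  obs <- mean(tc$value[tc$time_h == 96])
  expect_lt(abs(obs - truth96), 3 * 1 / sqrt(3))
})

test_that("truncation at zero is rare at default noise levels", {
  total <- 0L
  points <- 0L
  for (i in 1:50) {
    tc <- generate_time_course(i, ci = 25, rate = 0.046,
                               stream = "trunc-check")
    total <- total + attr(tc, "truncated")
    points <- points + nrow(tc)
  }
  expect_lt(total / points, 0.01)
})

test_that("pH screen: peak location and height are honoured", {
  scr <- generate_ph_screen(2, noise_sd = 0)
  means <- tapply(scr$removal_percent, scr$ph, mean)
  expect_equal(unname(means[["4"]]), 46.84)
  expect_equal(as.numeric(names(which.max(means))), 4)

  moved <- generate_ph_screen(2, ph_grid = seq(4, 10, by = 0.5),
                              peak_ph = 7.5, noise_sd = 0)
  mm <- tapply(moved$truth_percent, moved$ph, mean)
  expect_equal(as.numeric(names(which.max(mm))), 7.5)

  expect_error(generate_ph_screen(2, peak_ph = 3.2),
               class = "biosorb_config_error")
  expect_error(generate_time_course(2, model = "zeroth_order"))
})

test_that("calibration design covers the stated standard range", {
  cal <- generate_calibration(3)
  expect_true(all(c(50, 800) %in% cal$concentration_mg_per_L))
})

test_that("seeded isotherm noise keeps slope recovery within 3 SE", {
  reps <- 200
  slopes <- vapply(seq_len(reps), function(i) {
    fit_linear_origin(generate_isotherm(6000 + i, b_o = 10.22,
                                        stream = "rec"))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 10.22), 3 * sd(slopes) / sqrt(reps))
})

test_that("a full synthetic study assembles all four designs", {
  study <- generate_study(11)
  expect_named(study, c("calibration", "ph_screen", "time_courses",
                        "isotherms"))
  expect_equal(as.numeric(names(study$time_courses)), c(25, 50, 75, 100))
  expect_equal(as.numeric(names(study$isotherms)), c(30, 40, 50))
  expect_s3_class(study$time_courses[["50"]], "time_course")
})
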