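test_that("direct illuminance follows the cosine law and its domain checks", {
  expect_equal(direct_illuminance(1000, 0), 1000)
  expect_equal(direct_illuminance(1000, 60), 500)
  # frozen oracle: 2000 * cos(33.8 deg), evaluated term-by-term independently
  expect_equal(direct_illuminance(2000, 33.8), 1661.9689385486568)

  # linear in E0, decreasing in theta
  thetas <- seq(0, 89, by = 7)
  vals <- vapply(thetas, function(t) direct_illuminance(500, t), numeric(1))
  expect_true(all(diff(vals) < 0))
  for (t in thetas) {
    expect_equal(direct_illuminance(3 * 500, t), 3 * direct_illuminance(500, t))
  }

  expect_error(direct_illuminance(0, 30), class = "canopylight_domain_error")
  expect_error(direct_illuminance(1000, 90), class = "canopylight_domain_error")
  expect_error(direct_illuminance(NaN, 30), class = "canopylight_domain_error")
})

test_that("shadow length supports both conventions and they cross-check", {
  expect_equal(shadow_length(100, 45), 100)
  expect_equal(shadow_length(0, 30), 0)
  # frozen oracle: 113 * tan(27 deg)
  expect_equal(shadow_length(113, 27.0), 57.576375792870451)
  expect_equal(shadow_length(113, 27.0, mode = "geometric"), 221.77498712208202)

  # tan * cot identity: the two modes multiply to h^2 for any angle
  withr::with_seed(42, {
    for (k in 1:25) {
      h <- runif(1, 1, 200)
      th <- runif(1, 1, 89)
      expect_equal(
        shadow_length(h, th) * shadow_length(h, th, "geometric"),
        h^2
      )
    }
  })

  expect_error(shadow_length(100, 0, "geometric"), class = "canopylight_domain_error")
  expect_error(shadow_length(-1, 30), class = "canopylight_domain_error")
})

test_that("shaded-region illuminance combines direct, diffuse and reflected terms", {
  s1 <- stage_params(10, 60, direct_solar_intensity = 1000,
                     diffuse_coefficient = 0, reflectance = 0)
  expect_equal(shadow_illuminance(s1, f_value = 0), direct_illuminance(1000, 60))

  s2 <- stage_params(10, 1e-9, direct_solar_intensity = 1000,
                     diffuse_coefficient = 0.1, reflectance = 0.1)
  expect_equal(shadow_illuminance(s2, f_value = 0), 1200, tolerance = 1e-9)

  # hand-evaluated: 1000*(cos 60 - 0.2) + 1000*0.15 + 1000*0.1 = 550
  s3 <- stage_params(10, 60, direct_solar_intensity = 1000,
                     diffuse_coefficient = 0.15, reflectance = 0.1)
  expect_equal(shadow_illuminance(s3, f_value = 0.2), 550)

  expect_error(shadow_illuminance(s3, f_value = Inf), class = "canopylight_domain_error")
  expect_error(shadow_illuminance(list(), 0), class = "canopylight_domain_error")
})

test_that("intensity prediction equals the explicit ten-term sum", {
  intercept_only <- poly_coefficients(c(77, rep(0, 9)))
  expect_equal(predict_intensity(intercept_only, 50, 20, 100), 77)
  zeros <- poly_coefficients(rep(0, 10))
  expect_equal(predict_intensity(zeros, 50, 20, 100), 0)

  # frozen value from an independent term-by-term loop over the published
  # coefficients at the podding stage, l = 30 (note: extrapolates below zero)
  expect_equal(predict_intensity(tab_coeffs, 113, 27.0, 30), -12314.6)

  # brute-force loop oracle on random inputs
  brute <- function(a, h, th, l) {
    tt <- c(1, h, th, l, h^2, h * th, th * l, th^2, h * l, l^2)
    s <- 0
    for (i in 1:10) s <- s + a[i] * tt[i]
    s
  }
  withr::with_seed(7, {
    for (k in 1:1000) {
      a <- rnorm(10, sd = 10^runif(1, -2, 5))
      h <- runif(1, 0, 200); th <- runif(1, 1, 89); l <- runif(1, 30, 180)
      got <- predict_intensity(poly_coefficients(a), h, th, l)
      want <- brute(a, h, th, l)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })

  expect_warning(
    predict_intensity(tab_coeffs, 113, 27, 200),
    "outside the calibrated position range"
  )
  expect_silent(predict_intensity(tab_coeffs, 113, 27, c(30, 180)))
})

test_that("least-squares fit recovers generating coefficients on clean data", {
  grid <- tidyr::expand_grid(calibration_grid(), l_cm = seq(30, 180, 30))
  tbl <- tibble::tibble(
    h_cm = grid$h_cm, theta_deg = grid$theta_deg, l_cm = grid$l_cm,
    intensity = predict_intensity(tab_coeffs, grid$h_cm, grid$theta_deg, grid$l_cm)
  )
  fit <- fit_light_model(tbl)
  rel <- abs(unclass(fit$coefficients) - unclass(tab_coeffs)) / abs(unclass(tab_coeffs))
  expect_true(max(rel) < 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_samples, nrow(tbl))

  # arbitrary coefficient vectors recover too
  withr::with_seed(11, {
    for (k in 1:5) {
      a <- rnorm(10, sd = 10^runif(10, -1, 4))
      tbl$intensity <- predict_intensity(
        poly_coefficients(a), grid$h_cm, grid$theta_deg, grid$l_cm
      )
      fit_k <- fit_light_model(tbl)
      expect_equal(unname(unclass(fit_k$coefficients)), a, tolerance = 1e-6)
    }
  })
})

test_that("fit handles constant response, underdetermination and rank deficiency", {
  grid <- tidyr::expand_grid(calibration_grid(), l_cm = seq(30, 180, 30))
  tbl <- tibble::tibble(
    h_cm = grid$h_cm, theta_deg = grid$theta_deg, l_cm = grid$l_cm,
    intensity = 42
  )
  fit <- fit_light_model(tbl)
  expect_equal(as.numeric(fit$coefficients["a0"]), 42, tolerance = 1e-9)
  expect_true(all(abs(unclass(fit$coefficients)[-1]) < 1e-9))
  expect_equal(fit$r_squared, 1)

  expect_error(fit_light_model(tbl[1:9, ]), class = "canopylight_singular_design")

  # the five paired field stages cannot identify the six (h, theta) terms:
  # the error must name at least one deficient column
  paired <- generate_measurements(tab_coeffs, growth_stages())
  err <- tryCatch(fit_light_model(paired), condition = function(e) e)
  expect_s3_class(err, "canopylight_singular_design")
  expect_match(conditionMessage(err), "theta2|h2|h_theta")
})

test_that("noisy fits converge to the generating coefficients as n grows", {
  recovery_err <- function(n, seed) {
    withr::with_seed(seed, {
      h <- runif(n, 0, 150)
      th <- runif(n, 5, 85)
      l <- runif(n, 30, 180)
      y <- predict_intensity(tab_coeffs, h, th, l) + rnorm(n, sd = 500)
      fit <- fit_light_model(
        tibble::tibble(h_cm = h, theta_deg = th, l_cm = l, intensity = y)
      )
      max(abs(unclass(fit$coefficients) - unclass(tab_coeffs)) /
            pmax(abs(unclass(tab_coeffs)), 1))
    })
  }
  errs <- vapply(c(30, 300, 3000), function(n) {
    mean(vapply(99:103, function(s) recovery_err(n, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  # nonzero noise: r-squared strictly below one
  withr::with_seed(100, {
    tbl <- generate_measurements(tab_coeffs, calibration_grid(),
      noise_sd = 2000, n_reps = 2
    )
  })
  expect_lt(fit_light_model(tbl)$r_squared, 1)
})

test_that("compensation value applies the planting-direction cosine", {
  st90 <- stage_params(113, 27, planting_direction_deg = 90)
  expect_equal(compensation_value(tab_coeffs, st90, 90), 0, tolerance = 1e-8)

  st0 <- stage_params(113, 27, planting_direction_deg = 0,
                      direct_solar_intensity = 1,
                      diffuse_coefficient = 0, reflectance = 0)
  expect_equal(
    compensation_value(tab_coeffs, st0, 120),
    predict_intensity(tab_coeffs, 113, 27, 120)
  )

  # frozen hand-evaluated value: (pred(113, 27, 90) + 0.15 + 0.1) * 1 * cos(0)
  st <- stage_params(113, 27, planting_direction_deg = 0,
                     direct_solar_intensity = 1,
                     diffuse_coefficient = 0.15, reflectance = 0.1)
  expect_equal(compensation_value(tab_coeffs, st, 90), 20980.85)

  # linear in E0
  st2 <- stage_params(113, 27, direct_solar_intensity = 7)
  st1 <- stage_params(113, 27, direct_solar_intensity = 1)
  expect_equal(
    compensation_value(tab_coeffs, st2, 60),
    7 * compensation_value(tab_coeffs, st1, 60)
  )
})

test_that("coefficient and stage containers validate and round-trip", {
  expect_error(poly_coefficients(1:9), class = "canopylight_domain_error")
  expect_error(poly_coefficients(c(1:9, NA)), class = "canopylight_domain_error")

  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(tab_coeffs, path)
  expect_identical(unclass(read_coefficients(path)), unclass(tab_coeffs))

  shipped <- read_coefficients(
    system.file("extdata", "published_coefficients.json", package = "canopylight")
  )
  expect_identical(unclass(shipped), unclass(tab_coeffs))

  stages_csv <- system.file("extdata", "growth_stages.csv", package = "canopylight")
  st <- read_stage_params(stages_csv, row = 3)
  expect_equal(st$height_difference_cm, 113)
  expect_equal(st$solar_elevation_deg, 27.0)
  shipped_stages <- utils::read.csv(stages_csv)
  expect_equal(as.numeric(shipped_stages$h_cm), growth_stages()$h_cm)
  expect_equal(shipped_stages$theta_deg, growth_stages()$theta_deg)

  spath <- withr::local_tempfile(fileext = ".json")
  write_stage_params(podding, spath)
  st2 <- read_stage_params(spath)
  expect_equal(st2, podding)

  expect_error(stage_params(-1, 30), class = "canopylight_domain_error")
  expect_error(stage_params(10, 95), class = "canopylight_domain_error")
  expect_error(stage_params(10, 30, diffuse_coefficient = 1.5),
    class = "canopylight_domain_error"
  )
})
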