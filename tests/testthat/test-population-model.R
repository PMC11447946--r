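test_that("age categorization uses a strict breakpoint at 60 years", {
  expect_identical(agecat(c(19, 60, 60.5, 82)), c(0L, 0L, 1L, 1L))
})

test_that("typical clearance reproduces the covariate-model arithmetic", {
  th <- pk_theta()
  # reference carrier at 70 kg, age <= 60
  expect_equal(typical_params(th, 54, 70, TRUE)$CL, 26.5)
  # genotype multiplier for non-carriers
  expect_equal(typical_params(th, 54, 70, FALSE)$CL, 26.5 * 0.666,
               tolerance = 1e-12)
  # age decline beyond 60 uses full age in years
  expect_equal(typical_params(th, 80, 70, TRUE)$CL, 26.5 - 0.0562 * 80,
               tolerance = 1e-12)
  # allometric scaling of CL with exponent 0.75
  expect_equal(typical_params(th, 54, 56, TRUE)$CL, 26.5 * (56 / 70)^0.75,
               tolerance = 1e-12)
  # flat in age below the breakpoint
  expect_equal(typical_params(th, 25, 70, TRUE)$CL,
               typical_params(th, 60, 70, TRUE)$CL)
})

test_that("volumes and distribution clearance scale per the final model", {
  th <- pk_theta()
  tv <- typical_params(th, 54, 56, TRUE)
  expect_equal(tv$Vc, 327 * 56 / 70)
  expect_equal(tv$CLD, 51.9 * (56 / 70)^0.75)
  expect_equal(tv$Vp, 298) # peripheral volume not scaled
  expect_equal(tv$Ka, 2)
  expect_equal(tv$ALAG, 0.341)
})

test_that("carrier/non-carrier typical-CL ratio is 1/theta2 at all ages <= 60", {
  th <- pk_theta()
  for (age in c(20, 45, 60)) {
    for (bw in c(50, 70, 100)) {
      r <- typical_params(th, age, bw, TRUE)$CL /
        typical_params(th, age, bw, FALSE)$CL
      expect_equal(r, 1 / 0.666, tolerance = 1e-12)
    }
  }
})

test_that("hematocrit standardization is the linear partition rescale", {
  expect_equal(standardize_hct(6, 30), 9)
  expect_equal(destandardize_hct(9, 30), 6)
  x <- c(0, 1.3, 7.25, 40)
  expect_equal(standardize_hct(x, 45), x)
  expect_equal(destandardize_hct(x, 45), x)
  # exact round trip across the supported range
  for (h in seq(12, 58, by = 2)) {
    expect_equal(destandardize_hct(standardize_hct(x, h), h), x,
                 tolerance = 1e-12)
  }
  # monotone decreasing in hematocrit for fixed standardized value
  grid <- seq(15, 55, 5)
  expect_true(all(diff(destandardize_hct(9, grid)) > 0))
  expect_true(all(diff(standardize_hct(9, grid)) < 0))
  expect_error(standardize_hct(5, 9), "hematocrit")
  expect_error(standardize_hct(5, 61), "hematocrit")
})

test_that("individual parameters follow the exponential BPV model", {
  th <- pk_theta()
  expect_equal(individual_params(th, 54, 70, TRUE, 0, 0),
               typical_params(th, 54, 70, TRUE))
  set.seed(7)
  eta <- rnorm(1e5, 0, 0.321)
  cl <- individual_params(th, 54, 70, TRUE, eta_cl = eta)$CL
  # log-normal: median at the typical value, CV = sqrt(exp(omega^2)-1)
  expect_equal(median(cl), 26.5, tolerance = 0.01)
  expect_equal(sd(cl) / mean(cl), sqrt(exp(0.321^2) - 1), tolerance = 0.02)
})

test_that("proportional residual simulation has the stated spread", {
  p <- structural_params(CL = 17.65, Vc = 327, Vp = 298, CLD = 51.9)
  doses <- data.frame(time = 0, amount = 7)
  out0 <- predict_observation(p, doses, c(2, 12), sigma_prop = 0)
  expect_equal(out0$y, out0$pred)
  set.seed(11)
  out <- predict_observation(p, doses, rep(12, 1e5), sigma_prop = 0.282)
  expect_equal(sd(out$y / out$pred - 1), 0.282, tolerance = 0.01)
  # pre-lag prediction is zero, and proportional noise keeps it zero
  pre <- predict_observation(p, doses, 0.1, sigma_prop = 0.282)
  expect_identical(pre$y, 0)
})

test_that("covariate support bounds are enforced", {
  th <- pk_theta()
  expect_error(typical_params(th, 10, 70, TRUE), "age")
  expect_error(typical_params(th, 54, 20, TRUE), "bodyweight")
  th_bad <- pk_theta(theta3 = 0.5)
  expect_error(typical_params(th_bad, 95, 70, FALSE), "non-positive")
})

test_that("model configuration round-trips through the key-value file", {
  th <- pk_theta(theta1 = 24.123456789, fixed = c("ka", "alag"))
  om <- pk_omega(0.3, 0.45, 0.27)
  path <- tempfile(fileext = ".yaml")
  write_model_config(th, om, path, standardize_hct = TRUE)
  cfg <- read_model_config(path)
  nm <- names(unclass(th))
  expect_identical(unclass(cfg$theta)[nm], unclass(th)[nm])
  expect_identical(attr(cfg$theta, "fixed"), attr(th, "fixed"))
  expect_identical(unclass(cfg$omega), unclass(om))
  expect_true(cfg$standardize_hct)
})
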