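# A tiny deterministic dataset builder: hct fixed at 45 so the standardized
# and observed scales coincide unless stated otherwise.
tiny_dataset <- function(n = 2, n_rich = 1, seed = 3, hct = 45,
                         omega = pk_omega(0.3, 0.4, 0.2)) {
  cov <- sample_covariates(n, seed = seed)
  cov$hct_day5 <- cov$hct_day10 <- cov$hct_day15 <- hct
  skel <- build_design(cov, design_spec(n_total = n, n_rich = n_rich))
  simulate_dataset(skel, pk_theta(), omega, seed = seed + 100)
}

fixed_effects_m2ll <- function(data, theta, sigma) {
  d <- validate_pk_dataset(data)
  obs <- d[d$EVID == 0 & d$MDV == 0, ]
  dose <- d[d$EVID == 1, ]
  total <- 0
  for (i in seq_len(nrow(obs))) {
    sub <- dose[dose$ID == obs$ID[i] & dose$TIME < obs$TIME[i], ]
    p <- typical_params(theta, obs$AGE[i], obs$BW[i], obs$CYP3A5[i] == 1)
    f <- conc_profile(p, data.frame(time = sub$TIME, amount = sub$AMT),
                      obs$TIME[i])$conc
    y <- standardize_hct(obs$DV[i], obs$HCT[i])
    total <- total + log(sigma^2 * f^2) + (y - f)^2 / (sigma^2 * f^2)
  }
  total
}

test_that("with zero random effects the OFV is the fixed-effects -2 log likelihood", {
  d <- tiny_dataset(n = 3, n_rich = 2)
  sig <- 0.25
  expected <- fixed_effects_m2ll(d, pk_theta(), sig)
  got <- ofv_laplace(d, pk_theta(), pk_omega(0, 0, sig))
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("Laplace OFV matches adaptive quadrature for a one-observation subject", {
  d <- tiny_dataset(n = 1, n_rich = 0) # 3 trough observations
  # keep only the first observation
  obs_rows <- which(d$EVID == 0)
  d1 <- d[-obs_rows[-1], ]
  th <- pk_theta()
  om <- pk_omega(omega_cl = 0.321, omega_vc = 0, sigma_prop = 0.25)
  obs <- d1[d1$EVID == 0, ]
  dose <- d1[d1$EVID == 1 & d1$TIME < obs$TIME, ]
  y <- standardize_hct(obs$DV, obs$HCT)
  f_of <- function(eta) {
    vapply(eta, function(e) {
      p <- individual_params(th, obs$AGE, obs$BW, obs$CYP3A5 == 1, eta_cl = e)
      conc_profile(as_structural_params(p),
                   data.frame(time = dose$TIME, amount = dose$AMT),
                   obs$TIME)$conc
    }, numeric(1))
  }
  integrand <- function(eta) {
    f <- f_of(eta)
    stats::dnorm(y, f, om$sigma_prop * f) * stats::dnorm(eta, 0, om$omega_cl)
  }
  marg <- stats::integrate(integrand, -3, 3, rel.tol = 1e-10)$value
  ofv_exact <- -2 * log(marg) - log(2 * pi) # same constant convention
  got <- ofv_laplace(d1, th, om)
  expect_lt(abs(got - ofv_exact), 0.1)
})

test_that("OFV is invariant to subject ordering", {
  d <- tiny_dataset(n = 4, n_rich = 2)
  o1 <- ofv_laplace(d, pk_theta(), pk_omega())
  ids <- unique(d$ID)
  perm <- rev(ids)
  d2 <- dplyr::bind_rows(lapply(perm, function(i) d[d$ID == i, ]))
  o2 <- ofv_laplace(d2, pk_theta(), pk_omega())
  expect_equal(o1, o2, tolerance = 1e-6)
})

test_that("OFV at the generating parameters beats strongly perturbed ones", {
  d <- tiny_dataset(n = 25, n_rich = 8, seed = 21)
  truth <- ofv_laplace(d, pk_theta(), pk_omega())
  pert <- ofv_laplace(d, pk_theta(theta1 = 26.5 * 1.5), pk_omega())
  expect_lt(truth, pert)
})

test_that("likelihood-ratio thresholds map to the conventional p-values", {
  out <- lrt_threshold(c(3.841, 7.879, 10.83))
  expect_equal(out$p_value, c(0.05, 0.005, 0.001), tolerance = 1e-3)
  expect_identical(lrt_threshold(3.9)$significant, TRUE)
  expect_identical(lrt_threshold(3.7)$significant, FALSE)
  expect_equal(lrt_threshold(7.879, alpha = 0.005)$p_value, 0.005,
               tolerance = 1e-3)
})

test_that("empirical-Bayes estimates recover zero etas from noise-free data", {
  cov <- sample_covariates(2, seed = 8)
  cov$hct_day5 <- cov$hct_day10 <- cov$hct_day15 <- 45
  skel <- build_design(cov, design_spec(n_total = 2, n_rich = 2))
  d <- simulate_dataset(skel, pk_theta(), pk_omega(0, 0, 1e-5), seed = 9)
  ebe <- empirical_bayes(d, pk_theta(), pk_omega(0.3, 0.4, 1e-3))
  expect_true(all(abs(ebe$eta_cl) < 1e-3))
  expect_true(all(abs(ebe$eta_vc) < 1e-3))
})

test_that("a subject without observations gets the prior-mode EBE of zero", {
  d <- tiny_dataset(n = 3, n_rich = 1)
  # drop all observations of subject 2 (keep MDV = 1 scheduled rows absent)
  d2 <- d[!(d$ID == 2 & d$EVID == 0), ]
  ebe <- empirical_bayes(d2, pk_theta(), pk_omega())
  expect_identical(ebe$eta_cl[ebe$ID == 2], 0)
  expect_identical(ebe$eta_vc[ebe$ID == 2], 0)
  expect_true(any(ebe$eta_cl[ebe$ID != 2] != 0))
})

test_that("shrinkage is 100% when EBEs are all zero and NA when omega is zero", {
  ebes <- tibble::tibble(eta_cl = rep(0, 5), eta_vc = rep(0, 5))
  s <- shrinkage(ebes, pk_omega(0.3, 0.4, 0.2))
  expect_equal(s$shrinkage_pct, c(100, 100))
  s0 <- shrinkage(ebes, pk_omega(0, 0.4, 0.2))
  expect_true(is.na(s0$shrinkage_pct[s0$quantity == "eta_cl"]))
})

test_that("EBE spread is consistent with the reported shrinkage", {
  d <- tiny_dataset(n = 30, n_rich = 10, seed = 44)
  fit <- pk_fit(d, theta = pk_theta(fixed = c("ka", "vp", "cld70", "alag")),
                control = fit_control(se = FALSE))
  s <- fit$shrinkage
  expect_equal(sd(fit$ebes$eta_cl) / fit$omega$omega_cl,
               1 - s$eta_cl / 100, tolerance = 1e-8)
  expect_equal(sd(fit$ebes$eta_vc) / fit$omega$omega_vc,
               1 - s$eta_vc / 100, tolerance = 1e-8)
})

test_that("profile OFV in theta1 has its minimum near the generating value", {
  # all variability known and fixed; only theta1 moves
  d <- tiny_dataset(n = 60, n_rich = 20, seed = 13,
                    omega = pk_omega(0.321, 0.482, 0.1))
  om <- pk_omega(0.321, 0.482, 0.1)
  grid <- seq(0.85, 1.15, by = 0.05) * 26.5
  prof <- vapply(grid, function(t1)
    ofv_laplace(d, pk_theta(theta1 = t1), om), numeric(1))
  best <- grid[which.min(prof)]
  expect_lt(abs(best - 26.5) / 26.5, 0.11)
  # curvature: endpoints clearly worse than the interior minimum
  expect_gt(prof[1], min(prof) + 2)
  expect_gt(prof[length(prof)], min(prof) + 2)
})

test_that("fitting recovers parameters on a mid-sized simulated design", {
  d <- tiny_dataset(n = 40, n_rich = 14, seed = 71,
                    omega = pk_omega(0.321, 0.482, 0.282))
  fit <- pk_fit(d, theta = pk_theta(fixed = c("ka", "vp", "cld70")),
                control = fit_control(se = TRUE))
  expect_identical(fit$convergence, 0L)
  est <- setNames(fit$par$estimate, fit$par$term)
  expect_lt(abs(est[["theta1"]] - 26.5) / 26.5, 0.25)
  expect_lt(abs(est[["sigma_prop"]] - 0.282) / 0.282, 0.2)
  expect_lt(abs(est[["alag"]] - 0.341) / 0.341, 0.25)
  # RSEs available and positive for free parameters
  free <- fit$par[!fit$par$fixed, ]
  expect_true(all(is.finite(free$rse_pct) & free$rse_pct > 0))
  expect_gte(fit$condition_number, 1)
  # tidy/glance accessors
  expect_identical(tidy(fit), fit$par)
  g <- glance(fit)
  expect_identical(g$n_subjects, 40L)
  expect_identical(g$n_obs, nrow(d[d$EVID == 0, ]))
})

test_that("an empty candidate set returns the base model unchanged", {
  d <- tiny_dataset(n = 10, n_rich = 4, seed = 5)
  th <- pk_theta(fixed = c("ka", "vp", "cld70", "vc70", "alag"))
  out <- covariate_search(d, th, pk_omega(), candidates = list(),
                          control = fit_control(se = FALSE))
  expect_identical(out$selected, character(0))
  base <- pk_fit(d, th, pk_omega(), covariates = list(),
                 control = fit_control(se = FALSE))
  expect_equal(out$fit$ofv, base$ofv, tolerance = 1e-6)
  expect_identical(nrow(out$log), 0L)
})
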