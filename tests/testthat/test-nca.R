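test_that("linear-log trapezoid handles flat, rising and falling segments", {
  # rectangle
  expect_equal(auc_linlog(c(0, 24), c(5, 5)), 120)
  # rising straight line uses the linear rule (triangle)
  expect_equal(auc_linlog(c(0, 24), c(0, 10)), 120)
  # mono-exponential decline uses the log rule exactly
  k <- 0.11
  c0 <- 18
  t <- 9
  expect_equal(auc_linlog(c(0, t), c(c0, c0 * exp(-k * t))),
               c0 * (1 - exp(-k * t)) / k, tolerance = 1e-12)
  # zero endpoint falls back to the linear rule
  expect_equal(auc_linlog(c(0, 2), c(4, 0)), 4)
})

test_that("the AUC is additive over sub-intervals and collinear points are neutral", {
  t <- c(0, 1, 2, 4, 8, 12, 24)
  cc <- c(0, 12, 16, 11, 6, 3.5, 1.2)
  whole <- auc_linlog(t, cc, c(0, 24))
  expect_equal(auc_linlog(t, cc, c(0, 8)) + auc_linlog(t, cc, c(8, 24)),
               whole, tolerance = 1e-12)
  # inserting a point on the log interpolant of a falling segment is neutral
  tm <- 6
  cm <- 11 * (6 / 11)^((tm - 4) / 4) # log interpolation between (4,11), (8,6)
  t2 <- c(0, 1, 2, 4, tm, 8, 12, 24)
  c2 <- c(0, 12, 16, 11, cm, 6, 3.5, 1.2)
  expect_equal(auc_linlog(t2, c2, c(0, 24)), whole, tolerance = 1e-10)
  # and on the linear interpolant of a rising segment
  t3 <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  c3 <- c(0, 6, 12, 16, 11, 6, 3.5, 1.2)
  expect_equal(auc_linlog(t3, c3, c(0, 24)), whole, tolerance = 1e-10)
})

test_that("no extrapolation is performed outside the sampled range", {
  expect_error(auc_linlog(c(1, 24), c(5, 4), c(0, 24)), "not covered")
  expect_error(auc_linlog(c(0, 20), c(5, 4), c(0, 24)), "not covered")
})

test_that("dense sampling of a model profile reproduces the analytic integral", {
  p <- structural_params(CL = 17.65, Vc = 327, Vp = 298, CLD = 51.9)
  doses <- data.frame(time = seq(0, 96, 24), amount = 7)
  t <- seq(96, 120, by = 0.1)
  prof <- conc_profile(p, doses, t)
  expect_equal(auc_linlog(prof$time, prof$conc, c(96, 120)),
               analytic_auc(p, doses, 96, 120), tolerance = 1e-3)
})

test_that("troughs are the observations just before a dose", {
  cov <- sample_covariates(3, seed = 6)
  skel <- build_design(cov, design_spec(n_total = 3, n_rich = 1))
  d <- simulate_dataset(skel, seed = 10)
  tr <- trough_extract(d)
  # day-5/10/15 troughs at the dose instants for every subject
  expect_setequal(unique(tr$time), c(96, 216, 336, 120))
  # the rich subject's 24 h post-dose sample doubles as the day-6 trough
  rich <- tr[tr$ID == 1, ]
  expect_true(120 %in% rich$time)
  # values equal the recorded DV at those instants
  for (k in seq_len(nrow(tr))) {
    expect_equal(tr$ctrough[k],
                 d$DV[d$ID == tr$ID[k] & d$TIME == tr$time[k] & d$EVID == 0])
  }
})

test_that("occasions without a pre-dose sample are absent, never imputed", {
  cov <- sample_covariates(2, seed = 6)
  skel <- build_design(cov, design_spec(n_total = 2, n_rich = 0))
  d <- simulate_dataset(skel, seed = 10)
  d2 <- d[!(d$ID == 1 & d$EVID == 0 & d$TIME == 216), ]
  tr <- trough_extract(d2)
  expect_false(any(tr$ID == 1 & tr$time == 216))
  expect_true(any(tr$ID == 2 & tr$time == 216))
})

test_that("simulated steady-state troughs match the structural model", {
  p <- structural_params(CL = 17.65, Vc = 327, Vp = 298, CLD = 51.9)
  doses <- data.frame(time = seq(0, 96, 24), amount = 7)
  expect_equal(conc_profile(p, doses, 120)$conc,
               conc_profile(p, doses, seq(96, 120, 0.5))$conc[49],
               tolerance = 1e-12)
})

test_that("geometric means and CIs behave as the log-scale summary", {
  expect_equal(geomean_ci(c(4, 9))$geomean, 6)
  all_equal <- geomean_ci(rep(7.3, 10))
  expect_equal(all_equal$geomean, 7.3)
  expect_equal(all_equal$ci_lo, 7.3)
  expect_equal(all_equal$ci_hi, 7.3)
  set.seed(15)
  x <- rlnorm(1e5, log(7), 0.4)
  g <- geomean_ci(x)
  expect_equal(g$geomean, 7, tolerance = 0.005)
  expect_true(g$ci_lo < g$geomean & g$geomean < g$ci_hi)
  expect_error(geomean_ci(c(3, 0, 5)), "index 2")
})

test_that("per-occasion metrics table combines troughs and AUCs", {
  cov <- sample_covariates(4, seed = 16)
  skel <- build_design(cov, design_spec(n_total = 4, n_rich = 2))
  d <- simulate_dataset(skel, seed = 20)
  m <- nca_metrics(d)
  rich <- m[m$ID == 1 & m$DAY == 5, ]
  expect_true(is.finite(rich$auc24[1]))
  expect_equal(rich$auc24_per_dose, rich$auc24 / rich$dose)
  # trough-only occasions carry no AUC
  sparse <- m[m$ID == 4, ]
  expect_true(all(is.na(sparse$auc24)))
  expect_true(all(is.finite(sparse$ctrough)))
})
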