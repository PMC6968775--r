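test_that("lambda_z recovers the slope of exact log-linear data", {
  p <- exp_profile(c0 = 100, k = 0.3, times = c(2, 4, 8))
  fit <- lambda_z(p)
  expect_equal(fit$lambda_z, 0.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # half_life o lambda_z round-trips the generating half-life
  for (k in c(0.1, 0.5, 2)) {
    p <- exp_profile(k = k, times = c(0.5, 1, 2, 4, 8))
    expect_equal(lambda_z(p, n_terminal = 3)$t_half, log(2) / k,
                 tolerance = 1e-9)
  }
})

test_that("lambda_z shrinks its window past zeros and rejects flat data", {
  p <- conc_profile("d", "WT", "iv", "systemic", c(1, 2, 4, 8),
                    c(100 * exp(-0.3 * c(1, 2, 4)), 0), 1)
  fit <- lambda_z(p, n_terminal = 3)   # trailing zero excluded
  expect_equal(fit$lambda_z, 0.3, tolerance = 1e-12)
  flat <- conc_profile("d", "WT", "iv", "systemic", 1:4, rep(5, 4), 1)
  expect_error(lambda_z(flat), "no terminal decay")
})

test_that("half_life is ln2 over lambda_z", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.3466), 2.0, tolerance = 1e-3)
  expect_equal(round(half_life(0.4916), 2), 1.41)
  expect_error(half_life(0))
})

test_that("AUC/AUMC to infinity match closed forms for exponential decay", {
  times <- seq(0.01, 40, by = 0.01)
  p <- exp_profile(c0 = 100, k = 0.5, times = times)
  out <- auc_aumc_inf(p, lambda_z = 0.5)
  expect_equal(out$auc_inf, 100 / 0.5, tolerance = 1e-3)
  expect_equal(out$aumc_inf, 100 / 0.5^2, tolerance = 1e-3)

  zero <- conc_profile("d", "WT", "oral", "systemic", 1:3, rep(0, 3), 1)
  expect_equal(auc_aumc_inf(zero)$auc_inf, 0)
  expect_equal(auc_aumc_inf(zero)$aumc_inf, 0)

  # hand-computed small case: nodes (0,0),(0.5,5),(1,10), lambda_z = 1
  ramp <- conc_profile("d", "WT", "oral", "systemic", c(0, 0.5, 1),
                       c(0, 5, 10), 1)
  out2 <- auc_aumc_inf(ramp, lambda_z = 1)
  expect_equal(out2$auc_inf, 5 + 10)        # trapezoid 5 + tail 10
  expect_equal(out2$aumc_inf, 3.75 + 20)    # moment trapezoid + tail
})

test_that("trapezoidal AUC converges at order 2 for exponential decay", {
  err <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    times <- seq(dt, 20, by = dt)
    p <- exp_profile(c0 = 50, k = 0.7, times = times)
    abs(auc_aumc_inf(p, lambda_z = 0.7)$auc_inf - 50 / 0.7)
  })
  ratio <- err[-length(err)] / err[-1]
  expect_true(all(ratio > 3.5 & ratio < 4.5))
})

test_that("linlog integration is exact on declining exponentials", {
  p <- exp_profile(c0 = 80, k = 0.6, times = c(0.5, 1, 2, 4, 8))
  out <- auc_aumc_inf(p, lambda_z = 0.6, method = "linlog")
  expect_equal(out$auc_inf, 80 / 0.6, tolerance = 1e-10)
  expect_equal(out$aumc_inf, 80 / 0.36, tolerance = 1e-10)
})

test_that("clearance and Vdss reproduce printed reference values", {
  expect_equal(cl_tot(dose_to_nmol_per_kg(1, 331.34), 886), 3.41,
               tolerance = 0.002)
  expect_equal(cl_tot(dose_to_nmol_per_kg(1, 238.16), 1840), 2.28,
               tolerance = 0.002)
  expect_equal(cl_tot(100, 100), 1.0)
  expect_error(cl_tot(-1, 10))
  expect_equal(vd_ss(1, 1, 1), 1)
  # printed ciprofloxacin pair implies MRT = Vdss / CL
  expect_equal(vd_ss(886 * 1.041, 886, 3.41) / 3.41, 1.041)
})

test_that("one-compartment iv bolus NCA recovers CL and V exactly", {
  ke <- 0.55; v <- 2.5; dose <- dose_to_nmol_per_kg(1, 400)
  times <- seq(0.01, 30, by = 0.01)
  p <- conc_profile("d", "WT", "iv", "systemic", times,
                    dose / v * exp(-ke * times), 1)
  res <- nca(p, dose_nmol_per_kg = dose)
  expect_equal(res$lambda_z, ke, tolerance = 1e-9)
  expect_equal(res$cltot, v * ke, tolerance = 1e-3)
  expect_equal(res$vdss, v, tolerance = 1e-3)
  expect_equal(res$mrt, 1 / ke, tolerance = 1e-3)
  expect_equal(res$c0, dose / v, tolerance = 1e-6)
  # vdss = mrt * cl by construction
  expect_equal(res$vdss, res$mrt * res$cltot)
})

test_that("MAT is the MRT difference and matches 1/ka for Bateman input", {
  expect_equal(mat(2.0, 1.5), 0.5)
  expect_equal(mat(1.5, 1.5), 0)
  expect_warning(out <- mat(1.0, 1.5), "negative")
  expect_equal(out, -0.5)

  ka <- 2; ke <- 0.5
  times <- seq(0.005, 60, by = 0.005)
  oral <- bateman_profile(s = 100, ka = ka, ke = ke, times = times)
  iv <- conc_profile("d", "WT", "iv", "systemic", times,
                     250 * exp(-ke * times), 1)
  mrt_oral <- with(auc_aumc_inf(oral, ke), aumc_inf / auc_inf)
  mrt_iv <- with(auc_aumc_inf(iv, ke), aumc_inf / auc_inf)
  expect_equal(mat(mrt_oral, mrt_iv), 1 / ka, tolerance = 1e-3)
})

test_that("LLOQ censoring drops sub-quantification observations", {
  p <- conc_profile("d", "WT", "iv", "systemic", c(0.5, 1, 2, 4, 8),
                    c(100, 60, 20, 5, 0.4), 1)
  res <- nca(p, dose_nmol_per_kg = 1000, lloq = 1)
  full <- nca(p, dose_nmol_per_kg = 1000)
  expect_false(isTRUE(all.equal(res$lambda_z, full$lambda_z)))
  expect_error(nca(p, lloq = 50), "LLOQ")
})
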