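test_that("noiseless one-phase decay data are fitted exactly", {
  s <- generate_plasma_curve(50, 0.1, times = 1:5, noise_cv = 0)
  fit <- fit_disappearance(s)
  expect_s3_class(fit, "decay_fit")
  expect_equal(fit$C0, 50, tolerance = 1e-6)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$qc_pass)
})

test_that("constant concentrations give k ~ 0 and C0 ~ the sample mean", {
  s <- tibble::tibble(time = 0:5, concentration = 42)
  fit <- fit_disappearance(s)
  expect_equal(fit$k, 0, tolerance = 1e-8)
  expect_equal(fit$C0, 42, tolerance = 1e-6)
})

test_that("fit rejects degenerate inputs", {
  expect_error(fit_disappearance(
    tibble::tibble(time = c(1, 2), concentration = c(3, 2))), ">= 3")
  expect_error(fit_disappearance(
    tibble::tibble(time = 1:4, concentration = 0)), "all-zero")
  expect_error(fit_disappearance(
    tibble::tibble(time = c(1, 1, 1), concentration = c(1, 2, 3))),
    "positive time range")
})

test_that("k is recovered from noisy curves with small median error and bias", {
  k_true <- 0.2
  errs <- vapply(1:200, function(i) {
    s <- generate_plasma_curve(100, k_true,
                               times = seq(0.1, 5, length.out = 50),
                               noise_cv = 0.05, seed = 1000 + i)
    fit_disappearance(s)$k
  }, numeric(1))
  rel <- (errs - k_true) / k_true
  expect_lt(median(abs(rel)), 0.05)
  expect_lt(abs(mean(rel)), 0.05)  # bias below the noise CV
})

test_that("poor fits are QC-flagged, not rejected", {
  # heavy noise destroys the exponential signal
  s <- suppressWarnings(
    generate_plasma_curve(10, 0.01, times = seq(0.1, 5, length.out = 30),
                          noise_cv = 1.5, seed = 8))
  s$concentration <- pmax(s$concentration, 0)
  fit <- fit_disappearance(s)
  expect_s3_class(fit, "decay_fit")
  expect_false(fit$qc_pass)
  expect_lte(fit$r2, 0.6)
})

test_that("closed-form integral matches adaptive quadrature over a grid", {
  grid <- expand.grid(C0 = c(1, 50, 200), k = c(0, 1e-6, 0.05, 0.2, 1),
                      x = c(0.5, 1, 5, 20))
  for (i in seq_len(nrow(grid))) {
    C0 <- grid$C0[i]; k <- grid$k[i]; x <- grid$x[i]
    closed <- integral_to(list(C0 = C0, k = k), x)
    quad <- integrate(function(t) C0 * exp(-k * t), 0, x,
                      rel.tol = 1e-12)$value
    expect_lt(abs(closed - quad) / quad, 1e-8)
  }
  # k = 0 limit and the worked value
  expect_equal(integral_to(list(C0 = 10, k = 0), 5), 50)
  expect_equal(integral_to(list(C0 = 100, k = 0.2), 5), 316.0603,
               tolerance = 1e-6)
  expect_error(integral_to(list(C0 = 10, k = 0.1), 0), "> 0")
})

test_that("the integral increases monotonically to C0/k", {
  xs <- c(1, 5, 20, 100, 1000)
  vals <- integral_to(list(C0 = 80, k = 0.3), xs)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= 80 / 0.3))
  expect_equal(vals[length(vals)], 80 / 0.3, tolerance = 1e-6)
})

test_that("tail-tip correction is exact, identity at zero, and monotone", {
  expect_equal(correct_tail_tip(950, 0.05), 1000)
  expect_equal(correct_tail_tip(123.4, 0), 123.4)
  fr <- seq(0, 0.19, by = 0.01)
  expect_true(all(diff(correct_tail_tip(100, fr)) > 0))
  expect_true(all(correct_tail_tip(100, fr) >= 100))
  expect_error(correct_tail_tip(100, 1), "\\[0, 1\\)")
})

test_that("compute_kmf reproduces the worked example and its identities", {
  fit <- list(C0 = 100, k = 0.2)
  f <- tibble::tibble(fetus_id = "f1", fetal_weight = 1,
                      placental_weight = 0.1,
                      dpm_accumulated = 3160.603, sample_time_x = 5)
  res <- compute_kmf(f, fit)
  expect_equal(res$kmf_per_g_placenta, 100, tolerance = 1e-5)
  expect_equal(res$kmf_per_g_fetus, 10, tolerance = 1e-5)
  # clearance_total = kmf_per_g_placenta * W, exactly
  expect_identical(res$clearance_total,
                   res$kmf_per_g_placenta * f$placental_weight)

  # homogeneity: doubling Nx and W leaves Kmf/g unchanged, doubles total
  f2 <- dplyr::mutate(f, dpm_accumulated = 2 * dpm_accumulated,
                      placental_weight = 2 * placental_weight)
  res2 <- compute_kmf(f2, fit)
  expect_equal(res2$kmf_per_g_placenta, res$kmf_per_g_placenta)
  expect_equal(res2$clearance_total, 2 * res$clearance_total)

  # zero accumulation means zero clearance
  res0 <- compute_kmf(dplyr::mutate(f, dpm_accumulated = 0), fit)
  expect_equal(res0$kmf_per_g_placenta, 0)
  expect_equal(res0$clearance_total, 0)
})

test_that("per-fetus failures become error records, not aborts", {
  fit <- list(C0 = 100, k = 0.2)
  f <- tiny_fetuses()
  f$dpm_accumulated[1] <- NA
  f$placental_weight[2] <- 0
  res <- compute_kmf(f, fit)
  expect_equal(nrow(res), 2)
  expect_false(any(res$qc_pass))
  expect_match(res$error[1], "missing dpm")
  expect_match(res$error[2], "non-positive weight")
})

test_that("the zero-noise generate -> fit -> compute chain returns true Kmf", {
  true_kmf <- 37.5
  s <- generate_plasma_curve(200, 0.1, times = seq(0.5, 5, 0.5), noise_cv = 0)
  fit <- fit_disappearance(s)
  f <- tiny_fetuses()
  f$dpm_accumulated <- generate_accumulation(
    true_kmf, f$placental_weight, 200, 0.1, f$sample_time_x, noise_cv = 0)
  res <- compute_kmf(f, fit)
  expect_equal(res$kmf_per_g_placenta, rep(true_kmf, 2), tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in tabular form", {
  s <- generate_plasma_curve(50, 0.1, times = 1:6, noise_cv = 0)
  fit <- fit_disappearance(s)
  td <- tidy(fit)
  expect_equal(td$term, c("C0", "k", "plateau"))
  gl <- glance(fit)
  expect_true(gl$qc_pass)
  expect_equal(gl$n_samples, 6)
})
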