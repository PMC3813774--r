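test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(seed = 43)
  expect_false(identical(generate_cohort(cfg2)$fetuses$fetal_weight,
                         a$fetuses$fetal_weight))
})

test_that("zero variance collapses every pup onto its cell mean", {
  cfg <- cohort_config(calibration = zero_sd_calibration(), seed = 7)
  ch <- generate_cohort(cfg)
  p0w <- dplyr::filter(ch$fetuses, genotype == "P0", treatment == "water")
  expect_true(nrow(p0w) > 0)
  expect_true(all(p0w$fetal_weight == 0.94))
  expect_true(all(p0w$placental_weight == 0.065))
  wtsc <- dplyr::filter(ch$fetuses, genotype == "WT", treatment == "SC")
  expect_true(all(wtsc$fetal_weight == 1.25))
})

test_that("cell means and the two-level variance match the calibration at large n", {
  # ~1e5 pups: 12500 water litters of ~8 pups
  cfg <- cohort_config(n_litters = c(water = 12500, SC = 1), seed = 11)
  ch <- generate_cohort(cfg)
  p0w <- dplyr::filter(ch$fetuses, genotype == "P0", treatment == "water")
  n <- nrow(p0w)
  expect_gt(n, 10000)

  # analytic SE of the grand pup mean under the two-level model
  sigma <- 0.1334
  f <- cfg$variance_split
  n_lit <- dplyr::n_distinct(p0w$litter_id)
  se <- sqrt(sigma^2 * f / n_lit + sigma^2 * (1 - f) / n)
  expect_lt(abs(mean(p0w$fetal_weight) - 0.94), 3 * se)

  # marginal variance = between-litter + within-litter components
  expect_lt(abs(stats::var(p0w$fetal_weight) - sigma^2) / sigma^2, 0.05)
})

test_that("observed wild-type fraction lies within binomial 99% bounds", {
  cfg <- cohort_config(n_litters = c(water = 1500, SC = 1), seed = 3)
  ch <- generate_cohort(cfg)
  n <- nrow(ch$fetuses)
  expect_gt(n, 10000)
  phat <- mean(ch$fetuses$genotype == "WT")
  half <- qnorm(0.995) * sqrt(0.52 * 0.48 / n)
  expect_lt(abs(phat - 0.52), half)
})

test_that("per-arm litter counts are honoured and weights stay positive", {
  cfg <- cohort_config(n_litters = c(water = 5, SC = 9), seed = 2)
  ch <- generate_cohort(cfg)
  counts <- table(ch$litters$treatment)
  expect_equal(unname(counts[["water"]]), 5)
  expect_equal(unname(counts[["SC"]]), 9)
  expect_true(all(ch$litters$litter_size >= 1))
  expect_true(all(ch$fetuses$fetal_weight > 0))
  expect_true(all(ch$fetuses$placental_weight > 0))
})

test_that("plasma curve generator reproduces the closed form when noiseless", {
  s <- generate_plasma_curve(100, 0, times = c(0, 1, 7), noise_cv = 0)
  expect_equal(s$concentration, c(100, 100, 100))
  s2 <- generate_plasma_curve(100, 0.2, times = 5, noise_cv = 0)
  expect_equal(s2$concentration, 100 * exp(-1), tolerance = 1e-12)
})

test_that("log-linear regression recovers the decay rate from noisy samples", {
  k_true <- 0.2
  s <- generate_plasma_curve(100, k_true, times = seq(0.1, 5, length.out = 50),
                             noise_cv = 0.05, seed = 9)
  fit <- lm(log(concentration) ~ time, data = s)
  k_hat <- -unname(coef(fit)[2])
  expect_lt(abs(k_hat - k_true) / k_true, 0.10)
})

test_that("negative concentration draws are clamped with a warning", {
  expect_warning(
    s <- generate_plasma_curve(1, 0.1, times = 1:50, noise_cv = 3, seed = 4),
    "clamped")
  expect_true(all(s$concentration >= 0))
})

test_that("tracer accumulation inverts the clearance relation", {
  expect_equal(generate_accumulation(0, 0.1, 100, 0.2, 5), 0)
  nx <- generate_accumulation(100, 0.1, C0 = 100, k = 0.2, x = 5)
  oracle <- 100 * 0.1 * integrate(function(t) 100 * exp(-0.2 * t), 0, 5)$value
  expect_equal(nx, oracle, tolerance = 1e-10)
  expect_equal(nx, 3160.6, tolerance = 1e-4)
  expect_error(generate_accumulation(100, 0.1, 100, 0.2, x = 0), "> 0")
})

test_that("velocity trace hits generator inputs and the analytic cycle mean", {
  flat <- generate_velocity_trace(50, 50, heart_rate = 2, duration = 3)
  expect_true(all(flat$velocity == 50))

  tr <- generate_velocity_trace(80, 15, heart_rate = 2, duration = 3)
  expect_equal(max(tr$velocity), 80, tolerance = 1e-3)
  expect_equal(min(tr$velocity), 15, tolerance = 1e-12)
  ag <- aggregate_trace(tr)
  pi_analytic <- (80 - 15) / analytic_cycle_mean(80, 15)
  expect_equal(ag$pi, pi_analytic, tolerance = 0.01)

  expect_error(generate_velocity_trace(80, 15, heart_rate = 0.5, duration = 3),
               "3 cardiac cycles")
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(wt_fraction = 0), "wt_fraction")
  expect_error(cohort_config(n_litters = c(water = 0, SC = 5)), "n_litters")
  expect_error(cohort_config(tail_tip_fraction = 0.3), "0.2")
  expect_error(cohort_config(seed = NULL), "seed")
  cal <- default_calibration()
  cal$fetal_weight[1] <- -1
  expect_error(cohort_config(calibration = cal), "> 0")
})
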