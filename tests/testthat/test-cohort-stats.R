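test_that("litter summaries collapse pups to litter-genotype means", {
  fet <- tibble::tibble(
    fetus_id = c("a", "b", "c"),
    litter_id = c("L1", "L1", "L2"),
    treatment = "water",
    genotype = c("WT", "WT", "P0"),
    fetal_weight = c(1.0, 1.2, 0.9))
  ls <- litter_summaries(fet, "fetal_weight")
  expect_equal(ls$value[ls$litter_id == "L1"], 1.1)
  # a single-pup litter summarises to that pup
  expect_equal(ls$value[ls$litter_id == "L2"], 0.9)
  expect_error(litter_summaries(fet, "nope"), "not found")
})

test_that("cell means of litter summaries recover the generator calibration", {
  cfg <- cohort_config(n_litters = c(water = 60, SC = 60), seed = 17)
  ch <- generate_cohort(cfg)
  ls <- litter_summaries(ch$fetuses, "fetal_weight")
  cells <- ls |>
    dplyr::group_by(genotype, treatment) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  cal <- default_calibration()
  joined <- dplyr::left_join(cells, cal, by = c("genotype", "treatment"))
  expect_true(all(abs(joined$m - joined$fetal_weight) < 0.05))
})

test_that("degenerate summaries give p = 1 and seeds are mandatory", {
  s <- null_summaries(8)
  s$value <- 1
  res <- permutation_test(s, "treatment", n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1)
  expect_error(permutation_test(s, "treatment", n_perm = 99), "seed")
})

test_that("permutation p-values respect the add-one floor and reproducibility", {
  s <- null_summaries(12, seed = 2)
  a <- permutation_test(s, "treatment", n_perm = 199, seed = 7)
  b <- permutation_test(s, "treatment", n_perm = 199, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 200)
  expect_lte(a$p_value, 1)
})

test_that("a large injected treatment effect is detected almost surely", {
  hits <- vapply(1:60, function(i) {
    s <- null_summaries(16, seed = 5000 + i)
    # inject a 5-between-litter-SD shift into the SC litters
    s$value[s$treatment == "SC"] <- s$value[s$treatment == "SC"] + 5
    permutation_test(s, "treatment", n_perm = 999, seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(hits < 0.01), 0.95)
})

test_that("genotype permutation operates within litters", {
  # two litters, each with both genotypes; within-litter swap keeps litter
  # composition, so the statistic distribution is the paired-swap one
  s <- tibble::tibble(
    litter_id = rep(c("L1", "L2"), each = 2),
    treatment = "water",
    genotype = rep(c("WT", "P0"), 2),
    n_pups = 4L,
    value = c(1.2, 0.9, 1.25, 0.95))
  res <- permutation_test(s, "genotype", n_perm = 999, seed = 3)
  expect_equal(res$statistic, mean(c(1.2, 1.25)) - mean(c(0.9, 0.95)))
  # 4 equally likely swap patterns, all |T*| <= |T| with equality in 2
  expect_gt(res$p_value, 0.25)
})

test_that("step-down Sidak matches hand computation and its bounds", {
  expect_equal(sequential_sidak(0.2), 0.2)
  expect_equal(sequential_sidak(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(sequential_sidak(c(1, 1, 1)), c(1, 1, 1))
  # order-restoring, monotone, bounded by raw below and 1 above
  p <- withr::with_seed(9, runif(20))
  adj <- sequential_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in rank
  expect_error(sequential_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fetal:placental ratios are computed per pup and per cell", {
  fet <- tiny_fetuses()
  fet$fetal_weight <- c(1.0, 0.9)
  fet$placental_weight <- c(0.1, 0.06)
  fp <- fetal_placental_ratio(fet)
  expect_equal(fp$per_pup$fp_ratio, c(10, 15))
  # invariant to a common unit change
  fet_mg <- dplyr::mutate(fet, fetal_weight = fetal_weight * 1000,
                          placental_weight = placental_weight * 1000)
  expect_equal(fetal_placental_ratio(fet_mg)$per_pup$fp_ratio, c(10, 15))
  # zero placental weight becomes an error record
  fet$placental_weight[2] <- 0
  fp2 <- fetal_placental_ratio(fet)
  expect_true(is.na(fp2$per_pup$fp_ratio[2]))
  expect_match(fp2$per_pup$error[2], "placental")
})

test_that("P0 cells have higher F:P ratio than WT on the default calibration", {
  ch <- generate_cohort(cohort_config(seed = 23))
  pc <- fetal_placental_ratio(ch$fetuses)$per_cell
  wt <- pc$mean_ratio[pc$genotype == "WT" & pc$treatment == "water"]
  p0 <- pc$mean_ratio[pc$genotype == "P0" & pc$treatment == "water"]
  expect_gt(p0, wt)
})

test_that("Welch t test matches the brute-force formula", {
  idA <- c(1, 2, 3); idB <- c(1, 2, 3)
  expect_equal(two_sample_t(idA, idB)$t, 0)
  same <- two_sample_t(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  a <- c(2.1, 3.4, 2.8, 3.0); b <- c(4.2, 3.9, 5.1, 4.4, 4.8)
  res <- two_sample_t(a, b)
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  t_manual <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df_manual <- (sa + sb)^2 /
    (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, df_manual, tolerance = 1e-10)
  expect_equal(res$p_value, p_manual, tolerance = 1e-10)
})

test_that("compare_groups produces a coherent comparison table", {
  ch <- generate_cohort(cohort_config(seed = 29))
  cmp <- compare_groups(ch$fetuses, "fetal_weight", n_perm = 499, seed = 13)
  expect_s3_class(cmp, "group_comparison")
  expect_equal(nrow(cmp$cells), 4)
  expect_true(all(cmp$cells$sem > 0))
  expect_true(all(cmp$effects$p_value >= 0 & cmp$effects$p_value <= 1,
                  na.rm = TRUE))
  # adjusted never below raw
  expect_true(all(cmp$contrasts$p_adj >= cmp$contrasts$p_raw))
  # the calibrated genotype effect is overwhelming
  expect_lt(cmp$effects$p_value[cmp$effects$effect == "genotype"], 0.01)
  # broom-style accessors
  expect_equal(nrow(tidy(cmp)), 4)
  expect_true("p_genotype" %in% names(glance(cmp)))
})

test_that("litter permutation agrees with a mixed-model benchmark on sign", {
  # independent route: lme4 fit on the same cohort should agree that the
  # genotype effect is strong and the treatment effect direction matches
  ch <- generate_cohort(cohort_config(seed = 31))
  cmp <- compare_groups(ch$fetuses, "fetal_weight", n_perm = 999, seed = 3)
  fit <- lme4::lmer(fetal_weight ~ genotype + treatment + (1 | litter_id),
                    data = ch$fetuses)
  beta <- lme4::fixef(fit)
  # WT > P0 in the model iff the permutation statistic says so
  perm_geno <- cmp$effects$p_value[cmp$effects$effect == "genotype"]
  expect_lt(perm_geno, 0.05)
  expect_gt(beta[["genotypeWT"]], 0)
})
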