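#' Generate a synthetic litter-structured cohort
#'
#' Draws litters and pups under the two-level (litter intercept + pup
#' deviation) model described in [cohort_config()]. Litter sizes are rounded
#' normal draws clamped to at least one pup; genotype is Bernoulli per pup
#' with the configured wild-type fraction; each endpoint gets a shared
#' standard-normal litter factor scaled by the cell SD, so the marginal SD of
#' every cell equals its calibrated value and a fraction `variance_split` of
#' that variance lies between litters. Negative endpoint draws are resampled
#' at the pup level.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A list with two tibbles:
#' \describe{
#'   \item{litters}{`litter_id`, `treatment` ("water"/"SC"), `litter_size`,
#'     `gestational_day` (fixed 18.5).}
#'   \item{fetuses}{`fetus_id`, `litter_id`, `treatment`, `genotype`
#'     ("WT"/"P0"), `fetal_weight` (g), `placental_weight` (g), `crown_rump`,
#'     `abdominal_circ`, `head_circ` (mm), `tail_tip_fraction`, and
#'     placeholder tracer columns `dpm_accumulated`, `sample_time_x`
#'     (filled by [generate_accumulation()] / [run_pipeline()]).}
#' }
#' Deterministic given `config$seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dplyr::count(cohort$fetuses, genotype, treatment)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  arms <- names(config$n_litters)
  litters <- purrr::map_dfr(arms, function(arm) {
    n <- config$n_litters[[arm]]
    size <- pmax(1L, as.integer(round(
      rnorm(n, config$litter_size_mean[[arm]], config$litter_size_sd)
    )))
    tibble::tibble(treatment = arm, litter_size = size)
  })
  litters <- litters |>
    dplyr::mutate(
      litter_id = sprintf("L%03d", dplyr::row_number()),
      gestational_day = 18.5
    ) |>
    dplyr::select("litter_id", "treatment", "litter_size", "gestational_day")

  endpoints <- cohort_endpoints()
  f <- config$variance_split
  rho <- config$fp_correlation

  # one shared standard-normal litter factor per endpoint per litter
  litter_factors <- matrix(rnorm(nrow(litters) * length(endpoints)),
                           nrow = nrow(litters),
                           dimnames = list(litters$litter_id, endpoints))

  fetuses <- litters |>
    dplyr::select("litter_id", "treatment", "litter_size") |>
    tidyr::uncount(.data$litter_size, .remove = TRUE) |>
    dplyr::group_by(.data$litter_id) |>
    dplyr::mutate(pup = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fetus_id = sprintf("%s-F%02d", .data$litter_id, .data$pup),
      genotype = ifelse(rbinom(dplyr::n(), 1L, config$wt_fraction) == 1L,
                        "WT", "P0")
    ) |>
    dplyr::left_join(config$calibration, by = c("genotype", "treatment"))

  n_pup <- nrow(fetuses)
  # pup-level deviations; fetal and placental weight deviations optionally
  # correlated, all others independent
  z <- matrix(rnorm(n_pup * length(endpoints)), nrow = n_pup,
              dimnames = list(NULL, endpoints))
  if (rho != 0) {
    z[, "placental_weight"] <- rho * z[, "fetal_weight"] +
      sqrt(1 - rho^2) * z[, "placental_weight"]
  }

  for (ep in endpoints) {
    mu <- fetuses[[ep]]
    sigma <- fetuses[[paste0(ep, "_sd")]]
    b <- unname(litter_factors[fetuses$litter_id, ep])
    val <- mu + sigma * (sqrt(f) * b + sqrt(1 - f) * z[, ep])
    # resample the pup deviation (litter effect kept) until positive
    bad <- which(val <= 0)
    guard <- 0L
    while (length(bad) > 0 && guard < 1000L) {
      val[bad] <- mu[bad] + sigma[bad] *
        (sqrt(f) * b[bad] + sqrt(1 - f) * rnorm(length(bad)))
      bad <- bad[val[bad] <= 0]
      guard <- guard + 1L
    }
    if (length(bad) > 0) {
      abort("could not draw positive endpoint values; check calibration SDs.")
    }
    fetuses[[ep]] <- val
  }

  fetuses <- fetuses |>
    dplyr::mutate(
      tail_tip_fraction = config$tail_tip_fraction,
      dpm_accumulated = NA_real_,
      sample_time_x = NA_real_
    ) |>
    dplyr::select("fetus_id", "litter_id", "treatment", "genotype",
                  dplyr::all_of(endpoints), "tail_tip_fraction",
                  "dpm_accumulated", "sample_time_x")

  list(litters = litters, fetuses = fetuses)
}

#' Generate a maternal plasma tracer disappearance curve
#'
#' Samples a mono-exponential plasma concentration time course
#' \eqn{C(t) = C_0 e^{-kt}} with multiplicative Gaussian noise
#' `(1 + noise_cv * z)`. Negative noisy concentrations are clamped to zero
#' with a warning.
#'
#' @param C0 Concentration at time zero (dpm/ul), > 0.
#' @param k Disappearance rate constant (per min), >= 0.
#' @param times Sampling times (min), >= 0.
#' @param noise_cv Multiplicative coefficient of variation (0 = noiseless).
#' @param dam_id Identifier recorded on each sample.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `dam_id`, `time`, `concentration`.
#' @export
#' @examples
#' generate_plasma_curve(100, 0.2, times = 0:5, noise_cv = 0)
generate_plasma_curve <- function(C0, k, times, noise_cv = 0,
                                  dam_id = "dam1", seed = NULL) {
  check_number(C0, "C0", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (length(times) == 0 || any(times < 0)) {
    abort("`times` must be non-negative sampling times (min).")
  }
  draw <- function() {
    conc <- C0 * exp(-k * times)
    if (noise_cv > 0) {
      conc <- conc * (1 + noise_cv * rnorm(length(times)))
    }
    if (any(conc < 0)) {
      warn(sprintf("clamped %d negative plasma concentration(s) to zero",
                   sum(conc < 0)))
      conc <- pmax(conc, 0)
    }
    tibble::tibble(dam_id = dam_id, time = as.numeric(times),
                   concentration = conc)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate fetal tracer accumulation from a ground-truth clearance
#'
#' Inverts the maternofetal clearance relation: the total radiolabel a fetus
#' accumulates by exsanguination time `x` is
#' \deqn{N_x = K_{mf} \cdot W \cdot \int_0^x C_0 e^{-kt}\,dt,}
#' with `W` the placental wet weight (g), perturbed by multiplicative noise.
#' At `noise_cv = 0` the downstream [compute_kmf()] chain recovers
#' `true_kmf` exactly.
#'
#' @param true_kmf Ground-truth clearance (ul/min/g placenta), >= 0.
#' @param placental_weight Placental wet weight(s) W (g), > 0.
#' @param C0,k Plasma curve parameters as in [generate_plasma_curve()].
#' @param x Time(s) from injection to exsanguination (min), in `[1, 5]` under
#'   the protocol this emulates; any positive value is accepted.
#' @param noise_cv Multiplicative CV of the counts.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of accumulated counts (dpm), non-negative.
#' @export
#' @examples
#' generate_accumulation(100, placental_weight = 0.1, C0 = 100, k = 0.2, x = 5)
generate_accumulation <- function(true_kmf, placental_weight, C0, k, x,
                                  noise_cv = 0, seed = NULL) {
  check_number(true_kmf, "true_kmf", lower = 0)
  check_number(C0, "C0", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (any(placental_weight <= 0)) abort("`placental_weight` must be > 0.")
  if (any(x <= 0)) abort("sample time `x` must be > 0 min.")
  n <- max(length(placental_weight), length(x))
  w <- rep_len(placental_weight, n)
  xx <- rep_len(x, n)
  draw <- function() {
    nx <- true_kmf * w * decay_integral(C0, k, xx)
    if (noise_cv > 0) nx <- nx * (1 + noise_cv * rnorm(n))
    pmax(nx, 0)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
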