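#' Per-litter, per-genotype endpoint summaries
#'
#' Litters, not pups, are the independent statistical unit in a multi-pup
#' species: pups of one dam share maternal environment and are correlated.
#' This collapses pup records to one mean per (litter, genotype) cell, the
#' unit on which all group inference in this package operates. Litters
#' missing a genotype simply contribute no row for it.
#'
#' @param fetuses Tibble of pup records with `litter_id`, `genotype`,
#'   `treatment` and the endpoint column.
#' @param endpoint Name of the endpoint column (string).
#'
#' @return Tibble with `litter_id`, `treatment`, `genotype`, `n_pups`,
#'   `value` (the litter-genotype mean of the endpoint).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 11))
#' litter_summaries(cohort$fetuses, "fetal_weight")
litter_summaries <- function(fetuses, endpoint) {
  if (!endpoint %in% names(fetuses)) {
    abort(sprintf("endpoint `%s` not found in `fetuses`.", endpoint))
  }
  fetuses |>
    dplyr::filter(!is.na(.data[[endpoint]])) |>
    dplyr::group_by(.data$litter_id, .data$treatment, .data$genotype) |>
    dplyr::summarise(n_pups = dplyr::n(),
                     value = mean(.data[[endpoint]]),
                     .groups = "drop")
}

#' Permutation test on litter summaries
#'
#' Two-sided permutation test of a group difference, respecting the litter
#' structure:
#' \describe{
#'   \item{`factor = "treatment"`}{treatment labels are permuted across whole
#'     litters (a litter never splits), the exchangeable unit under the null
#'     of no treatment effect;}
#'   \item{`factor = "genotype"`}{genotype labels are permuted within each
#'     litter (swapping the WT and P0 litter means at random), since
#'     genotypes are randomised within dams.}
#' }
#' The statistic is the difference of cell means of litter summaries and the
#' p-value uses the add-one rule
#' \eqn{p = (1 + \#\{|T^*| \ge |T|\}) / (1 + n_{perm})}, so degenerate
#' (all-equal) data give p = 1.
#'
#' @param summaries Output of [litter_summaries()] (columns `litter_id`,
#'   `treatment`, `genotype`, `value`).
#' @param factor `"treatment"` or `"genotype"`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed (mandatory; permutation inference must be
#'   reproducible).
#'
#' @return One-row tibble: `factor`, `statistic` (difference of cell means),
#'   `p_value`, `n_perm`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 5))
#' ls <- litter_summaries(cohort$fetuses, "fetal_weight")
#' permutation_test(ls, "genotype", n_perm = 999, seed = 1)
permutation_test <- function(summaries, factor = c("treatment", "genotype"),
                             n_perm = 9999, seed) {
  factor <- match.arg(factor)
  if (missing(seed)) abort("`seed` is mandatory for permutation inference.")
  need <- c("litter_id", "treatment", "genotype", "value")
  if (!all(need %in% names(summaries))) {
    abort("`summaries` must come from litter_summaries().")
  }
  lab <- summaries[[factor]]
  lev <- unique(lab)
  if (length(lev) != 2) {
    abort(sprintf("`%s` must have exactly 2 levels (got %d).",
                  factor, length(lev)))
  }
  # canonical orientation: statistic is WT - P0 / water - SC where applicable
  for (pref in list(c("WT", "P0"), c("water", "SC"))) {
    if (setequal(lev, pref)) lev <- pref
  }
  v <- summaries$value
  diff_means <- function(labels) {
    mean(v[labels == lev[1]]) - mean(v[labels == lev[2]])
  }
  t_obs <- diff_means(lab)

  if (factor == "treatment") {
    # permute treatment across litters; every row of a litter moves together
    litter_tab <- summaries |>
      dplyr::distinct(.data$litter_id, .data$treatment)
    if (min(table(litter_tab$treatment)) < 2) {
      abort("need >= 2 litters per treatment level.")
    }
    idx <- match(summaries$litter_id, litter_tab$litter_id)
    perm_stats <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      diff_means(sample(litter_tab$treatment)[idx])
    }, numeric(1)))
  } else {
    # permute genotype within litter: randomly swap the genotype labels of
    # each litter's rows
    split_idx <- split(seq_len(nrow(summaries)), summaries$litter_id)
    if (length(split_idx) < 2) abort("need >= 2 litters.")
    perm_stats <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      lab_p <- lab
      for (ii in split_idx) {
        if (length(ii) > 1 && runif(1) < 0.5) lab_p[ii] <- rev(lab_p[ii])
      }
      diff_means(lab_p)
    }, numeric(1)))
  }

  p <- (1 + sum(abs(perm_stats) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  tibble::tibble(factor = factor, statistic = t_obs,
                 p_value = min(p, 1), n_perm = n_perm)
}

#' Step-down Sidak multiple-comparison adjustment
#'
#' Orders the raw p-values ascending, applies
#' \eqn{\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}} (the Sidak exponent
#' shrinking as hypotheses are stepped through), enforces monotone
#' non-decrease along the ordered sequence, and returns the adjusted values
#' in the original order. Adjusted values never fall below the raw ones and
#' are capped at 1; a single p-value is returned unchanged.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' sequential_sidak(c(0.01, 0.04))  # 0.0199, 0.04
sequential_sidak <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Fetal:placental weight ratio per pup and per cell
#'
#' The F:P ratio, fetal weight divided by placental weight, is a crude index
#' of placental efficiency. Per-pup ratios are summarised per
#' (genotype, treatment) cell as the mean of pup ratios with the SEM taken
#' over litter means of the ratio — litters being the independent unit.
#' Pups with non-positive placental weight get an error record.
#'
#' @param fetuses Tibble with `litter_id`, `genotype`, `treatment`,
#'   `fetal_weight`, `placental_weight`.
#' @return List of two tibbles: `per_pup` (`fetus_id`, ..., `fp_ratio`,
#'   `error`) and `per_cell` (cell, `n_pups`, `n_litters`, `mean_ratio`,
#'   `sem_ratio`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 2))
#' fetal_placental_ratio(cohort$fetuses)$per_cell
fetal_placental_ratio <- function(fetuses) {
  need <- c("litter_id", "genotype", "treatment", "fetal_weight",
            "placental_weight")
  if (!all(need %in% names(fetuses))) {
    abort("`fetuses` must carry litter, group and both weight columns.")
  }
  per_pup <- fetuses |>
    dplyr::mutate(
      fp_ratio = dplyr::if_else(.data$placental_weight > 0,
                                .data$fetal_weight / .data$placental_weight,
                                NA_real_),
      error = dplyr::if_else(.data$placental_weight > 0, NA_character_,
                             "non-positive placental weight")
    )
  litter_means <- per_pup |>
    dplyr::filter(!is.na(.data$fp_ratio)) |>
    dplyr::group_by(.data$litter_id, .data$genotype, .data$treatment) |>
    dplyr::summarise(litter_ratio = mean(.data$fp_ratio), .groups = "drop")
  per_cell <- per_pup |>
    dplyr::filter(!is.na(.data$fp_ratio)) |>
    dplyr::group_by(.data$genotype, .data$treatment) |>
    dplyr::summarise(n_pups = dplyr::n(),
                     mean_ratio = mean(.data$fp_ratio), .groups = "drop") |>
    dplyr::left_join(
      litter_means |>
        dplyr::group_by(.data$genotype, .data$treatment) |>
        dplyr::summarise(n_litters = dplyr::n(),
                         sem_ratio = sem(.data$litter_ratio),
                         .groups = "drop"),
      by = c("genotype", "treatment"))
  list(per_pup = per_pup, per_cell = per_cell)
}

#' Welch two-sample t test
#'
#' Thin wrapper around [stats::t.test()] (Welch, two-sided) returning a tidy
#' one-row tibble; used for endpoints measured once per litter, e.g. litter
#' size between treatment arms.
#'
#' @param values_a,values_b Numeric samples, each of length >= 2.
#' @return Tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_sample_t(c(8, 7, 9, 8), c(9, 8, 10, 9))
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("both samples need n >= 2.")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(tibble::tibble(t = 0, df = NA_real_, p_value = 1,
                          mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Litter-aware group comparison of an endpoint
#'
#' Full comparison table for one endpoint over the genotype x treatment
#' design: cell means with SEM over litters, permutation p-values for the
#' genotype and treatment main effects (see [permutation_test()]), an
#' interaction p-value from permutation of residuals of the additive
#' litter-summary model (an approximation, documented as such), and the four
#' within-factor pairwise contrasts with raw and step-down-Sidak-adjusted
#' p-values.
#'
#' @inheritParams litter_summaries
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return List of class `group_comparison`: `endpoint`, `cells` (per-cell
#'   tibble), `effects` (main + interaction p-values), `contrasts` (pairwise
#'   with `p_adj`), `method = "litter_permutation"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 5))
#' cmp <- compare_groups(cohort$fetuses, "fetal_weight",
#'                       n_perm = 499, seed = 1)
#' cmp$cells
compare_groups <- function(fetuses, endpoint, n_perm = 9999, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  ls <- litter_summaries(fetuses, endpoint)

  cells <- ls |>
    dplyr::group_by(.data$genotype, .data$treatment) |>
    dplyr::summarise(n_litters = dplyr::n(), n_pups = sum(.data$n_pups),
                     mean = mean(.data$value), sem = sem(.data$value),
                     .groups = "drop")

  p_geno <- permutation_test(ls, "genotype", n_perm, seed)$p_value
  p_trt <- permutation_test(ls, "treatment", n_perm, seed + 1L)$p_value
  p_int <- interaction_permutation(ls, n_perm, seed + 2L)

  effects <- tibble::tibble(
    effect = c("genotype", "treatment", "interaction"),
    p_value = c(p_geno, p_trt, p_int))

  contrast_specs <- list(
    list(name = "WT water vs P0 water", fix = c(treatment = "water"),
         factor = "genotype"),
    list(name = "WT SC vs P0 SC", fix = c(treatment = "SC"),
         factor = "genotype"),
    list(name = "WT water vs WT SC", fix = c(genotype = "WT"),
         factor = "treatment"),
    list(name = "P0 water vs P0 SC", fix = c(genotype = "P0"),
         factor = "treatment"))
  contrasts <- purrr::imap_dfr(contrast_specs, function(spec, i) {
    sub <- ls[ls[[names(spec$fix)]] == spec$fix, , drop = FALSE]
    res <- permutation_test(sub, spec$factor, n_perm, seed + 2L + i)
    tibble::tibble(contrast = spec$name, statistic = res$statistic,
                   p_raw = res$p_value)
  })
  contrasts$p_adj <- sequential_sidak(contrasts$p_raw)

  structure(list(endpoint = endpoint, cells = cells, effects = effects,
                 contrasts = contrasts, n_perm = n_perm, seed = seed,
                 method = "litter_permutation"),
            class = "group_comparison")
}

# interaction via permutation of residuals from the additive model on
# litter summaries (approximate; exact interaction permutation does not
# exist for unbalanced two-factor designs)
interaction_permutation <- function(ls, n_perm, seed) {
  if (dplyr::n_distinct(ls$genotype) < 2 ||
      dplyr::n_distinct(ls$treatment) < 2) {
    return(NA_real_)
  }
  fit_add <- lm(value ~ genotype + treatment, data = ls)
  res <- resid(fit_add)
  fitted_add <- stats::fitted(fit_add)
  int_stat <- function(v, d) {
    cm <- tapply(v, list(d$genotype, d$treatment), mean)
    if (any(is.na(cm))) return(NA_real_)
    cm[1, 1] - cm[1, 2] - cm[2, 1] + cm[2, 2]
  }
  t_obs <- int_stat(ls$value, ls)
  if (is.na(t_obs)) return(NA_real_)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    int_stat(fitted_add + sample(res), ls)
  }, numeric(1)))
  (1 + sum(abs(perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> endpoint: %s (%s, %d permutations)\n",
              x$endpoint, x$method, x$n_perm))
  print(x$cells)
  cat("effects:\n"); print(x$effects)
  cat("pairwise contrasts (step-down Sidak adjusted):\n")
  print(x$contrasts)
  invisible(x)
}
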