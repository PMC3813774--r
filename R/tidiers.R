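#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-phase decay fit
#'
#' @param x A `decay_fit` from [fit_disappearance()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("C0", "k", "plateau"),
                 estimate = c(x$C0, x$k, x$plateau),
                 unit = c("dpm/ul", "1/min", "dpm/ul"))
}

#' One-row summary of a decay fit
#'
#' @inheritParams tidy.decay_fit
#' @return Tibble: `r2`, `n_samples`, `pooled`, `qc_pass`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n_samples = x$n_samples, pooled = x$pooled,
                 qc_pass = x$qc_pass)
}

#' Tidy a Gaussian weight-distribution fit
#'
#' @param x A `gaussian_fit` from [fit_weight_distribution()].
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("mean", "sd", "amplitude"),
                 estimate = c(x$mean, x$sd, x$amplitude),
                 unit = c("g", "g", "count"))
}

#' One-row summary of a Gaussian weight-distribution fit
#'
#' @inheritParams tidy.gaussian_fit
#' @return Tibble: `mean`, `sd`, `r2`, `n`, `method`.
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, r2 = x$r2, n = x$n,
                 method = x$method)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return The pairwise contrast tibble with raw and adjusted p-values,
#'   prefixed by the endpoint name.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$contrasts, endpoint = x$endpoint, .before = 1)
}

#' One-row summary of a group comparison
#'
#' @inheritParams tidy.group_comparison
#' @return Tibble with the endpoint, main-effect and interaction p-values.
#' @export
glance.group_comparison <- function(x, ...) {
  p <- setNames(x$effects$p_value, paste0("p_", x$effects$effect))
  tibble::tibble(endpoint = x$endpoint, !!!p, n_perm = x$n_perm,
                 method = x$method)
}
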