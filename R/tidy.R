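#' Tidy a divergence-time estimate
#'
#' One row with the point time and the three nested confidence intervals
#' (rate-propagated, site-bootstrap, multiplicatively combined), all in
#' years; missing intervals (bootstrap not run) are NA.
#'
#' @param x a `time_estimate` from [divergence_time()].
#' @param ... unused.
#' @return a one-row tibble.
#' @importFrom generics tidy
#' @method tidy time_estimate
#' @export
tidy.time_estimate <- function(x, ...) {
  tibble::tibble(
    T_years = x$T_years,
    ci_rate_lo = x$ci_rate[1], ci_rate_hi = x$ci_rate[2],
    ci_boot_lo = if (is.null(x$ci_boot)) NA_real_ else x$ci_boot[1],
    ci_boot_hi = if (is.null(x$ci_boot)) NA_real_ else x$ci_boot[2],
    ci_combined_lo = if (is.null(x$ci_combined)) NA_real_ else x$ci_combined[1],
    ci_combined_hi = if (is.null(x$ci_combined)) NA_real_ else x$ci_combined[2],
    n_boot = if (is.null(x$replicates)) 0L else length(x$replicates))
}

#' One-line summary of a divergence-time estimate
#'
#' @param x a `time_estimate` from [divergence_time()].
#' @param ... unused.
#' @return a one-row tibble with pooled mutation counts, callable totals and
#'   the per-site rho of both clades.
#' @importFrom generics glance
#' @method glance time_estimate
#' @export
glance.time_estimate <- function(x, ...) {
  tibble::tibble(
    rho_a = x$rho_a$rho_per_site, rho_b = x$rho_b$rho_per_site,
    count_a = x$rho_a$count, count_b = x$rho_b$count,
    callable_a = x$rho_a$total, callable_b = x$rho_b$total,
    rate = x$rate$point, T_years = x$T_years)
}

#' Plot a bootstrapped divergence-time estimate
#'
#' Histogram of the site-bootstrap replicate times with the point estimate
#' and the three confidence intervals.
#'
#' @param object a `time_estimate` with bootstrap replicates.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot time_estimate
#' @export
autoplot.time_estimate <- function(object, ...) {
  if (is.null(object$replicates)) {
    stop("no bootstrap replicates; rerun divergence_time() with n_boot >= 2")
  }
  df <- data.frame(T_ky = object$replicates / 1000)
  ci <- data.frame(
    ci = factor(c("rate", "bootstrap", "combined"),
                levels = c("rate", "bootstrap", "combined")),
    lo = c(object$ci_rate[1], object$ci_boot[1], object$ci_combined[1]) / 1000,
    hi = c(object$ci_rate[2], object$ci_boot[2], object$ci_combined[2]) / 1000,
    y = -c(1, 2, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = T_ky)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$T_years / 1000,
                        colour = "firebrick") +
    ggplot2::geom_segment(data = ci,
                          ggplot2::aes(x = lo, xend = hi, y = y, yend = y,
                                       colour = ci),
                          inherit.aes = FALSE, linewidth = 1.2) +
    ggplot2::labs(x = "divergence time (ky)", y = "bootstrap replicates",
                  colour = "95% CI") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("true_T", "estimator", "se", "T_ky", "lo", "hi", "y"))
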