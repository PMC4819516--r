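#' Average squared distance (ASD) between two groups' STR profiles
#'
#' Mean over loci and over cross-group sample pairs of the squared repeat-
#' length difference. A locus missing (NA) in any involved sample is skipped
#' with a warning; if every locus is skipped that is an error.
#'
#' @param panel an [simulate_str_panel()] result, or a samples x loci
#'   integer matrix with sample rownames.
#' @param group_a,group_b disjoint, non-empty vectors of sample ids.
#' @return mean squared difference (scalar).
#' @export
asd <- function(panel, group_a, group_b) {
  x <- if (inherits(panel, "str_panel")) panel$lengths else as.matrix(panel)
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  missing_s <- setdiff(c(group_a, group_b), rownames(x))
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
  a <- x[group_a, , drop = FALSE]
  b <- x[group_b, , drop = FALSE]
  usable <- !colSums(is.na(a)) & !colSums(is.na(b))
  if (any(!usable)) {
    warning("skipping ", sum(!usable), " locus/loci with missing lengths: ",
            paste(colnames(x)[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no usable loci: all have missing lengths")
  sq <- 0
  for (l in which(usable)) sq <- sq + mean(outer(a[, l], b[, l], `-`)^2)
  sq / sum(usable)
}

#' TMRCA from an ASD value under the single-step mutation-drift expectation
#'
#' Under the unbounded stepwise mutation model the expected ASD between two
#' lineages separated for `t` generations (each) is `2 * rate * t`, so
#' `T = asd / (2 * rate)` generations, converted to years.
#'
#' @param asd_value an [asd()] value (>= 0).
#' @param rate_per_gen per-locus per-generation mutation rate (> 0).
#' @param generation_years years per generation.
#' @return estimated TMRCA in years.
#' @export
str_tmrca <- function(asd_value, rate_per_gen = 2.08e-3,
                      generation_years = 25) {
  if (rate_per_gen <= 0) stop("rate must be > 0")
  if (asd_value < 0) stop("ASD cannot be negative")
  asd_value / (2 * rate_per_gen) * generation_years
}

#' STR saturation experiment: ASD/TMRCA bias against sequence-based truth
#'
#' For each true split time, simulates matched datasets on the same
#' two-clade genealogy — a bounded-allele stepwise-mutation STR panel and an
#' infinite-sites SNV dataset — and estimates the divergence time both ways:
#' [str_tmrca()] from the cross-clade [asd()], and the sequence route
#' (parsimony mapping on the true topology, pooled rho, [divergence_time()]).
#' Bounded allele ranges make STR distances plateau, so the STR estimator's
#' bias ratio falls below 1 as the true time grows, while the sequence
#' estimator stays unbiased.
#'
#' @param true_T_grid true split times in years.
#' @param n_reps simulation replicates per grid point.
#' @param n_per_clade tips per clade.
#' @param mu,L sequence mutation rate and callable site count.
#' @param str_loci,str_rate,generation_years,str_bound STR panel settings
#'   (see [sim_config()]).
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @return a tibble of class `saturation_bias`: `true_T`, means, standard
#'   errors and bias ratios of both estimators.
#' @export
saturation_experiment <- function(true_T_grid = c(1000, 10000, 50000),
                                  n_reps = 30L, n_per_clade = 3L,
                                  mu = 0.76e-9, L = 1e7,
                                  str_loci = 10L, str_rate = 2.08e-3,
                                  generation_years = 25, str_bound = 10,
                                  seed = 1L) {
  rows <- lapply(seq_along(true_T_grid), function(gi) {
    T0 <- true_T_grid[gi]
    t_str <- t_seq <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- (seed + 7919L * gi + 104729L * r) %% .Machine$integer.max
      tree <- two_clade_tree(n_a = n_per_clade, n_b = n_per_clade,
                             t_split = T0, t_within = T0 / 2,
                             t_outgroup = NULL)
      cfg <- sim_config(tree, mu = mu, L = L, coverage = 1.0,
                        str_loci = str_loci, str_rate = str_rate,
                        generation_years = generation_years,
                        str_bound = str_bound, seed = rep_seed)
      clade_a <- grep("^AUS", tree$tip.label, value = TRUE)
      clade_b <- grep("^ASN", tree$tip.label, value = TRUE)
      sp <- simulate_str_panel(cfg)
      t_str[r] <- str_tmrca(asd(sp, clade_a, clade_b),
                            rate_per_gen = str_rate,
                            generation_years = generation_years)
      sim <- simulate_snv_dataset(cfg)
      ht <- map_mutations_parsimony(tree, sim$matrix)
      t_seq[r] <- divergence_time(ht, sim$matrix, clade_a, clade_b,
                                  rate = mutation_rate(mu, mu, mu))$T_years
    }
    tibble::tibble(
      true_T = T0,
      t_str_mean = mean(t_str), t_str_se = stats::sd(t_str) / sqrt(n_reps),
      t_seq_mean = mean(t_seq), t_seq_se = stats::sd(t_seq) / sqrt(n_reps),
      bias_str = mean(t_str) / T0, bias_seq = mean(t_seq) / T0,
      n_reps = as.integer(n_reps))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_bias", class(out))
  out
}

#' Plot an STR saturation-bias table
#'
#' Both estimators against the truth on log-log axes; the dashed line is
#' unbiasedness.
#' @param object a [saturation_experiment()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot saturation_bias
#' @export
autoplot.saturation_bias <- function(object, ...) {
  df <- rbind(
    data.frame(true_T = object$true_T, estimator = "STR (ASD)",
               mean = object$t_str_mean, se = object$t_str_se),
    data.frame(true_T = object$true_T, estimator = "sequence (rho)",
               mean = object$t_seq_mean, se = object$t_seq_se))
  ggplot2::ggplot(df, ggplot2::aes(x = true_T, y = mean,
                                   colour = estimator)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - 2 * se,
                                          ymax = mean + 2 * se)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true split time (years)",
                  y = "estimated TMRCA (years)", colour = NULL) +
    ggplot2::theme_minimal()
}
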