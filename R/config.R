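#' Simulation configuration
#'
#' Parameters of the synthetic causal-trait generator: a random acyclic
#' causal graph over continuous traits, binary instrumental variables (IVs)
#' assigned to each trait, and horizontal pleiotropy in which an instrument
#' gains a direct effect on a trait other than its primary one.
#'
#' Defaults reproduce the benchmark's study conditions: 15 traits, each with
#' 10--20 binary IVs (about 225 in total), causal links to around 1--2 other
#' traits, and a pleiotropy probability `p_pleio` on the grid 0, 0.1, ...,
#' 0.4.
#'
#' @param n_traits Number of continuous traits (>= 2).
#' @param iv_per_trait_min,iv_per_trait_max Range of the per-trait instrument
#'   count; the count is drawn uniformly on this integer range.
#' @param p_pleio Probability that an instrument is horizontally
#'   pleiotropic, i.e. gains a direct effect on one uniformly chosen
#'   non-primary trait; each instrument is an independent draw.
#' @param n_samples Number of individuals per simulated replicate.
#' @param n_replicates Number of simulation replicates per setting.
#' @param mean_children Mean of the (truncated) Poisson number of direct
#'   causal children per trait, taken over traits later in a random ordering.
#' @param effect_range Length-2 positive range; trait-to-trait and IV-to-trait
#'   effect magnitudes are drawn uniformly here, with random sign.
#' @param maf_range Length-2 range in (0, 0.5] for instrument allele
#'   frequencies.
#' @param noise_sd Standard deviation of each trait's independent Gaussian
#'   noise term.
#' @param seed Integer seed for the experiment; replicate-level child seeds
#'   are derived deterministically from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_traits = 4, n_samples = 500)
#' cfg$n_traits
#' @export
sim_config <- function(n_traits = 15,
                       iv_per_trait_min = 10,
                       iv_per_trait_max = 20,
                       p_pleio = 0,
                       n_samples = 2000,
                       n_replicates = 100,
                       mean_children = 1.5,
                       effect_range = c(0.1, 0.4),
                       maf_range = c(0.1, 0.5),
                       noise_sd = 1,
                       seed = 1L) {
  stopifnot(
    is.numeric(n_traits), length(n_traits) == 1, n_traits >= 2,
    iv_per_trait_min >= 1, iv_per_trait_min <= iv_per_trait_max,
    is.numeric(p_pleio), p_pleio >= 0, p_pleio <= 1,
    n_samples >= 10, n_replicates >= 1,
    mean_children >= 0,
    length(effect_range) == 2, all(effect_range > 0),
    effect_range[1] <= effect_range[2],
    length(maf_range) == 2, all(maf_range > 0), all(maf_range <= 0.5),
    maf_range[1] <= maf_range[2],
    noise_sd > 0
  )
  if (mean_children > n_traits - 1) {
    warning("mean_children exceeds the number of available downstream ",
            "traits; child counts will be heavily truncated")
  }
  structure(
    list(
      n_traits = as.integer(n_traits),
      iv_per_trait_min = as.integer(iv_per_trait_min),
      iv_per_trait_max = as.integer(iv_per_trait_max),
      p_pleio = p_pleio,
      n_samples = as.integer(n_samples),
      n_replicates = as.integer(n_replicates),
      mean_children = mean_children,
      effect_range = effect_range,
      maf_range = maf_range,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Evaluation configuration
#'
#' Settings for the benchmark loop: which methods and instrument-filter
#' variants to run, the discovery thresholds, the pleiotropy grid and the
#' sizes of the resampling schemes.
#'
#' Discovery thresholds follow the benchmark design: Benjamini--Yekutieli
#' adjusted p-value thresholds 0.1, 0.05, 0.01 for the MR methods, and
#' directed-edge probability thresholds 0.7, 0.8, 0.9 for the Bayesian
#' network.
#'
#' @param mr_thresholds Thresholds applied to (BY-adjusted) MR p-values.
#' @param bn_thresholds Thresholds applied to BN directed-edge probabilities.
#' @param p_pleio_grid Pleiotropy levels to simulate.
#' @param methods Subset of `"IVW"`, `"Egger"`, `"PRESSO"`, `"BN"`.
#' @param filters Instrument-set variants: `"none"` (all Bonferroni-selected
#'   instruments) and/or `"uniqueiv"` (conditional-independence filtered).
#' @param n_boot Bootstrap resamples per BN pair analysis.
#' @param presso_nsim Simulated datasets for the MR-PRESSO reference
#'   distribution.
#' @param alpha_select Family-wise level for Bonferroni instrument selection.
#' @param ci_alpha Significance level of the conditional-association test in
#'   the UniqueIV filter.
#' @param presso_outlier_alpha Level for MR-PRESSO's Bonferroni-adjusted
#'   per-instrument outlier test.
#' @param adjust_mr Apply BY adjustment to MR p-values before thresholding
#'   and ROC construction (`TRUE`, the default) or use raw p-values.
#' @param roc_points Number of evenly spaced thresholds on \[0, 1\] for ROC
#'   curves.
#'
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(mr_thresholds = c(0.1, 0.05, 0.01),
                        bn_thresholds = c(0.7, 0.8, 0.9),
                        p_pleio_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                        methods = c("IVW", "Egger", "PRESSO", "BN"),
                        filters = c("none", "uniqueiv"),
                        n_boot = 1000,
                        presso_nsim = 1000,
                        alpha_select = 0.05,
                        ci_alpha = 0.01,
                        presso_outlier_alpha = 0.05,
                        adjust_mr = TRUE,
                        roc_points = 201) {
  methods <- match.arg(methods, c("IVW", "Egger", "PRESSO", "BN"),
                       several.ok = TRUE)
  filters <- match.arg(filters, c("none", "uniqueiv"), several.ok = TRUE)
  stopifnot(
    length(mr_thresholds) >= 1, all(mr_thresholds > 0), all(mr_thresholds < 1),
    length(bn_thresholds) >= 1, all(bn_thresholds > 0), all(bn_thresholds < 1),
    length(p_pleio_grid) >= 1, all(p_pleio_grid >= 0), all(p_pleio_grid <= 1),
    n_boot >= 1, presso_nsim >= 100,
    alpha_select > 0, alpha_select < 1,
    ci_alpha > 0, ci_alpha < 1,
    presso_outlier_alpha > 0, presso_outlier_alpha < 1,
    is.logical(adjust_mr), roc_points >= 2
  )
  structure(
    list(
      mr_thresholds = mr_thresholds,
      bn_thresholds = bn_thresholds,
      p_pleio_grid = p_pleio_grid,
      methods = methods,
      filters = filters,
      n_boot = as.integer(n_boot),
      presso_nsim = as.integer(presso_nsim),
      alpha_select = alpha_select,
      ci_alpha = ci_alpha,
      presso_outlier_alpha = presso_outlier_alpha,
      adjust_mr = isTRUE(adjust_mr),
      roc_points = as.integer(roc_points)
    ),
    class = "eval_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  traits: %d, IVs per trait: %d-%d (expected total %.0f)\n",
              x$n_traits, x$iv_per_trait_min, x$iv_per_trait_max,
              x$n_traits * (x$iv_per_trait_min + x$iv_per_trait_max) / 2))
  cat(sprintf("  p_pleio: %.2f, samples: %d, replicates: %d, seed: %d\n",
              x$p_pleio, x$n_samples, x$n_replicates, x$seed))
  cat(sprintf("  mean children: %.2f, effects: [%.2f, %.2f], MAF: [%.2f, %.2f], noise sd: %.2f\n",
              x$mean_children, x$effect_range[1], x$effect_range[2],
              x$maf_range[1], x$maf_range[2], x$noise_sd))
  invisible(x)
}

#' @export
print.eval_config <- function(x, ...) {
  cat("Evaluation configuration\n")
  cat("  methods:", paste(x$methods, collapse = ", "),
      "| filters:", paste(x$filters, collapse = ", "), "\n")
  cat("  MR thresholds:", paste(x$mr_thresholds, collapse = ", "),
      "| BN thresholds:", paste(x$bn_thresholds, collapse = ", "), "\n")
  cat("  p_pleio grid:", paste(x$p_pleio_grid, collapse = ", "), "\n")
  cat(sprintf("  n_boot: %d, presso_nsim: %d, adjust_mr: %s\n",
              x$n_boot, x$presso_nsim, x$adjust_mr))
  invisible(x)
}
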