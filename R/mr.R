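#' Per-instrument summary statistics for one exposure-outcome pair
#'
#' @param beta_x,se_x Exposure association slopes and standard errors.
#' @param beta_y,se_y Outcome association slopes and standard errors.
#' @param instruments Optional instrument ids (default `iv_1`, ...).
#' @return An object of class `mr_input`.
#' @export
mr_input <- function(beta_x, se_x, beta_y, se_y, instruments = NULL) {
  J <- length(beta_x)
  stopifnot(J >= 1,
            length(se_x) == J, length(beta_y) == J, length(se_y) == J,
            all(is.finite(beta_x)), all(is.finite(beta_y)),
            all(se_x > 0), all(se_y > 0))
  if (is.null(instruments)) instruments <- paste0("iv_", seq_len(J))
  structure(
    list(beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
         beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
         instruments = as.character(instruments)),
    class = "mr_input"
  )
}

mr_result <- function(method, estimate = NA_real_, se = NA_real_,
                      pval = NA_real_, n_instruments_used = 0L,
                      outliers_removed = character(0), intercept = NA_real_,
                      intercept_pval = NA_real_, global_pval = NA_real_,
                      tested = TRUE) {
  structure(
    list(method = method, estimate = estimate, se = se, pval = pval,
         n_instruments_used = as.integer(n_instruments_used),
         outliers_removed = outliers_removed, intercept = intercept,
         intercept_pval = intercept_pval, global_pval = global_pval,
         tested = tested),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  if (!x$tested) {
    cat(sprintf("%s: not tested (insufficient instruments)\n", x$method))
    return(invisible(x))
  }
  cat(sprintf("%s: estimate %.4f (se %.4f), p = %.3g, %d instruments",
              x$method, x$estimate, x$se, x$pval, x$n_instruments_used))
  if (length(x$outliers_removed) > 0) {
    cat(sprintf(", outliers removed: %s",
                paste(x$outliers_removed, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect weighted regression through the origin of the outcome
#' associations on the exposure associations, with weights `1/se_y^2`:
#' estimate `sum(w bx by) / sum(w bx^2)`, standard error
#' `1 / sqrt(sum(w bx^2))`, two-sided normal test.
#'
#' @param input An `mr_input` with at least one instrument.
#' @return An `mr_result` with `method = "IVW"`.
#' @export
mr_ivw <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  w <- 1 / input$se_y^2
  sxx <- sum(w * input$beta_x^2)
  if (sxx <= 0) stop("all exposure effects are zero; IVW slope undefined")
  est <- sum(w * input$beta_x * input$beta_y) / sxx
  se <- 1 / sqrt(sxx)
  mr_result("IVW", estimate = est, se = se,
            pval = max(2 * stats::pnorm(-abs(est / se)), 1e-300),
            n_instruments_used = length(input$beta_x))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome associations on the exposure
#' associations with a free intercept (weights `1/se_y^2`). The slope is
#' the causal estimate; the intercept absorbs directional pleiotropy and
#' is retained in the result. Standard errors use the estimated residual
#' scale (as in weighted least squares); slope and intercept are tested
#' against a normal reference. Fewer than 3 instruments yields a
#' not-tested result.
#'
#' @param input An `mr_input`.
#' @return An `mr_result` with `method = "Egger"`.
#' @export
mr_egger <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$beta_x)
  if (J < 3) return(mr_result("Egger", tested = FALSE))
  w <- 1 / input$se_y^2
  bx <- input$beta_x; by <- input$beta_y
  W <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  D <- W * swxx - swx^2
  if (abs(D) < 1e-14 * W * swxx || D <= 0) {
    stop("exposure effects are constant; Egger slope undefined")
  }
  slope <- (W * swxy - swx * swy) / D
  icpt <- (swy - slope * swx) / W
  rss <- sum(w * (by - icpt - slope * bx)^2)
  sigma2 <- rss / (J - 2)
  se_slope <- sqrt(sigma2 * W / D)
  se_icpt <- sqrt(sigma2 * swxx / D)
  mr_result("Egger", estimate = slope, se = se_slope,
            pval = max(2 * stats::pnorm(-abs(slope / se_slope)), 1e-300),
            n_instruments_used = J,
            intercept = icpt,
            intercept_pval = 2 * stats::pnorm(-abs(icpt / se_icpt)))
}

#' MR-PRESSO: global heterogeneity test and outlier-corrected estimate
#'
#' Residual-sum-of-squares heterogeneity test with a simulated reference
#' distribution, followed by per-instrument outlier removal and IVW
#' re-estimation:
#'
#' 1. leave-one-out IVW slopes are computed for each instrument;
#' 2. the observed RSS is `sum_j w_j (by_j - b_loo_j * bx_j)^2` with
#'    `w_j = 1/se_y_j^2`;
#' 3. `n_sim` parametric draws `bx* ~ N(bx, se_x^2)`,
#'    `by* ~ N(b_loo * bx, se_y^2)` are scored by the same statistic
#'    (with leave-one-out slopes recomputed on the simulated data), giving
#'    the empirical global p-value `(1 + #\{RSS* >= RSS\}) / (1 + n_sim)`;
#' 4. each instrument's observed residual term is compared with its
#'    simulated distribution; the per-instrument p-values are
#'    Bonferroni-adjusted and instruments below `outlier_alpha` removed;
#' 5. the reported estimate and p-value are IVW on the retained set
#'    (plain IVW when nothing is removed). If every instrument is
#'    flagged the pair is recorded as not tested.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param input An `mr_input` with at least 4 instruments.
#' @param n_sim Number of simulated datasets (>= 100).
#' @param outlier_alpha Level of the Bonferroni-adjusted outlier test.
#' @return An `mr_result` with `method = "PRESSO"`; the global test
#'   p-value is kept in `global_pval`, removed instruments in
#'   `outliers_removed`.
#' @export
mr_presso <- function(input, n_sim = 1000, outlier_alpha = 0.05) {
  stopifnot(inherits(input, "mr_input"), n_sim >= 100,
            outlier_alpha > 0, outlier_alpha < 1)
  J <- length(input$beta_x)
  if (J < 4) return(mr_result("PRESSO", tested = FALSE))
  w <- 1 / input$se_y^2
  bx <- input$beta_x; by <- input$beta_y

  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  den <- sxx - w * bx^2
  if (any(den <= 0)) stop("leave-one-out IVW slope undefined")
  b_loo <- (sxy - w * bx * by) / den
  r_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(r_obs)

  bxs <- matrix(stats::rnorm(J * n_sim, bx, input$se_x), J, n_sim)
  bys <- matrix(stats::rnorm(J * n_sim, b_loo * bx, input$se_y), J, n_sim)
  sxys <- colSums(w * bxs * bys)
  sxxs <- colSums(w * bxs^2)
  num_s <- matrix(sxys, J, n_sim, byrow = TRUE) - w * bxs * bys
  den_s <- matrix(sxxs, J, n_sim, byrow = TRUE) - w * bxs^2
  rstar <- w * (bys - (num_s / den_s) * bxs)^2
  rss_star <- colSums(rstar)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (1 + n_sim)
  p_out <- (1 + rowSums(rstar >= r_obs)) / (1 + n_sim)
  p_adj <- pmin(1, p_out * J)
  flagged <- which(p_adj < outlier_alpha)

  if (length(flagged) == J) {
    res <- mr_result("PRESSO", tested = FALSE, global_pval = global_p)
    res$outliers_removed <- input$instruments[flagged]
    return(res)
  }
  keep <- setdiff(seq_len(J), flagged)
  sub <- mr_input(bx[keep], input$se_x[keep], by[keep], input$se_y[keep],
                  input$instruments[keep])
  ivw <- mr_ivw(sub)
  mr_result("PRESSO", estimate = ivw$estimate, se = ivw$se, pval = ivw$pval,
            n_instruments_used = length(keep),
            outliers_removed = input$instruments[flagged],
            global_pval = global_p)
}

#' Benjamini-Yekutieli p-value adjustment
#'
#' Step-up adjustment controlling the false discovery rate under
#' arbitrary dependence; wraps `stats::p.adjust(method = "BY")`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order, each >= its input and <= 1.
#' @examples
#' by_adjust(c(0.01, 0.02, 0.9))
#' @export
by_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BY")
}
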