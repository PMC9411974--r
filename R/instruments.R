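#' Marginal GWAS of every trait on every instrument
#'
#' Simple linear regression of each trait column on each genotype column:
#' slope, slope standard error and two-sided t-test p-value. Computed in
#' closed form from centred cross-products, which is exactly equivalent to
#' `lm(trait ~ genotype)` for every pair but vectorised over the full
#' instrument-by-trait grid.
#'
#' Zero-variance genotype columns are flagged with `beta = 0`, `se = Inf`,
#' `pval = 1`.
#'
#' @param dataset An `mr_dataset`.
#' @return An object of class `gwas_table`: matrices `beta`, `se`, `pval`
#'   (instruments x traits) and the sample size `n`. Use
#'   [as.data.frame.gwas_table()] for the long per-pair form.
#' @export
run_gwas <- function(dataset) {
  stopifnot(inherits(dataset, "mr_dataset"))
  G <- dataset$genotypes
  Y <- dataset$traits
  n <- nrow(G)
  stopifnot(n > 3)

  Gc <- scale(G, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)                     # per instrument
  syy <- colSums(Yc^2)                     # per trait
  sxy <- crossprod(Gc, Yc)                 # m x t

  ok <- sxx > 0
  beta <- sxy / ifelse(ok, sxx, 1)
  beta[!ok, ] <- 0
  rss <- pmax(outer(rep(1, length(sxx)), syy) - beta^2 * sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)                 # sxx recycles down columns
  se[!ok, ] <- Inf
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  pval[!ok, ] <- 1
  pval <- pmax(pval, 1e-300)
  dn <- list(colnames(G), colnames(Y))
  dimnames(beta) <- dimnames(se) <- dimnames(pval) <- dn

  structure(list(beta = beta, se = se, pval = pval, n = n),
            class = "gwas_table")
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d instruments x %d traits (n = %d)\n",
              nrow(x$beta), ncol(x$beta), x$n))
  invisible(x)
}

#' Long-format view of a GWAS table
#'
#' @param x A `gwas_table`.
#' @param ... Unused.
#' @return Data frame with columns `instrument`, `trait`, `beta`, `se`,
#'   `pval`, one row per (instrument, trait) pair.
#' @export
as.data.frame.gwas_table <- function(x, ...) {
  data.frame(
    instrument = rep(rownames(x$beta), times = ncol(x$beta)),
    trait = rep(colnames(x$beta), each = nrow(x$beta)),
    beta = as.vector(x$beta),
    se = as.vector(x$se),
    pval = as.vector(x$pval),
    stringsAsFactors = FALSE
  )
}

#' Bonferroni selection of instruments for an exposure
#'
#' Retains the instruments whose marginal association p-value with the
#' exposure satisfies `pval <= alpha / n_tests`; the number of tests
#' defaults to the replicate's total instrument count (around 225 under
#' the default generator), matching a 0.05 family-wise threshold over all
#' available IVs. Instrument weights are the marginal slopes.
#'
#' @param gwas A `gwas_table`.
#' @param exposure Trait id.
#' @param alpha Family-wise significance level.
#' @param n_tests Bonferroni denominator; defaults to the number of
#'   instruments in `gwas`.
#' @return An `instrument_set`: list with `exposure`, `instruments`
#'   (character vector, possibly empty) and `weights` (named numeric).
#' @export
select_instruments <- function(gwas, exposure, alpha = 0.05, n_tests = NULL) {
  stopifnot(inherits(gwas, "gwas_table"),
            exposure %in% colnames(gwas$pval),
            alpha > 0, alpha < 1)
  if (is.null(n_tests)) n_tests <- nrow(gwas$pval)
  stopifnot(n_tests >= 1)
  keep <- rownames(gwas$pval)[gwas$pval[, exposure] <= alpha / n_tests]
  structure(
    list(exposure = exposure,
         instruments = keep,
         weights = stats::setNames(gwas$beta[keep, exposure], keep)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d instruments\n",
              x$exposure, length(x$instruments)))
  invisible(x)
}

#' Conditional association p-values of instruments with other traits
#'
#' For each instrument g and each trait Z other than the exposure X,
#' tests the coefficient of g in the regression `Z ~ g + X` (two-sided
#' t-test, n - 3 df). Under the structural model with no pleiotropy,
#' g is independent of every non-descendant Z given X, so a small
#' p-value is evidence that g affects Z other than through X.
#'
#' Computed by Frisch--Waugh residualisation, vectorised over instruments
#' and traits.
#'
#' @param dataset An `mr_dataset`.
#' @param exposure Trait id conditioned on.
#' @param instruments Instrument ids to test (default: all).
#' @return Matrix of p-values, instruments x traits; the exposure column
#'   is `NA`.
#' @export
conditional_assoc_pvals <- function(dataset, exposure, instruments = NULL) {
  stopifnot(inherits(dataset, "mr_dataset"))
  traits <- colnames(dataset$traits)
  stopifnot(exposure %in% traits)
  if (is.null(instruments)) instruments <- colnames(dataset$genotypes)
  G <- dataset$genotypes[, instruments, drop = FALSE]
  x <- dataset$traits[, exposure]
  Z <- dataset$traits[, setdiff(traits, exposure), drop = FALSE]
  n <- length(x)
  stopifnot(n > 4)

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  # residualise both sides on [1, x]
  Gr <- Gc - outer(xc, colSums(Gc * xc) / sxx)
  Zr <- Zc - outer(xc, colSums(Zc * xc) / sxx)

  sgg <- colSums(Gr^2)
  szz <- colSums(Zr^2)
  sgz <- crossprod(Gr, Zr)                 # instruments x (t-1)
  ok <- sgg > 1e-10
  beta <- sgz / ifelse(ok, sgg, 1)
  rss <- pmax(outer(rep(1, length(sgg)), szz) - beta^2 * sgg, 0)
  se2 <- pmax(rss / (n - 3) / sgg, 1e-300)
  tval <- beta / sqrt(se2)
  pv <- 2 * stats::pt(-abs(tval), df = n - 3)
  pv[!ok, ] <- 1

  out <- matrix(NA_real_, length(instruments), length(traits),
                dimnames = list(instruments, traits))
  out[, colnames(Z)] <- pv
  out
}

#' Conditional-independence ("UniqueIV") instrument filter
#'
#' Starting from the Bonferroni selection for an exposure, retains only
#' the instruments that show no significant conditional association with
#' any other trait given the exposure (see [conditional_assoc_pvals()]).
#' An instrument with a direct pleiotropic effect on another trait is
#' conditionally associated with it and is removed with power growing in
#' the sample size; instruments acting on other traits only through the
#' exposure are retained.
#'
#' When the filtered set feeds the analysis of a specific exposure-outcome
#' pair, pass the outcome in `exclude_traits` so the true causal signal
#' on the outcome is not itself grounds for removal.
#'
#' @param gwas A `gwas_table` (supplies the weights of the result).
#' @param dataset The `mr_dataset` the statistics came from.
#' @param exposure Trait id.
#' @param base_set The Bonferroni `instrument_set` for the exposure.
#' @param ci_alpha Significance level of the conditional test.
#' @param exclude_traits Traits left out of the conditional screen
#'   (e.g. the outcome of the pair under analysis).
#' @return An `instrument_set`, a subset of `base_set`.
#' @export
unique_iv_filter <- function(gwas, dataset, exposure, base_set,
                             ci_alpha = 0.01, exclude_traits = NULL) {
  stopifnot(inherits(base_set, "instrument_set"),
            identical(base_set$exposure, exposure),
            ci_alpha > 0, ci_alpha < 1)
  if (length(base_set$instruments) == 0) return(base_set)
  pm <- conditional_assoc_pvals(dataset, exposure, base_set$instruments)
  keep_from_cond_pvals(gwas, exposure, base_set, pm, ci_alpha, exclude_traits)
}

# shared by unique_iv_filter and the pipeline (which precomputes `pm` once
# per exposure and reuses it across outcome pairs)
keep_from_cond_pvals <- function(gwas, exposure, base_set, pm, ci_alpha,
                                 exclude_traits = NULL) {
  zcols <- setdiff(colnames(pm), c(exposure, exclude_traits))
  if (length(zcols) == 0) return(base_set)
  sub <- pm[base_set$instruments, zcols, drop = FALSE]
  keep <- base_set$instruments[apply(sub, 1, min) > ci_alpha]
  structure(
    list(exposure = exposure,
         instruments = keep,
         weights = stats::setNames(gwas$beta[keep, exposure], keep)),
    class = "instrument_set"
  )
}

#' Weighted allele score
#'
#' Per-sample weighted sum of instrument genotypes, with weights equal to
#' the instruments' marginal slopes on their trait. Used as the single
#' genetic proxy node in the four-variable Bayesian network analysis.
#'
#' @param dataset An `mr_dataset`.
#' @param iset A nonempty `instrument_set`.
#' @return An `allele_score`: list with `trait` and `values`
#'   (length-n numeric vector).
#' @export
weighted_allele_score <- function(dataset, iset) {
  stopifnot(inherits(dataset, "mr_dataset"), inherits(iset, "instrument_set"))
  if (length(iset$instruments) == 0) {
    stop("cannot build an allele score from an empty instrument set")
  }
  v <- as.vector(dataset$genotypes[, iset$instruments, drop = FALSE] %*%
                   iset$weights[iset$instruments])
  structure(list(trait = iset$exposure, values = v), class = "allele_score")
}
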