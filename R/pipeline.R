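#' Run all methods on one simulated replicate
#'
#' Per-replicate analysis: marginal GWAS, Bonferroni instrument selection
#' per trait, optional UniqueIV conditional-independence filtering, the
#' MR estimators (IVW, Egger, PRESSO) on every ordered trait pair with
#' enough instruments, per-method Benjamini-Yekutieli adjustment across
#' pairs, and the four-variable bootstrap-averaged Bayesian network on
#' every unordered pair.
#'
#' When the UniqueIV variant analyses pair (X, Y), the outcome Y is
#' excluded from the conditional screen of X's instruments (and vice
#' versa for the allele scores of the BN pair), so true causal signal on
#' the outcome does not remove valid instruments.
#'
#' Pairs lacking the minimum number of instruments after selection or
#' filtering are recorded with `NA` statistics: they are never counted as
#' discoveries but still shrink power.
#'
#' @param dataset An `mr_dataset`.
#' @param config An [eval_config()]; controls which methods and filter
#'   variants run and the resampling sizes.
#' @return List of class `replicate_analysis` with data frames `mr`
#'   (exposure, outcome, method, filtered, estimate, se, pval,
#'   pval_adjusted, n_instruments_used) and `bn` (t1, t2, strength,
#'   direction_12, prob_12, prob_21, n_boot, filtered).
#' @export
analyse_replicate <- function(dataset, config = eval_config()) {
  stopifnot(inherits(dataset, "mr_dataset"), inherits(config, "eval_config"))
  traits <- colnames(dataset$traits)
  nt <- length(traits)
  gwas <- run_gwas(dataset)

  mr_methods <- intersect(config$methods, c("IVW", "Egger", "PRESSO"))
  do_bn <- "BN" %in% config$methods
  min_iv <- c(IVW = 1L, Egger = 3L, PRESSO = 4L)

  base_sets <- lapply(traits, function(tr) {
    select_instruments(gwas, tr, alpha = config$alpha_select)
  })
  names(base_sets) <- traits

  need_filter <- "uniqueiv" %in% config$filters
  cond_p <- NULL
  if (need_filter) {
    cond_p <- lapply(traits, function(tr) {
      ids <- base_sets[[tr]]$instruments
      if (length(ids) == 0) return(NULL)
      conditional_assoc_pvals(dataset, tr, ids)
    })
    names(cond_p) <- traits
  }

  # UniqueIV sets are pair-independent: an instrument conditionally
  # associated with ANY other trait given its exposure is dropped for all
  # outcomes. True causal signal is safe because g is independent of the
  # exposure's descendants given the exposure under the structural model.
  filt_sets <- NULL
  if (need_filter) {
    filt_sets <- lapply(traits, function(tr) {
      bs <- base_sets[[tr]]
      if (length(bs$instruments) == 0) return(bs)
      keep_from_cond_pvals(gwas, tr, bs, cond_p[[tr]], config$ci_alpha)
    })
    names(filt_sets) <- traits
  }
  set_for <- function(exposure, filt) {
    if (filt == "none") base_sets[[exposure]] else filt_sets[[exposure]]
  }

  mr_rows <- list()
  if (length(mr_methods) > 0) {
    for (filt in config$filters) {
      for (x in traits) for (y in traits) {
        if (x == y) next
        iset <- set_for(x, filt)
        ids <- iset$instruments
        J <- length(ids)
        input <- if (J >= 1) {
          mr_input(gwas$beta[ids, x], gwas$se[ids, x],
                   gwas$beta[ids, y], gwas$se[ids, y], ids)
        }
        for (meth in mr_methods) {
          res <- if (J >= min_iv[[meth]]) {
            switch(meth,
                   IVW = mr_ivw(input),
                   Egger = mr_egger(input),
                   PRESSO = mr_presso(input, n_sim = config$presso_nsim,
                                      outlier_alpha = config$presso_outlier_alpha))
          } else {
            mr_result(meth, tested = FALSE)
          }
          mr_rows[[length(mr_rows) + 1L]] <- data.frame(
            exposure = x, outcome = y, method = meth, filtered = filt,
            estimate = res$estimate, se = res$se, pval = res$pval,
            n_instruments_used = res$n_instruments_used,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  mr <- if (length(mr_rows) > 0) {
    do.call(rbind, mr_rows)
  } else {
    data.frame(exposure = character(0), outcome = character(0),
               method = character(0), filtered = character(0),
               estimate = numeric(0), se = numeric(0), pval = numeric(0),
               n_instruments_used = integer(0),
               pval_adjusted = numeric(0), stringsAsFactors = FALSE)
  }

  # BY adjustment per method x filter variant, across the pairs actually
  # tested in this replicate
  if (nrow(mr) > 0) {
    mr$pval_adjusted <- NA_real_
    for (meth in unique(mr$method)) for (filt in unique(mr$filtered)) {
      sel <- mr$method == meth & mr$filtered == filt & !is.na(mr$pval)
      if (any(sel)) mr$pval_adjusted[sel] <- by_adjust(mr$pval[sel])
    }
  }

  bn_rows <- list()
  if (do_bn) {
    score_from <- function(sets) {
      out <- lapply(traits, function(tr) {
        s <- sets[[tr]]
        if (length(s$instruments) == 0) return(NULL)
        weighted_allele_score(dataset, s)
      })
      names(out) <- traits
      out
    }
    scores_filt <- if ("none" %in% config$filters) score_from(base_sets)
    scores_uiv <- if (need_filter) score_from(filt_sets)
    for (filt in config$filters) {
      for (i in seq_len(nt - 1L)) for (j in seq.int(i + 1L, nt)) {
        t1 <- traits[i]; t2 <- traits[j]
        if (filt == "none") {
          sc1 <- scores_filt[[t1]]; sc2 <- scores_filt[[t2]]
        } else {
          sc1 <- scores_uiv[[t1]]; sc2 <- scores_uiv[[t2]]
        }
        if (is.null(sc1) || is.null(sc2)) {
          bn_rows[[length(bn_rows) + 1L]] <- data.frame(
            t1 = t1, t2 = t2, strength = NA_real_, direction_12 = NA_real_,
            prob_12 = NA_real_, prob_21 = NA_real_,
            n_boot = config$n_boot, filtered = filt, stringsAsFactors = FALSE
          )
          next
        }
        dat4 <- four_var_data(dataset, t1, t2, sc1, sc2)
        ep <- average_network(dat4, n_boot = config$n_boot)
        bn_rows[[length(bn_rows) + 1L]] <- data.frame(
          t1 = t1, t2 = t2, strength = ep$strength,
          direction_12 = ep$direction_12,
          prob_12 = ep$prob_12, prob_21 = ep$prob_21,
          n_boot = ep$n_boot, filtered = filt, stringsAsFactors = FALSE
        )
      }
    }
  }
  bn <- if (length(bn_rows) > 0) {
    do.call(rbind, bn_rows)
  } else {
    data.frame(t1 = character(0), t2 = character(0), strength = numeric(0),
               direction_12 = numeric(0), prob_12 = numeric(0),
               prob_21 = numeric(0), n_boot = integer(0),
               filtered = character(0), stringsAsFactors = FALSE)
  }

  structure(list(mr = mr, bn = bn, traits = traits),
            class = "replicate_analysis")
}

#' Per-ordered-pair discovery statistics for one replicate
#'
#' Flattens a [analyse_replicate()] result into one row per (method,
#' filter, exposure, outcome): the MR rows carry the BY-adjusted (or raw)
#' p-value, the BN rows carry the directed-edge probability for each
#' orientation of every analysed pair. `NA` marks untested pairs.
#'
#' @param analysis A `replicate_analysis`.
#' @param adjust_mr Use BY-adjusted MR p-values (default) or raw ones.
#' @return Data frame with columns `method`, `filtered`, `exposure`,
#'   `outcome`, `stat`, `mode`.
#' @export
replicate_stat_tables <- function(analysis, adjust_mr = TRUE) {
  out <- list()
  mr <- analysis$mr
  if (nrow(mr) > 0) {
    out[[1L]] <- data.frame(
      method = mr$method, filtered = mr$filtered,
      exposure = mr$exposure, outcome = mr$outcome,
      stat = if (adjust_mr) mr$pval_adjusted else mr$pval,
      mode = "pvalue", stringsAsFactors = FALSE
    )
  }
  bn <- analysis$bn
  if (nrow(bn) > 0) {
    out[[length(out) + 1L]] <- data.frame(
      method = "BN", filtered = rep(bn$filtered, 2L),
      exposure = c(bn$t1, bn$t2), outcome = c(bn$t2, bn$t1),
      stat = c(bn$prob_12, bn$prob_21),
      mode = "probability", stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
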