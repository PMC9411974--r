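#' Threshold a table of per-pair statistics into discoveries
#'
#' In `"pvalue"` mode a pair is discovered when its statistic is at or
#' below the threshold; in `"probability"` mode when at or above.
#' Untested pairs (`NA` statistics) are never discoveries.
#'
#' @param scores Data frame with columns `exposure`, `outcome`, `stat`.
#' @param threshold Discovery threshold.
#' @param mode `"pvalue"` or `"probability"`.
#' @return The discovered subset of `scores` rows.
#' @export
discoveries <- function(scores, threshold, mode = c("pvalue", "probability")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(scores),
            all(c("exposure", "outcome", "stat") %in% names(scores)))
  if (nrow(scores) == 0) return(scores)
  hit <- if (mode == "pvalue") scores$stat <= threshold else
    scores$stat >= threshold
  scores[!is.na(scores$stat) & hit, , drop = FALSE]
}

#' Empirical FDR, power and discovery count for one replicate
#'
#' Scores a discovery set against the directed-path ground truth:
#' `fdr = FP / (TP + FP)` (0 when nothing is discovered),
#' `power = TP / #positives` where positives are the ordered trait pairs
#' connected by a directed path. A replicate whose graph has no positive
#' pairs is flagged degenerate and contributes power 0.
#'
#' @param found Data frame of discovered pairs (columns `exposure`,
#'   `outcome`), e.g. from [discoveries()].
#' @param truth Logical reachability matrix from [true_causal_matrix()].
#' @return List with `fdr`, `power`, `n_discoveries`, `tp`, `fp`,
#'   `n_positives`, `degenerate`.
#' @export
fdr_power <- function(found, truth) {
  stopifnot(is.matrix(truth), is.logical(truth),
            nrow(truth) == ncol(truth))
  n_pos <- sum(truth)
  nf <- nrow(found)
  if (nf > 0) {
    stopifnot(all(found$exposure %in% rownames(truth)),
              all(found$outcome %in% colnames(truth)))
    tp <- sum(truth[cbind(found$exposure, found$outcome)])
  } else {
    tp <- 0L
  }
  fp <- nf - tp
  list(
    fdr = if (nf > 0) fp / nf else 0,
    power = if (n_pos > 0) tp / n_pos else 0,
    n_discoveries = nf,
    tp = tp, fp = fp, n_positives = n_pos,
    degenerate = n_pos == 0
  )
}

#' Replicate-averaged ROC curve
#'
#' At each threshold on a common grid, computes every replicate's true
#' positive rate (`TP / #positives`) and false positive rate
#' (`FP / #negatives`, negatives being ordered non-diagonal pairs with no
#' directed path), then averages across replicates. Untested pairs are
#' never discovered, and BY truncation at 1 or zero-probability edges can
#' keep the mean curve away from (1, 1).
#'
#' @param score_tables List (one per replicate) of data frames with
#'   columns `exposure`, `outcome`, `stat`.
#' @param truths List of reachability matrices, parallel to
#'   `score_tables`.
#' @param grid Numeric vector of thresholds.
#' @param mode `"pvalue"` (discover at `stat <= t`) or `"probability"`
#'   (discover at `stat >= t`).
#' @return Data frame of class `roc_curve` with columns `threshold`,
#'   `mean_tpr`, `mean_fpr`, ordered from strict to loose.
#'
#' @details The degenerate endpoint of the grid is dropped: a probability
#' threshold of exactly 0 (every tested pair discovered) and a p-value
#' threshold of exactly 1 (pairs with adjusted p truncated at 1
#' discovered) say nothing about ranking, and edges with bootstrap
#' probability 0 or adjusted p-values of 1 are deliberately never
#' discoverable at any retained threshold.
#' @export
roc_curve <- function(score_tables, truths, grid = seq(0, 1, length.out = 201),
                      mode = c("pvalue", "probability")) {
  mode <- match.arg(mode)
  grid <- if (mode == "pvalue") grid[grid < 1] else grid[grid > 0]
  stopifnot(length(score_tables) >= 1, length(grid) >= 1,
            length(truths) == length(score_tables))
  tpr <- matrix(0, length(score_tables), length(grid))
  fpr <- matrix(0, length(score_tables), length(grid))
  for (r in seq_along(score_tables)) {
    sc <- score_tables[[r]]
    truth <- truths[[r]]
    n_pos <- sum(truth)
    n_neg <- nrow(truth) * (nrow(truth) - 1) - n_pos
    is_pos <- truth[cbind(sc$exposure, sc$outcome)]
    stat <- sc$stat
    hit <- if (mode == "pvalue") {
      outer(stat, grid, `<=`)
    } else {
      outer(stat, grid, `>=`)
    }
    hit[is.na(stat), ] <- FALSE
    tp <- colSums(hit & is_pos)
    fp <- colSums(hit & !is_pos)
    tpr[r, ] <- if (n_pos > 0) tp / n_pos else 0
    fpr[r, ] <- if (n_neg > 0) fp / n_neg else 0
  }
  ord <- if (mode == "pvalue") order(grid) else order(grid, decreasing = TRUE)
  out <- data.frame(threshold = grid[ord],
                    mean_tpr = colMeans(tpr)[ord],
                    mean_fpr = colMeans(fpr)[ord])
  class(out) <- c("roc_curve", "data.frame")
  out
}

# deterministic child seeds: one per (p_pleio setting, replicate)
derive_seeds <- function(seed, n_settings, n_replicates) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, n_settings * n_replicates),
         nrow = n_replicates, ncol = n_settings)
}

#' Run the full simulation benchmark
#'
#' For every pleiotropy level in `eval_cfg$p_pleio_grid` and every
#' replicate: draws a causal trait graph and dataset, runs the configured
#' methods via [analyse_replicate()], thresholds discoveries, and scores
#' them against the directed-path truth. Each (setting, replicate) uses a
#' deterministic child seed derived from `sim_cfg$seed`, so any replicate
#' can be reproduced in isolation. Replicates that fail are logged,
#' skipped and counted.
#'
#' @param sim_cfg A [sim_config()]; its `p_pleio` is overridden by the
#'   grid in `eval_cfg`.
#' @param eval_cfg An [eval_config()].
#' @param verbose Print one progress line per replicate.
#' @return An object of class `mr_bn_experiment`: list with
#'   `summary` (mean FDR/power/discoveries per method x filter x p_pleio
#'   x threshold), `per_replicate` (the unaggregated rows), `roc` (long
#'   data frame of mean ROC curves per method x filter x p_pleio),
#'   `n_failed`, and the two configs.
#' @export
run_experiment <- function(sim_cfg = sim_config(), eval_cfg = eval_config(),
                           verbose = FALSE) {
  stopifnot(inherits(sim_cfg, "sim_config"), inherits(eval_cfg, "eval_config"))
  grid_p <- eval_cfg$p_pleio_grid
  n_rep <- sim_cfg$n_replicates
  seeds <- derive_seeds(sim_cfg$seed, length(grid_p), n_rep)

  rep_rows <- list()
  roc_store <- list() # per setting: list(tables = list of stat dfs, truths)
  n_failed <- 0L

  for (pi in seq_along(grid_p)) {
    cfg <- sim_cfg
    cfg$p_pleio <- grid_p[pi]
    tables_r <- vector("list", n_rep)
    truths_r <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      res <- tryCatch({
        set.seed(seeds[r, pi])
        graph <- sample_trait_graph(cfg)
        ds <- simulate_dataset(graph, cfg)
        truth <- true_causal_matrix(graph)
        an <- analyse_replicate(ds, eval_cfg)
        list(truth = truth,
             stats = replicate_stat_tables(an, adjust_mr = eval_cfg$adjust_mr))
      }, error = function(e) {
        warning(sprintf("replicate %d (p_pleio = %.2f) failed: %s",
                        r, grid_p[pi], conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      tables_r[[r]] <- res$stats
      truths_r[[r]] <- res$truth
      st <- res$stats
      variants <- unique(st[, c("method", "filtered", "mode")])
      for (v in seq_len(nrow(variants))) {
        vv <- variants[v, ]
        sub <- st[st$method == vv$method & st$filtered == vv$filtered, ]
        thresholds <- if (vv$mode == "pvalue") eval_cfg$mr_thresholds else
          eval_cfg$bn_thresholds
        for (th in thresholds) {
          found <- discoveries(sub, th, mode = vv$mode)
          fp <- fdr_power(found, res$truth)
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            method = vv$method, filtered = vv$filtered,
            p_pleio = grid_p[pi], threshold = th, replicate = r,
            fdr = fp$fdr, power = fp$power,
            n_discoveries = fp$n_discoveries,
            degenerate = fp$degenerate, stringsAsFactors = FALSE
          )
        }
      }
      if (verbose) {
        message(sprintf("p_pleio %.2f replicate %d/%d done",
                        grid_p[pi], r, n_rep))
      }
    }
    ok <- !vapply(tables_r, is.null, logical(1))
    roc_store[[pi]] <- list(tables = tables_r[ok], truths = truths_r[ok])
  }

  per_replicate <- do.call(rbind, rep_rows)
  if (is.null(per_replicate)) stop("every replicate failed; nothing to summarise")
  summary_df <- stats::aggregate(
    cbind(fdr, power, n_discoveries) ~ method + filtered + p_pleio + threshold,
    data = per_replicate, FUN = mean
  )
  names(summary_df)[names(summary_df) == "fdr"] <- "mean_fdr"
  names(summary_df)[names(summary_df) == "power"] <- "mean_power"
  names(summary_df)[names(summary_df) == "n_discoveries"] <- "mean_discoveries"
  summary_df <- summary_df[order(summary_df$method, summary_df$filtered,
                                 summary_df$p_pleio, summary_df$threshold), ]
  rownames(summary_df) <- NULL

  roc_grid <- seq(0, 1, length.out = eval_cfg$roc_points)
  roc_rows <- list()
  for (pi in seq_along(grid_p)) {
    store <- roc_store[[pi]]
    if (length(store$tables) == 0) next
    variants <- unique(do.call(rbind,
      lapply(store$tables, function(x) x[, c("method", "filtered", "mode")])))
    for (v in seq_len(nrow(variants))) {
      vv <- variants[v, ]
      subs <- lapply(store$tables, function(x) {
        x[x$method == vv$method & x$filtered == vv$filtered, ]
      })
      rc <- roc_curve(subs, store$truths, grid = roc_grid, mode = vv$mode)
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        method = vv$method, filtered = vv$filtered, p_pleio = grid_p[pi],
        threshold = rc$threshold, mean_tpr = rc$mean_tpr,
        mean_fpr = rc$mean_fpr, stringsAsFactors = FALSE
      )
    }
  }
  roc <- if (length(roc_rows) > 0) do.call(rbind, roc_rows) else NULL

  structure(
    list(summary = summary_df, per_replicate = per_replicate, roc = roc,
         n_failed = n_failed, sim_config = sim_cfg, eval_config = eval_cfg),
    class = "mr_bn_experiment"
  )
}

#' @export
print.mr_bn_experiment <- function(x, ...) {
  cat(sprintf("Simulation benchmark: %d replicates x p_pleio {%s}, %d failed\n",
              x$sim_config$n_replicates,
              paste(x$eval_config$p_pleio_grid, collapse = ", "),
              x$n_failed))
  print(utils::head(x$summary, 20))
  if (nrow(x$summary) > 20) cat(sprintf("... %d more rows\n",
                                        nrow(x$summary) - 20))
  invisible(x)
}
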