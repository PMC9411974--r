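#' Four-variable data table for a Bayesian network pair analysis
#'
#' Assembles the two trait columns and their weighted allele scores into
#' the `n x 4` matrix (`T1`, `T2`, `S1`, `S2`) scored by the constrained
#' network search.
#'
#' @param dataset An `mr_dataset`.
#' @param t1,t2 Trait ids.
#' @param score1,score2 `allele_score` objects for `t1` and `t2`.
#' @return Numeric matrix with columns `T1`, `T2`, `S1`, `S2`.
#' @export
four_var_data <- function(dataset, t1, t2, score1, score2) {
  stopifnot(inherits(dataset, "mr_dataset"),
            inherits(score1, "allele_score"), inherits(score2, "allele_score"),
            identical(score1$trait, t1), identical(score2$trait, t2))
  out <- cbind(T1 = dataset$traits[, t1], T2 = dataset$traits[, t2],
               S1 = score1$values, S2 = score2$values)
  stopifnot(nrow(out) == nrow(dataset$traits))
  out
}

#' Admissible four-variable network structures
#'
#' The allele scores are fixed parents of their traits (`S1 -> T1`,
#' `S2 -> T2`) and may gain no other edges, so the only free edge is
#' between the two traits: absent, `T1 -> T2` or `T2 -> T1`.
#'
#' @return Character vector of the three structure labels.
#' @export
bn_structures <- function() c("none", "t1->t2", "t2->t1")

# Gaussian node score: max log-likelihood of y | parents minus the BIC
# penalty (d/2) log n with d = #slopes + intercept + variance.
node_score <- function(y, X, n) {
  Xm <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  fit <- stats::lm.fit(Xm, y)
  if (any(is.na(fit$coefficients))) stop("singular regression in network score")
  rss <- max(sum(fit$residuals^2), 1e-12)
  d <- length(fit$coefficients) + 1
  -n / 2 * (log(2 * pi * rss / n) + 1) - d / 2 * log(n)
}

#' BIC network score of a four-variable structure
#'
#' Sum over nodes of the maximised Gaussian log-likelihood of the node
#' given its parents minus a BIC penalty of `(d/2) log n` per node, where
#' `d` counts the node's regression coefficients, intercept and variance.
#' Higher is better. The score-node terms for `S1` and `S2` (no parents)
#' are included, so scores are comparable across the three structures.
#'
#' @param data A matrix from [four_var_data()] with more than 6 rows.
#' @param structure One of `bn_structures()`.
#' @return The network score (numeric scalar).
#' @export
gaussian_bic_score <- function(data, structure = bn_structures()) {
  structure <- match.arg(structure)
  n <- nrow(data)
  stopifnot(n > 6, ncol(data) == 4)
  t1 <- data[, "T1"]; t2 <- data[, "T2"]
  s1 <- data[, "S1"]; s2 <- data[, "S2"]
  base <- node_score(s1, NULL, n) + node_score(s2, NULL, n)
  base + switch(
    structure,
    "none"   = node_score(t1, cbind(s1), n) + node_score(t2, cbind(s2), n),
    "t1->t2" = node_score(t1, cbind(s1), n) + node_score(t2, cbind(s2, t1), n),
    "t2->t1" = node_score(t1, cbind(s1, t2), n) + node_score(t2, cbind(s2), n)
  )
}

#' Best-scoring admissible structure
#'
#' Exhaustively scores the three admissible structures and returns the
#' argmax; ties break toward `"none"`, then `"t1->t2"`. With only three
#' candidates the search is exact and needs no restarts.
#'
#' @param data A matrix from [four_var_data()].
#' @return One of `bn_structures()`.
#' @export
best_structure <- function(data) {
  sc <- vapply(bn_structures(), function(s) gaussian_bic_score(data, s),
               numeric(1))
  bn_structures()[which.max(sc)]
}

#' Bootstrap-averaged edge probability for a trait pair
#'
#' Resamples the rows of the four-variable table with replacement
#' `n_boot` times, fits the best structure to each resample, and tallies
#' the outcomes. The *strength* is the proportion of resamples in which
#' the trait-trait edge appears (either direction); the *direction* is
#' the proportion of those in which it points `T1 -> T2`; the probability
#' of each directed edge is the product of strength and direction (or its
#' complement). When the edge never appears the direction is defined as 0
#' and both directed-edge probabilities are 0.
#'
#' All bootstrap fits are computed from count-weighted cross-products in
#' a single pass, which is exactly the BIC comparison [best_structure()]
#' performs on each materialised resample. A resample in which any of the
#' four columns is degenerate (zero variance, or collinear predictors)
#' falls back to `"none"`.
#'
#' Uses the current RNG state; seed beforehand for reproducibility. The
#' index stream is a single `sample.int(n, n * n_boot, replace = TRUE)`
#' call, consumed one resample per consecutive block of `n` indices.
#'
#' @param data A matrix from [four_var_data()].
#' @param n_boot Number of bootstrap resamples.
#' @return An `edge_probability`: list with `strength`, `direction_12`,
#'   `prob_12`, `prob_21`, `n_boot` and the structure `tallies`.
#' @export
average_network <- function(data, n_boot = 1000) {
  n <- nrow(data)
  stopifnot(n > 6, ncol(data) == 4, n_boot >= 1)
  t1 <- data[, "T1"]; t2 <- data[, "T2"]
  s1 <- data[, "S1"]; s2 <- data[, "S2"]

  P <- cbind(t1, t2, s1, s2,
             t1 * t1, t2 * t2, s1 * s1, s2 * s2,
             t1 * t2, t1 * s1, t2 * s2, t2 * s1, t1 * s2)

  idx <- sample.int(n, n * n_boot, replace = TRUE)
  cnt <- tabulate(idx + n * rep(0:(n_boot - 1L), each = n),
                  nbins = n * n_boot)
  C <- matrix(as.double(cnt), n, n_boot)
  M <- crossprod(P, C) # 13 x n_boot moment sums

  m1 <- M[1, ]; m2 <- M[2, ]; m3 <- M[3, ]; m4 <- M[4, ]
  S11 <- M[5, ] - m1^2 / n;  S22 <- M[6, ] - m2^2 / n
  S33 <- M[7, ] - m3^2 / n;  S44 <- M[8, ] - m4^2 / n
  S12 <- M[9, ] - m1 * m2 / n
  S13 <- M[10, ] - m1 * m3 / n
  S24 <- M[11, ] - m2 * m4 / n
  S23 <- M[12, ] - m2 * m3 / n
  S14 <- M[13, ] - m1 * m4 / n

  ll <- function(rss, n_par) {
    rss <- pmax(rss, 1e-12)
    -n / 2 * (log(2 * pi * rss / n) + 1) - (n_par + 2) / 2 * log(n)
  }

  # T1 ~ S1 ; T2 ~ S2
  rss_a <- S11 - S13^2 / S33
  rss_b <- S22 - S24^2 / S44
  # T2 ~ S2 + T1
  det_c <- S44 * S11 - S14^2
  b1 <- (S11 * S24 - S14 * S12) / det_c
  b2 <- (S44 * S12 - S14 * S24) / det_c
  rss_c <- S22 - (b1 * S24 + b2 * S12)
  # T1 ~ S1 + T2
  det_d <- S33 * S22 - S23^2
  c1 <- (S22 * S13 - S23 * S12) / det_d
  c2 <- (S33 * S12 - S23 * S13) / det_d
  rss_d <- S11 - (c1 * S13 + c2 * S12)

  sc_t1_s1 <- ll(rss_a, 1); sc_t2_s2 <- ll(rss_b, 1)
  sc_t2_s2t1 <- ll(rss_c, 2); sc_t1_s1t2 <- ll(rss_d, 2)

  scores <- cbind(none = sc_t1_s1 + sc_t2_s2,
                  `t1->t2` = sc_t1_s1 + sc_t2_s2t1,
                  `t2->t1` = sc_t1_s1t2 + sc_t2_s2)

  tol <- 1e-10
  degenerate <- S11 < tol | S22 < tol | S33 < tol | S44 < tol |
    abs(det_c) < tol | abs(det_d) < tol
  choice <- max.col(scores, ties.method = "first")
  choice[degenerate] <- 1L

  n12 <- sum(choice == 2L); n21 <- sum(choice == 3L)
  n_edge <- n12 + n21
  strength <- n_edge / n_boot
  direction_12 <- if (n_edge > 0) n12 / n_edge else 0
  structure(
    list(strength = strength,
         direction_12 = direction_12,
         prob_12 = strength * direction_12,
         prob_21 = strength * (1 - direction_12),
         n_boot = as.integer(n_boot),
         tallies = c(none = n_boot - n_edge, `t1->t2` = n12, `t2->t1` = n21)),
    class = "edge_probability"
  )
}

#' @export
print.edge_probability <- function(x, ...) {
  cat(sprintf("Edge probability (%d bootstraps): strength %.3f, direction(T1->T2) %.3f\n",
              x$n_boot, x$strength, x$direction_12))
  cat(sprintf("  P(T1->T2) = %.3f, P(T2->T1) = %.3f\n", x$prob_12, x$prob_21))
  invisible(x)
}
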