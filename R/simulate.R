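#' Draw a random causal trait graph with instrument assignments
#'
#' Samples the ground-truth structure of one replicate: a random DAG over
#' the traits, signed effect sizes on its edges, per-trait binary
#' instruments with allele frequencies and primary effects, and (when
#' `p_pleio > 0`) direct pleiotropic instrument effects on non-primary
#' traits.
#'
#' The DAG is built over a uniformly random trait ordering; the trait at
#' position i receives `rpois(1, mean_children)` children (truncated to the
#' number of traits later in the ordering), chosen uniformly among them.
#' Acyclicity is guaranteed by construction. Each (instrument, non-primary
#' trait) pair independently gains a direct pleiotropic effect with
#' probability `p_pleio`; effect magnitudes are uniform on
#' `config$effect_range` with random sign.
#'
#' Uses the current R random number generator state; call [set.seed()]
#' beforehand for reproducibility.
#'
#' @param config A [sim_config()].
#' @return An object of class `trait_graph` with elements
#'   `trait_ids`, `edges` (data frame `parent`, `child`, `effect`),
#'   `instruments` (data frame `iv_id`, `trait`, `effect`, `freq`) and
#'   `pleiotropy` (data frame `iv_id`, `trait`, `effect`).
#' @examples
#' set.seed(1)
#' g <- sample_trait_graph(sim_config(n_traits = 5))
#' g$edges
#' @export
sample_trait_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$n_traits
  trait_ids <- sprintf("trait_%02d", seq_len(nt))

  ord <- sample.int(nt) # position -> trait index in causal order
  edge_list <- vector("list", nt)
  for (i in seq_len(nt - 1L)) {
    pool <- ord[(i + 1L):nt]
    k <- min(stats::rpois(1L, config$mean_children), length(pool))
    if (k > 0L) {
      ch <- pool[sample.int(length(pool), k)]
      eff <- stats::runif(k, config$effect_range[1], config$effect_range[2]) *
        sample(c(-1, 1), k, replace = TRUE)
      edge_list[[i]] <- data.frame(
        parent = trait_ids[ord[i]], child = trait_ids[ch], effect = eff,
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- do.call(rbind, edge_list[!vapply(edge_list, is.null, logical(1))])
  if (is.null(edges)) {
    edges <- data.frame(parent = character(0), child = character(0),
                        effect = numeric(0), stringsAsFactors = FALSE)
  }

  iv_pool <- seq.int(config$iv_per_trait_min, config$iv_per_trait_max)
  n_iv <- iv_pool[sample.int(length(iv_pool), nt, replace = TRUE)]
  m <- sum(n_iv)
  iv_ids <- sprintf("iv_%03d", seq_len(m))
  instruments <- data.frame(
    iv_id = iv_ids,
    trait = rep(trait_ids, times = n_iv),
    effect = stats::runif(m, config$effect_range[1], config$effect_range[2]) *
      sample(c(-1, 1), m, replace = TRUE),
    freq = stats::runif(m, config$maf_range[1], config$maf_range[2]),
    stringsAsFactors = FALSE
  )

  # horizontal pleiotropy: each instrument independently becomes
  # pleiotropic with probability p_pleio, gaining a direct effect on one
  # uniformly chosen non-primary trait
  pleiotropy <- data.frame(iv_id = character(0), trait = character(0),
                           effect = numeric(0), stringsAsFactors = FALSE)
  if (config$p_pleio > 0 && nt > 1) {
    hit <- stats::runif(m) < config$p_pleio
    if (any(hit)) {
      np <- sum(hit)
      other <- vapply(which(hit), function(k) {
        pool <- setdiff(trait_ids, instruments$trait[k])
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      pleiotropy <- data.frame(
        iv_id = iv_ids[hit],
        trait = other,
        effect = stats::runif(np, config$effect_range[1],
                              config$effect_range[2]) *
          sample(c(-1, 1), np, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }

  structure(
    list(trait_ids = trait_ids, edges = edges, instruments = instruments,
         pleiotropy = pleiotropy),
    class = "trait_graph"
  )
}

# igraph object over the trait-to-trait edges (vertices = all traits)
trait_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("parent", "child")],
                                directed = TRUE,
                                vertices = graph$trait_ids)
}

#' @export
print.trait_graph <- function(x, ...) {
  cat(sprintf("Causal trait graph: %d traits, %d causal edges, %d instruments, %d pleiotropic effects\n",
              length(x$trait_ids), nrow(x$edges), nrow(x$instruments),
              nrow(x$pleiotropy)))
  invisible(x)
}

#' Simulate one replicate dataset from a trait graph
#'
#' Generates genotypes and traits under a linear-Gaussian structural
#' equation model. Each instrument column is Bernoulli with its assigned
#' frequency; traits are then built in topological order as the sum of
#' their instrument effects (primary and pleiotropic), their parent-trait
#' effects, and independent `Normal(0, noise_sd^2)` noise.
#'
#' @param graph A `trait_graph` from [sample_trait_graph()].
#' @param config The [sim_config()] used to draw the graph (supplies
#'   `n_samples` and `noise_sd`).
#' @return An object of class `mr_dataset`: list with `genotypes`
#'   (n x m binary matrix), `traits` (n x n_traits numeric matrix) and
#'   `graph`.
#' @export
simulate_dataset <- function(graph, config) {
  stopifnot(inherits(graph, "trait_graph"), inherits(config, "sim_config"))
  n <- config$n_samples
  m <- nrow(graph$instruments)
  nt <- length(graph$trait_ids)

  G <- matrix(stats::rbinom(n * m, 1L, rep(graph$instruments$freq, each = n)),
              nrow = n, ncol = m,
              dimnames = list(NULL, graph$instruments$iv_id))

  # instrument -> trait effect matrix (primary + pleiotropic)
  B <- matrix(0, m, nt, dimnames = list(graph$instruments$iv_id,
                                        graph$trait_ids))
  B[cbind(graph$instruments$iv_id, graph$instruments$trait)] <-
    graph$instruments$effect
  if (nrow(graph$pleiotropy) > 0) {
    B[cbind(graph$pleiotropy$iv_id, graph$pleiotropy$trait)] <-
      B[cbind(graph$pleiotropy$iv_id, graph$pleiotropy$trait)] +
      graph$pleiotropy$effect
  }

  ig <- trait_igraph(graph)
  if (!igraph::is_dag(ig)) stop("trait graph contains a cycle")
  topo <- names(igraph::topo_sort(ig, mode = "out"))

  Y <- matrix(0, n, nt, dimnames = list(NULL, graph$trait_ids))
  genetic <- G %*% B
  for (tr in topo) {
    y <- genetic[, tr] + stats::rnorm(n, 0, config$noise_sd)
    par_rows <- graph$edges[graph$edges$child == tr, , drop = FALSE]
    if (nrow(par_rows) > 0) {
      y <- y + Y[, par_rows$parent, drop = FALSE] %*% par_rows$effect
    }
    Y[, tr] <- y
  }

  structure(list(genotypes = G, traits = Y, graph = graph),
            class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d samples, %d traits, %d instruments\n",
              nrow(x$traits), ncol(x$traits), ncol(x$genotypes)))
  invisible(x)
}

#' Directed-path ground truth for a trait graph
#'
#' Trait i is considered causal on trait j when a directed path from i
#' to j exists in the trait graph, with any number of intermediate
#' traits. This is the positive set against which discoveries are scored.
#'
#' @param graph A `trait_graph`.
#' @return Logical `n_traits x n_traits` matrix; entry (i, j) is `TRUE`
#'   iff a directed path i -> j exists. Diagonal is `FALSE`.
#' @export
true_causal_matrix <- function(graph) {
  ig <- trait_igraph(graph)
  if (!igraph::is_dag(ig)) stop("trait graph contains a cycle")
  d <- igraph::distances(ig, mode = "out")
  d <- d[graph$trait_ids, graph$trait_ids]
  reach <- is.finite(d) & d > 0
  dimnames(reach) <- list(graph$trait_ids, graph$trait_ids)
  reach
}

#' Total causal effects implied by a trait graph
#'
#' Path-tracing totals: the (i, j) entry is the sum over all directed
#' paths from trait i to trait j of the product of edge effects, i.e.
#' `solve(I - A) - I` for the direct-effect matrix A. This is the
#' estimand a valid-instrument MR analysis of exposure i on outcome j
#' targets under the linear model.
#'
#' @param graph A `trait_graph`.
#' @return Numeric `n_traits x n_traits` matrix of total effects.
#' @export
total_effect_matrix <- function(graph) {
  nt <- length(graph$trait_ids)
  A <- matrix(0, nt, nt, dimnames = list(graph$trait_ids, graph$trait_ids))
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$parent, graph$edges$child)] <- graph$edges$effect
  }
  solve(diag(nt) - A) - diag(nt)
}
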