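# Independent oracles and fixture builders used across the test files.

# DFS path-existence oracle: reachability by explicit depth-first search
# over the edge list, independent of the package's transitive closure.
dfs_reachable <- function(trait_ids, edges) {
  adj <- split(edges$child, factor(edges$parent, levels = trait_ids))
  out <- matrix(FALSE, length(trait_ids), length(trait_ids),
                dimnames = list(trait_ids, trait_ids))
  for (start in trait_ids) {
    stack <- adj[[start]]
    seen <- character(0)
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, adj[[v]])
    }
    out[start, seen] <- TRUE
  }
  out
}

# Step-up Benjamini-Yekutieli oracle, written from the definition:
# adjusted_(i) = min(1, min_{j >= i} m * c(m) * p_(j) / j).
by_stepup_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  raw <- m * cm * ps / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(raw))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# BIC network score oracle built on lm()/logLik(), independent of the
# package's closed-form scoring.
lm_structure_score <- function(data, structure) {
  n <- nrow(data)
  df <- as.data.frame(data)
  node <- function(formula) {
    fit <- lm(formula, data = df)
    ll <- logLik(fit)
    as.numeric(ll) - attr(ll, "df") / 2 * log(n)
  }
  base <- node(S1 ~ 1) + node(S2 ~ 1)
  base + switch(structure,
    "none"   = node(T1 ~ S1) + node(T2 ~ S2),
    "t1->t2" = node(T1 ~ S1) + node(T2 ~ S2 + T1),
    "t2->t1" = node(T1 ~ S1 + T2) + node(T2 ~ S2)
  )
}

# Small dataset fixture: draws a graph + dataset at reduced size.
small_dataset <- function(seed = 1, n_traits = 4, n_samples = 400,
                          p_pleio = 0, iv_per_trait_min = 4,
                          iv_per_trait_max = 6, ...) {
  cfg <- sim_config(n_traits = n_traits, n_samples = n_samples,
                    p_pleio = p_pleio, iv_per_trait_min = iv_per_trait_min,
                    iv_per_trait_max = iv_per_trait_max, ...)
  set.seed(seed)
  g <- sample_trait_graph(cfg)
  list(config = cfg, graph = g, dataset = simulate_dataset(g, cfg))
}

# Hand-built gwas_table for tests that exercise selection logic directly.
fake_gwas <- function(pvals, betas = NULL, exposure = "trait_01") {
  m <- length(pvals)
  if (is.null(betas)) betas <- rep(0.2, m)
  ids <- sprintf("iv_%03d", seq_len(m))
  mk <- function(v) matrix(v, m, 1, dimnames = list(ids, exposure))
  structure(list(beta = mk(betas), se = mk(0.05), pval = mk(pvals), n = 1000L),
            class = "gwas_table")
}
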