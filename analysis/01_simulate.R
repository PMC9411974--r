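#!/usr/bin/env Rscript
# Simulate one example replicate at each pleiotropy level and write the
# datasets (genotypes, traits, generating graph) as plain text under
# results/data/. These replicates are reused by 02_single_replicate.R.

library(mrbnbench)

p_pleio_levels <- c(0, 0.2, 0.4)
out_root <- "results/data"

for (pp in p_pleio_levels) {
  cfg <- sim_config(p_pleio = pp, seed = 1)
  set.seed(1000 + round(100 * pp))
  graph <- sample_trait_graph(cfg)
  ds <- simulate_dataset(graph, cfg)
  truth <- true_causal_matrix(graph)
  dir <- file.path(out_root, sprintf("p_pleio_%02.0f", 100 * pp))
  write_dataset(ds, dir)
  message(sprintf(
    "p_pleio = %.1f: %d traits, %d causal edges (%d directed-path pairs), %d instruments, %d pleiotropic effects -> %s",
    pp, length(graph$trait_ids), nrow(graph$edges), sum(truth),
    nrow(graph$instruments), nrow(graph$pleiotropy), dir))
}

message("Done. Each directory holds genotypes.tsv, traits.tsv, graph.json.")
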