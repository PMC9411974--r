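#!/usr/bin/env Rscript
# Figures from the benchmark tables written by 03_benchmark.R:
# mean FDR / power / discovery counts per method and threshold, and ROC
# curves per pleiotropy level. PDFs under results/figures/.

library(ggplot2)

summary_tbl <- read.delim("results/benchmark/summary.tsv")
roc_tbl <- read.delim("results/benchmark/roc.tsv")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

summary_tbl$variant <- paste(summary_tbl$method, summary_tbl$filtered,
                             sep = " / ")
roc_tbl$variant <- paste(roc_tbl$method, roc_tbl$filtered, sep = " / ")

for (metric in c("mean_fdr", "mean_power", "mean_discoveries")) {
  p <- ggplot(summary_tbl,
              aes(x = p_pleio, y = .data[[metric]], colour = variant)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~threshold, labeller = label_both) +
    labs(x = "p_pleio", y = metric,
         title = sprintf("%s by method, filter and threshold", metric)) +
    theme_bw()
  ggsave(sprintf("results/figures/%s.pdf", metric), p,
         width = 9, height = 4)
}

p_roc <- ggplot(roc_tbl, aes(x = mean_fpr, y = mean_tpr, colour = variant)) +
  geom_path() +
  geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey50") +
  facet_wrap(~p_pleio, labeller = label_both) +
  coord_equal() +
  labs(x = "mean false positive rate", y = "mean true positive rate",
       title = "Replicate-averaged ROC curves") +
  theme_bw()
ggsave("results/figures/roc.pdf", p_roc, width = 10, height = 4)

message("Figures written under results/figures/.")
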