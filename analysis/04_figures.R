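#!/usr/bin/env Rscript
# Stage 4: boxplots of each network metric by life-history stage and sex.

library(foraynet)
suppressMessages(library(ggplot2))

bundle <- "results/synthetic-study"
metrics <- read.csv(file.path(bundle, "node_metrics.csv"))
attrs <- read_attributes(file.path(bundle, "attributes.csv"))
d <- merge(metrics, attrs, by = "individual_id")
long <- do.call(rbind, lapply(
  c("degree", "betweenness", "clustering", "unique_points"),
  function(m) data.frame(stage = d$stage, sex = d$sex, metric = m,
                         value = d[[m]])))
long <- long[!is.na(long$value), ]

p <- ggplot(long, aes(x = stage, y = value, fill = sex)) +
  geom_boxplot(outlier.size = 0.6) +
  facet_wrap(~metric, scales = "free_y") +
  labs(x = "Life history stage", y = NULL, fill = "Sex") +
  theme_bw()

dir.create("scratch", showWarnings = FALSE)
ggsave("scratch/metrics_by_stage.pdf", p, width = 8, height = 6)
cat("Figure written to scratch/metrics_by_stage.pdf\n")
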