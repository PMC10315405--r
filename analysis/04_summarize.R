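#!/usr/bin/env Rscript
# Stage 4: turn the posterior draws into the reported objects — pruned and
# relabeled patterns, modal consumption patterns, the global-allocation
# heatmap — and score them against the generative truth from stage 1.

library(rpclust)

samples <- readRDS("results/run/draws.rds")
truth <- read_truth("results/run/truth.json")
tr <- truth$spec

summ <- summarize_rpc(samples, occupancy_threshold = 0.05)
print(summ)

## persisted tables
write_modal_csv(summ, "results/run/modal_patterns.csv")
heat <- data.frame(item = rownames(summ$allocation$G), summ$allocation$G,
                   check.names = FALSE)
write.csv(heat, "results/run/allocation_heatmap.csv", row.names = FALSE)

## figures (modal-pattern map and allocation heatmap)
grDevices::png("results/run/fig_local_modal.png", 900, 500)
plot_modal_patterns(summ, scope = 1)
grDevices::dev.off()
grDevices::png("results/run/fig_allocation.png", 600, 800)
plot_allocation_heatmap(summ$allocation)
grDevices::dev.off()

## findings
cat("\n-- Findings --\n")
cat("Max posterior global-allocation probability:",
    round(max(summ$allocation$G), 3),
    "(truth nu <=", max(tr$nu_true), "- every item localizes)\n")
recov <- 0
for (s in seq_len(samples$S)) {
  truem <- apply(tr$theta1_true[s, 1, , ], 1, which.max)
  hit <- mean(summ$modal$local[[s]]$levels[1, ] == truem)
  recov <- recov + hit / samples$S
  cat(sprintf("  %-14s local patterns: %d, modal agreement with truth: %d/%d\n",
              samples$subgroups[s], summ$local[[s]]$n,
              round(hit * samples$p), samples$p))
}
cat("Mean modal recovery across subgroups:", round(100 * recov, 1), "%\n")
cat("Wrote modal_patterns.csv, allocation_heatmap.csv and figures",
    "under results/run/\n")
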