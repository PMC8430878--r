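#!/usr/bin/env Rscript
# Stage 4: longitudinal cohort statistics.
#
# Builds the three-time-point summary table from the simulated cohort,
# runs pairwise rank-sum comparisons and volume correlations, computes the
# percent changes that summarize the longitudinal shifts, and sets the
# synthetic-cohort results next to the published reference means.

suppressPackageStartupMessages(library(dceflow))

summaries <- tibble::as_tibble(read.csv("results/timepoint_summaries.csv"))
st <- cohort_table(summaries)

writeLines(st$report, "results/cohort_report.md")
write.csv(st$by_timepoint, "results/cohort_by_timepoint.csv",
          row.names = FALSE)
write.csv(st$wilcoxon, "results/cohort_wilcoxon.csv", row.names = FALSE)
write.csv(st$spearman, "results/cohort_spearman.csv", row.names = FALSE)

bt <- st$by_timepoint
pc <- data.frame(
  metric = rep(c("ktrans", "ifp", "ifv"), each = 3),
  interval = rep(c("pre->D1", "pre->D2", "D1->D2"), 3),
  simulated_pct = c(
    percent_change(bt$ktrans_mean[1], bt$ktrans_mean[2]),
    percent_change(bt$ktrans_mean[1], bt$ktrans_mean[3]),
    percent_change(bt$ktrans_mean[2], bt$ktrans_mean[3]),
    percent_change(bt$ifp_kpa_mean[1], bt$ifp_kpa_mean[2]),
    percent_change(bt$ifp_kpa_mean[1], bt$ifp_kpa_mean[3]),
    percent_change(bt$ifp_kpa_mean[2], bt$ifp_kpa_mean[3]),
    percent_change(bt$ifv_ms_mean[1], bt$ifv_ms_mean[2]),
    percent_change(bt$ifv_ms_mean[1], bt$ifv_ms_mean[3]),
    percent_change(bt$ifv_ms_mean[2], bt$ifv_ms_mean[3])))
ref <- reference_cohort_summary()
pc$reference_pct <- c(
  percent_change(ref$ktrans_mean[1], ref$ktrans_mean[2]),
  percent_change(ref$ktrans_mean[1], ref$ktrans_mean[3]),
  percent_change(ref$ktrans_mean[2], ref$ktrans_mean[3]),
  percent_change(ref$ifp_kpa_mean[1], ref$ifp_kpa_mean[2]),
  percent_change(ref$ifp_kpa_mean[1], ref$ifp_kpa_mean[3]),
  percent_change(ref$ifp_kpa_mean[2], ref$ifp_kpa_mean[3]),
  percent_change(ref$ifv_ms_mean[1], ref$ifv_ms_mean[2]),
  percent_change(ref$ifv_ms_mean[1], ref$ifv_ms_mean[3]),
  percent_change(ref$ifv_ms_mean[2], ref$ifv_ms_mean[3]))
write.csv(pc, "results/percent_changes.csv", row.names = FALSE)

cat(st$report, "\n\n")
cat("Percent changes (simulated vs reference):\n")
print(pc, digits = 3)

## figures ---------------------------------------------------------------------
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
  summaries$timepoint <- factor(summaries$timepoint,
                                levels = c("pre-TX", "D1-TX", "D2-TX"))
  for (m in c("ktrans_mean", "ifp_kpa_mean", "ifv_ms_mean")) {
    g <- ggplot(summaries, aes(x = timepoint, y = .data[[m]])) +
      geom_boxplot(outlier.shape = 1) + geom_jitter(width = 0.08, alpha = 0.6) +
      theme_minimal() + labs(x = NULL, y = m)
    ggsave(sprintf("scratch/figures/box_%s.png", m), g,
           width = 4, height = 3.2, dpi = 150)
  }
  g <- ggplot(summaries, aes(x = vt_cm3, y = ifp_kpa_mean,
                             color = timepoint)) +
    geom_point() + geom_smooth(method = "lm", se = FALSE, linewidth = 0.4) +
    theme_minimal() + labs(x = "tumor volume (cm^3)", y = "mean IFP (kPa)")
  ggsave("scratch/figures/scatter_vt_ifp.png", g,
         width = 4.5, height = 3.2, dpi = 150)
  cat("Figures written under scratch/figures/\n")
}
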