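#!/usr/bin/env Rscript

# Step 3: compare the two lines on every extracted feature with
# two-sided Mann-Whitney tests, at both units of analysis (each section
# a data point, and organoid means), and draw per-group strip plots.
# Writes comparisons.csv, comparisons_by_organoid.csv and
# stripplots.pdf under results/.
#
#   Rscript analysis/03_group_comparison.R

suppressPackageStartupMessages({
  library(organoidIF)
  library(dplyr)
  library(ggplot2)
  library(tidyr)
})

features <- read_features_table("results/features.csv")
passed <- features[features$qc_pass, ]

lines <- sort(unique(passed$line_id))
stopifnot(length(lines) == 2)

by_section <- aggregate_features(passed, "section")
by_organoid <- aggregate_features(passed, "organoid")

cmp_sec <- compare_groups(by_section, lines[1], lines[2])
cmp_org <- compare_groups(by_organoid, lines[1], lines[2])
write.csv(cmp_sec, "results/comparisons.csv", row.names = FALSE)
write.csv(cmp_org, "results/comparisons_by_organoid.csv",
          row.names = FALSE)

cat("Per-section comparisons (", sum(by_section$line_id == lines[1]), "vs",
    sum(by_section$line_id == lines[2]), "sections ):\n")
print(as.data.frame(cmp_sec[, c("feature", "n_a", "n_b", "u_statistic",
                                "p_value", "direction")]),
      row.names = FALSE, digits = 4)
cat("\nOrganoid-mean comparisons:\n")
print(as.data.frame(cmp_org[, c("feature", "n_a", "n_b", "u_statistic",
                                "p_value", "direction")]),
      row.names = FALSE, digits = 4)

long <- pivot_longer(by_section,
                     cols = c(gfap_percentage, s100b_percentage,
                              tuj1_pixels, th_fragmentation,
                              nuclear_pixels),
                     names_to = "feature", values_to = "value")
p <- ggplot(long, aes(line_id, value)) +
  geom_jitter(width = 0.12, height = 0, size = 1.6, alpha = 0.7) +
  stat_summary(fun = median, geom = "crossbar", width = 0.4,
               linewidth = 0.3) +
  facet_wrap(~feature, scales = "free_y") +
  labs(x = "cell line", y = NULL,
       title = "Per-section features by line (QC-passed sections)") +
  theme_bw()
ggsave("results/stripplots.pdf", p, width = 8, height = 5.5)
cat("\nWrote results/comparisons.csv and results/stripplots.pdf\n")
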