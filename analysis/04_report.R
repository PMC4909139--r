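#!/usr/bin/env Rscript
# Reporting layer: the scatter-style table of paired changes in absolute
# (SII) and relative (CIX) inequality -- CIX multiplied by -1 here, and only
# here, so that positive means equity improved -- and the five-dot quintile
# prevalence table behind it. Usage: Rscript analysis/04_report.R

suppressPackageStartupMessages(library(stuntineq))

trends <- read.csv("results/analysis/trends.csv")
scatter <- sii_cix_change_table(trends)
write.csv(scatter, "results/analysis/sii_cix_scatter.csv", row.names = FALSE)
cat("paired inequality changes per decade (d_cix_reported = -d_cix):\n")
print(scatter, row.names = FALSE)

prev <- read.csv("results/analysis/quintile_prevalence.csv")
dots <- prev[prev$group != "national",
             c("survey_id", "group", "prevalence", "se")]
dots$prevalence <- round(dots$prevalence, 1)
dots$se <- round(dots$se, 2)
write.csv(dots, "results/analysis/quintile_dots.csv", row.names = FALSE)
cat(sprintf("\nquintile dot-chart table written (%d survey-quintile points)\n", nrow(dots)))
worst <- dots[ave(dots$prevalence, dots$survey_id, FUN = max) == dots$prevalence, ]
cat(sprintf("the poorest quintile carries the highest prevalence in %d of %d surveys\n",
            sum(worst$group == "Q1"), length(unique(dots$survey_id))))
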