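#!/usr/bin/env Rscript
# Summarize decade-scale trends: change per 10-year interval in national,
# Q1 and Q5 prevalence and in both inequality measures, with significance
# from the earliest-vs-latest test, plus Spearman correlations between
# countries' rates of decline. Usage: Rscript analysis/03_trends.R

suppressPackageStartupMessages(library(stuntineq))

trends <- read.csv("results/analysis/trends.csv")
cat("change per decade by country and indicator (stars: earliest-vs-latest test):\n")
print(trend_table(trends), row.names = FALSE)

nat <- trends[trends$indicator == "PREVALENCE_NATIONAL", ]
cat(sprintf("\n%d of %d countries show declining national stunting prevalence\n",
            sum(nat$change_per_decade < 0), nrow(nat)))
q1 <- trends[trends$indicator == "PREVALENCE_Q1", ]
q5 <- trends[trends$indicator == "PREVALENCE_Q5", ]
rel_q1 <- q1$change_per_decade
rel_q5 <- q5$change_per_decade
cat(sprintf("poorest-quintile declines: %s pp/decade; wealthiest: %s pp/decade\n",
            paste(sprintf("%.1f", rel_q1), collapse = ", "),
            paste(sprintf("%.1f", rel_q5), collapse = ", ")))

cor_path <- "results/analysis/trend_correlations.csv"
if (file.exists(cor_path)) {
  cors <- read.csv(cor_path)
  cat("\nSpearman correlations among rates of decline:\n")
  print(cors, row.names = FALSE)
}
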