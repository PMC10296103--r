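#!/usr/bin/env Rscript
# Stage 3: group comparisons for age, GIDYQ-AA, strength of attractions and
# degree of androphilia-gynephilia: one-way ANOVA with LSD post hocs, plus
# Levene, Welch, Brown-Forsythe and Games-Howell where variances differ.

suppressPackageStartupMessages(library(cortexmicro))
seed <- 1L
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(seed = seed, stages = "stats")
rows <- lapply(names(res$stats), function(v) {
  s <- res$stats[[v]]
  data.frame(variable = v,
             F = round(s$anova$F, 2), df1 = s$anova$df1,
             df2 = s$anova$df2, p = format_p(s$anova$p),
             levene_p = format_p(s$levene$p),
             welch_F = round(s$welch$F, 2),
             welch_df2 = round(s$welch$df2, 2),
             welch_p = format_p(s$welch$p),
             bf_F = round(s$brown_forsythe$F, 2),
             bf_df2 = round(s$brown_forsythe$df2, 2),
             bf_p = format_p(s$brown_forsythe$p))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/omnibus_tests.csv", row.names = FALSE)
gh <- res$stats$gidyq$games_howell
gh[c("diff", "se", "t", "df")] <- lapply(gh[c("diff", "se", "t", "df")],
                                         round, 3)
gh$p <- format_p(gh$p)
write.csv(gh, "results/gidyq_games_howell.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nGames-Howell post hocs for the GIDYQ-AA (heteroscedastic):\n")
print(gh, row.names = FALSE)
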