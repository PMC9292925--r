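#!/usr/bin/env Rscript
# Stage 2 — score the balloon task.
#
# Per subject: risk-taking RT = mean pumps x (explosions + 1) / trials, and
# the coefficient of variability COV = SD(pumps) / mean(pumps), the inverse
# index of strategic consistency. The cohort summary should sit near the
# study scale (RT mean ~4, SD ~3; COV mean ~0.46, SD ~0.13).

library(neurotrait)

sessions <- read_bart_sessions("results/data/sessions.csv")
scored <- score_cohort(sessions)

write_tsv_report(scored$scores, "results/bart_scores.tsv")
write_tsv_report(scored$summary, "results/bart_summary.tsv")

cat("Cohort behavioural summary:\n")
print(as.data.frame(scored$summary))
cat("RT-COV correlation:",
    round(cor(scored$scores$rt, scored$scores$cov), 3), "\n")
cat("Scores written to results/bart_scores.tsv\n")
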