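#!/usr/bin/env Rscript
# Missingness diagnostics and inclusion rules: recorded-day lengths,
# the proportion-missing-by-age curve (with its half-year dropout
# jumps), the burden-vs-length check for outcome-related dropout, and
# the per-month 15-missing-days tolerance that decides which diaries
# enter each representation.

library(diarystrat)

out <- "results/analysis"
cohort <- read_cohort(file.path(out, "cohort"), default_symptoms())

ld <- length_distribution(cohort)
write.csv(data.frame(child_id = names(ld$counts),
                     recorded_days = as.integer(ld$counts)),
          file.path(out, "length_distribution.csv"), row.names = FALSE)
cat(sprintf("Recorded days: median %d; %.0f%% of diaries >= 1000 days.\n",
            ld$summary$median_days, 100 * ld$summary$frac_ge_1000))

curve <- missing_fraction_by_age(cohort)
write.csv(curve, file.path(out, "missing_fraction_by_age.csv"),
          row.names = FALSE)
cat(sprintf("Missingness at age 2.5y (day 913): %.1f%%.\n",
            100 * curve$prop_missing[913]))

bl <- suppressWarnings(burden_vs_length(cohort))
write.csv(bl$table, file.path(out, "burden_vs_length.csv"),
          row.names = FALSE)
cat(sprintf("Burden-length correlation: %.3f.\n", bl$correlation))

incl <- shape_inclusion(cohort)
write.csv(incl$children, file.path(out, "inclusion.csv"), row.names = FALSE)
print(incl)
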