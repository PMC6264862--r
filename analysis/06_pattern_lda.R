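#!/usr/bin/env Rscript
# Pattern-based analysis: daily symptom-combination codes, the pattern
# vocabulary and the diary-year frequency matrix, then a 4-topic LDA
# fitted by collapsed Gibbs sampling (eta = 0.1, alpha = 50/K,
# hyperparameters updated along the chain) with the top-5 patterns per
# topic.

library(diarystrat)

out <- "results/analysis"
cohort <- read_cohort(file.path(out, "cohort"), default_symptoms())
incl <- pattern_inclusion(cohort)

vocab <- build_vocabulary(cohort, incl)
F_mat <- build_frequency_matrix(cohort, vocab, incl)
write.csv(vocab, file.path(out, "pattern_vocabulary.csv"),
          row.names = FALSE)
write.csv(cbind(diary_year = rownames(F_mat),
                as.data.frame(F_mat, check.names = FALSE)),
          file.path(out, "frequency_matrix.csv"), row.names = FALSE)
cat(sprintf("%d distinct patterns over %d diary-years (of 2^10 = 1024 possible).\n",
            nrow(vocab), nrow(F_mat)))

cfg <- lda_config(K = 4, eta = 0.1, alpha = 50 / 4, iterations = 1500,
                  burnin = 300, thin = 10, hyper_update = TRUE, seed = 303)
fit <- fit_lda_gibbs(corpus_from_frequency(F_mat), cfg)
cat(sprintf("LDA: %d draws; hyperparameters converged to alpha %.2f, eta %.3f.\n",
            fit$n_draws, fit$alpha, fit$eta))

tt <- top_terms(fit, vocab)
write.csv(tt, file.path(out, "lda_top_terms.csv"), row.names = FALSE)
tab <- format_topic_table(tt)
write.csv(cbind(rank = rownames(tab), tab),
          file.path(out, "lda_topic_table.csv"), row.names = FALSE)
cat("Top five patterns per topic:\n")
print(tab, quote = FALSE)
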