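#!/usr/bin/env Rscript
# Render the summary report (figures + markdown) purely from the CSV
# artifacts written by the previous steps.

library(diarystrat)

out <- "results/analysis"
md <- report_run(out)
cat("Report written to", md, "\n")
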