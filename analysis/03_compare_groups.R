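#!/usr/bin/env Rscript
# Compare the measured lambda/d between the pre-branch and post-branch
# groups (two-tailed pooled-variance t-test) and quantify the surface-area
# decrease across branching. Reads results/tortuosity_records.csv written by
# 02_segment_measure.R; writes results/comparison.json.
suppressPackageStartupMessages(library(emtort))

rec <- read.csv("results/tortuosity_records.csv", stringsAsFactors = FALSE)
cmp <- compare_groups(rec$ratio[rec$group == "pre"],
                      rec$ratio[rec$group == "post"])
print(cmp)
jsonlite::write_json(unclass(cmp), "results/comparison.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nwrote results/comparison.json\n")
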