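#!/usr/bin/env Rscript

# Stage 4 — homology triage against the reference, and the novel-miRNA
# decision tree.
#
# Reported candidates are classified as known (perfect mature match at word
# size 16), iso (near-perfect mature: <=1 mismatch or <=2 nt length
# difference; or a hairpin-only hit surviving the 8-base coverage rule) or
# novel. Novel candidates then pass through the presence-based decision tree
# over stages and replicates.

library(mirstack)

cfg <- default_config(seed = 1, out_dir = file.path("results", "analysis"))
run_pipeline("homology", cfg)
run_pipeline("triage", cfg)

hom <- read_stage_tsv(file.path(cfg$out_dir, "homology.tsv"))
cat("homology labels among reported candidates:\n")
print(table(hom$label))
nt <- read_stage_tsv(file.path(cfg$out_dir, "novel_triage.tsv"))
cat("\nnovel-candidate triage verdicts:\n")
print(nt[c("id", "decision", "rule_fired")], row.names = FALSE)
cat(sprintf("\naccepted novel miRNAs: %d (sequences in novel_mirnas.fa)\n",
            sum(nt$decision == "accept")))
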