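#!/usr/bin/env Rscript

# Stage 2 — length filter, read collapsing and stringent genome mapping.
#
# Reads below 17 nt are discarded, identical sequences collapsed per library,
# and unique sequences mapped with an exact 18 nt seed, up to 2 mismatches
# after the seed, dropping reads hitting more than 5 genomic loci and keeping
# only the best alignment.

library(mirstack)

cfg <- default_config(seed = 1, out_dir = file.path("results", "analysis"))
run_pipeline("preprocess", cfg)
run_pipeline("map", cfg)

sm <- read_stage_tsv(file.path(cfg$out_dir, "mapping_summary.tsv"))
cat("per-library sequencing and mapping summary:\n")
print(sm, row.names = FALSE)
cat(sprintf("\noverall usable fraction: %.1f %%\n",
            100 * sum(sm$usable_reads) / sum(sm$total_reads)))
cat(sprintf("unique sequences mapping: %.1f %%\n",
            100 * sum(sm$unique_mapped) / sum(sm$unique_sequences)))
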