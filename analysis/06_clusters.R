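#!/usr/bin/env Rscript

# Stage 6 — tandem genomic clusters.
#
# Part A runs the <=10 kb same-strand chaining on the reported candidates of
# the synthetic study. Part B applies the same operation to the packaged
# 31-locus fly fixture and compares a duplicated-family cluster arrangement
# against a 6-member reference, the way cross-species cluster conservation
# is assessed.

library(mirstack)

cfg <- default_config(seed = 1, out_dir = file.path("results", "analysis"))
run_pipeline("clusters", cfg)
cl <- read_stage_tsv(file.path(cfg$out_dir, "clusters.tsv"))
cat("clusters among reported synthetic candidates:\n")
print(table(cl$cluster_id[!is.na(cl$cluster_id)]))

loci <- load_cluster_fixture()
det <- detect_clusters(loci, max_gap = 10000L)
cat(sprintf("\nfixture: %d loci -> %d tandem clusters\n",
            nrow(loci), nrow(det$clusters)))
print(det$clusters, row.names = FALSE)
big <- det$clusters[which.max(det$clusters$n_members), ]
cat(sprintf("largest cluster: %s, %d members, %.1f kb span\n",
            big$scaffold, big$n_members, big$span_kb))

# arrangement of the duplicated-family cluster vs a 6-member reference
bdo309 <- det$members[det$members$scaffold == "scaffold00054", ]
dme309 <- data.frame(
  id = c("dme-mir-309", "dme-mir-3", "dme-mir-286", "dme-mir-4",
         "dme-mir-5", "dme-mir-6"),
  start = c(100L, 300L, 500L, 700L, 900L, 1100L), strand = "+")
cat(sprintf("arrangement of the mir-309-type cluster vs reference: %s\n",
            compare_arrangement(bdo309, dme309)))
let7_a <- det$members[det$members$scaffold == "scaffold00010", ]
let7_b <- data.frame(id = c("dme-mir-100", "dme-let-7", "dme-mir-125"),
                     start = c(10L, 150L, 280L), strand = "+")
cat(sprintf("arrangement of the let-7 complex vs reference: %s\n",
            compare_arrangement(let7_a, let7_b)))
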