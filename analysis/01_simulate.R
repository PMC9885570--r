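#!/usr/bin/env Rscript
# Generate the stated-world synthetic drug-gene dataset: 382 drugs across a
# 9,490-gene universe, 720 target genes and 9,233 sensitive genes of which
# 463 are both, with zeta-tailed gene-side degrees in each layer and
# rank-reversal coupling between the two degree sequences on shared genes.
# Writes the on-disk dialects the pipeline readers consume.

library(druglandscape)

spec <- synthetic_spec(seed = 20260918L)
landscape <- generate_landscape(spec)
paths <- write_landscape(landscape, "results/synthetic")

p <- landscape$truth$partition
cat(sprintf("planted landscape: %d target pairs, %d sensitive pairs\n",
            nrow(landscape$target$table$pairs),
            nrow(landscape$signature$planted_calls)))
cat(sprintf("planted partition: DTG %d, DSG %d, DTSG %d\n",
            length(p$DTG), length(p$DSG), length(p$DTSG)))
cat(sprintf("files: %s\n", paste(paths, collapse = ", ")))
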