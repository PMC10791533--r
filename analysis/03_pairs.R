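#!/usr/bin/env Rscript
# Stage 3: actual and potential parent pairs under the random-mating null.
#
# For every offspring whose mother and sire are both genotyped: one actual
# row, plus one potential row for each reproductively aged genotyped male
# co-resident with the mother within +/-15 days of the conception date
# (birth date minus 228 days).

suppressMessages(library(kinavoid))

records <- read_residency("results/data/residency.tsv")
parentage <- read_parentage("results/data/parentage.tsv", records)
rel <- read_relatedness("results/relatedness.tsv")

pairs <- build_pair_table(parentage, records, relatedness_lookup(rel),
                          window_days = 15L)
write_pairs(pairs, "results/pairs.tsv")

n_act <- sum(pairs$pair_kind == "actual")
cat(sprintf("pair table: %d rows (%d actual, %d potential) over %d offspring\n",
            nrow(pairs), n_act, nrow(pairs) - n_act,
            length(unique(pairs$offspring_id))))
print(aggregate(relatedness ~ natality + pair_kind, pairs, mean))
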