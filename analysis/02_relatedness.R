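#!/usr/bin/env Rscript
# Stage 2: site filters, pairwise relatedness by Jacquard EM, and validation
# against the pedigree.
#
# Allele frequencies and the missingness/Hardy-Weinberg/MAF filters use the
# reference panel only, so the focal community's kin structure does not leak
# into the frequency estimates. Relatedness is then estimated for every
# mother-male pair the parent-pair analysis needs, plus a pedigree-labelled
# validation set.

suppressMessages(library(kinavoid))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

records <- read_residency("results/data/residency.tsv")
parentage <- read_parentage("results/data/parentage.tsv", records)
gl <- read_beagle("results/data/gl.beagle.gz")
panel_gl <- read_beagle("results/data/panel.beagle.gz")
freqs <- read_freqs("results/data/freqs.tsv")
ped_obs <- read_pedigree("results/data/pedigree.tsv")

keep <- site_filters(panel_gl, freqs, min_ind_frac = 0.9, hwe_alpha = 0.001,
                     maf_min = 0.05)
cat(sprintf("site filters: %d of %d sites retained\n", length(keep),
            length(gl$sites)))
gl_f <- gl_subset(gl, sites = keep)

# pairs needed downstream: mother x (actual sire + potential sires)
needed <- required_pairs(parentage, records, window_days = 15L)
cat(sprintf("estimating relatedness for %d mother-male pairs\n", nrow(needed)))
rel <- relatedness_table(gl_f, freqs[keep], pairs = needed, seed = seed)
write_relatedness(rel, "results/relatedness.tsv")

# validation against the observable pedigree: labelled relative pairs
lp <- sample_labelled_pairs(ped_obs, gl$ids, per_class = 40L, seed = seed + 1L)
rel_val <- relatedness_table(gl_f, freqs[keep], pairs = lp[, c("a", "b")],
                             seed = seed + 2L)
val <- validate_against_pedigree(rel_val, ped_obs)
cat(sprintf("pedigree validation: R^2 = %.3f, slope = %.3f, intercept = %.4f over %d pairs\n",
            val$r_squared, val$slope, val$intercept, val$n_pairs))
write.table(val$data, "results/validation_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# cryptic relatives: pairs unlinked on the pedigree with genetic r in 0.1-0.35
cryptic <- find_cryptic_pairs(rbind(rel[, c("a", "b", "r")],
                                    rel_val[, c("a", "b", "r")]), ped_obs)
cat(sprintf("cryptic relative pairs flagged (genetic r in 0.10-0.35, no pedigree link): %d\n",
            nrow(cryptic)))
write.table(cryptic, "results/cryptic_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
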