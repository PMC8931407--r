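#!/usr/bin/env Rscript
# Step 2: apply the standard pre-filters. The fungal view is restricted to
# ASVs positively classified as Fungi; both views then lose singletons
# (total count <= 1) and, for the network stage, low-prevalence ASVs
# (< 10% prevalence or present in fewer than 3 samples).

suppressPackageStartupMessages(library(pairnet))

meta <- read.delim("results/data/metadata.tsv")
a <- read_count_table("results/data/counts_A.tsv", metadata = meta,
                      taxonomy = read.delim("results/data/taxonomy_A.tsv"))
b <- read_count_table("results/data/counts_B.tsv", metadata = meta,
                      taxonomy = read.delim("results/data/taxonomy_B.tsv"))

b <- filter_by_taxonomy(b, "Kingdom", keep_values = "Fungi")
cat("fungal view after Kingdom filter:", n_asvs(b), "ASVs\n")

a1 <- remove_singletons(a)
b1 <- remove_singletons(b)
cat(sprintf("singleton removal: A %d -> %d, B %d -> %d ASVs\n",
            n_asvs(a), n_asvs(a1), n_asvs(b), n_asvs(b1)))

a2 <- filter_low_prevalence(a1)
b2 <- filter_low_prevalence(b1)
cat(sprintf("prevalence filter (<10%% or <3 samples): A %d -> %d, B %d -> %d\n",
            n_asvs(a1), n_asvs(a2), n_asvs(b1), n_asvs(b2)))

dir.create("results/filtered", showWarnings = FALSE, recursive = TRUE)
write_count_table(a1, "results/filtered/counts_A_diversity.tsv")
write_count_table(b1, "results/filtered/counts_B_diversity.tsv")
write_count_table(a2, "results/filtered/counts_A_network.tsv")
write_count_table(b2, "results/filtered/counts_B_network.tsv")
cat("wrote results/filtered/\n")
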