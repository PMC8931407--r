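#!/usr/bin/env Rscript
# Step 1: generate the synthetic paired survey the rest of the workflow
# analyses — 17 samples (9 marine, 3 brackish, 5 limnic), a 120-ASV
# eukaryote view and a 60-ASV fungal view over the same samples, three
# planted co-occurrence modules per view, and one cross-view module pair
# coupled at r = 0.8 (the planted "host-parasite" signal).

suppressPackageStartupMessages(library(pairnet))

seed <- 20260918
cfg <- simulation_config(seed = seed)
sim <- simulate_paired_dataset(cfg)

out <- "results/data"
write_simulation(sim, out)

cat("wrote", out, ":", n_samples(sim$a), "samples;",
    n_asvs(sim$a), "eukaryote ASVs,", n_asvs(sim$b), "fungal-view ASVs\n")
cat("planted modules A:", paste(cfg$module_sizes_A, collapse = "/"),
    " B:", paste(cfg$module_sizes_B, collapse = "/"),
    " coupling: A1~B1 r=0.8\n")
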