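#!/usr/bin/env Rscript
# Step 4: within-view co-occurrence structure. SparCC correlations on the
# prevalence-filtered tables, unsigned adjacency, topological overlap,
# dynamic tree cut (deepSplit 2, minModuleSize 5), module eigenprofiles
# and memberships — independently for the eukaryote and fungal views.

suppressPackageStartupMessages(library(pairnet))

meta <- read.delim("results/data/metadata.tsv")
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
seed <- 20260918

for (view in c("A", "B")) {
  ct <- read_count_table(sprintf("results/filtered/counts_%s_network.tsv",
                                 view), metadata = meta)
  rho <- sparcc(ct, seed = seed + match(view, c("A", "B")))
  write.table(data.frame(asv_id = rownames(rho), unclass(rho),
                         check.names = FALSE),
              sprintf("results/networks/sparcc_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tom <- tom_similarity(adjacency_from_correlation(rho))
  part <- detect_modules(tom, deep_split = 2, min_module_size = 5)
  sizes <- table(part$labels[part$labels > 0])
  cat(sprintf("[%s] %d taxa -> %d modules (sizes %s), %d unassigned\n",
              view, n_asvs(ct), length(sizes),
              paste(as.integer(sizes), collapse = "/"),
              sum(part$labels == 0)))

  ep <- module_eigenprofiles(ct, part)
  cat(sprintf("[%s] variance explained: %s\n", view,
              paste(names(ep$variance_explained),
                    round(ep$variance_explained, 2),
                    sep = "=", collapse = ", ")))

  write.table(data.frame(asv_id = names(part$labels),
                         module = unname(part$labels)),
              sprintf("results/networks/partition_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(ep$eigenprofiles),
                         ep$eigenprofiles, check.names = FALSE),
              sprintf("results/networks/eigenprofiles_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(asv_id = names(ep$membership),
                         membership = unname(ep$membership)),
              sprintf("results/networks/membership_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/networks/\n")
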