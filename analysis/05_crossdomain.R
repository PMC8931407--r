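#!/usr/bin/env Rscript
# Step 5: link the two views. Spearman correlations between module
# eigenprofiles across views, ASV-pair product scores
# (rho_module x MM_a x MM_b), thresholded edge lists (0.5 for the core
# network, 0.2 for the display superset) and a Cytoscape-loadable GraphML.

suppressPackageStartupMessages(library(pairnet))

read_ep <- function(view) {
  e <- read.delim(sprintf("results/networks/eigenprofiles_%s.tsv", view),
                  check.names = FALSE)
  em <- as.matrix(e[, -1])
  rownames(em) <- e$sample_id
  part <- read.delim(sprintf("results/networks/partition_%s.tsv", view))
  mm <- read.delim(sprintf("results/networks/membership_%s.tsv", view))
  structure(list(eigenprofiles = em,
                 partition = setNames(part$module, part$asv_id),
                 membership = setNames(mm$membership, mm$asv_id),
                 variance_explained = NULL, transform = "clr"),
            class = "eigenprofile_set")
}

ep_a <- read_ep("A")
ep_b <- read_ep("B")
mc <- module_correlations(ep_a, ep_b)
mc <- mc[order(-abs(mc$rho)), ]
cat("strongest module pairs:\n")
print(head(mc, 5), digits = 2, row.names = FALSE)

edges <- asv_pair_scores(mc, ep_a, ep_b)
dir.create("results/crossdomain", showWarnings = FALSE, recursive = TRUE)
write.table(mc, "results/crossdomain/module_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tax_a <- read.delim("results/data/taxonomy_A.tsv")
tax_b <- read.delim("results/data/taxonomy_B.tsv")
for (thr in c(0.5, 0.2)) {
  kept <- filter_and_export(edges, threshold = thr,
                            path = sprintf("results/crossdomain/edges_%s.tsv",
                                           gsub("\\.", "", thr)))
  filter_and_export(edges, threshold = thr, format = "graphml",
                    path = sprintf("results/crossdomain/network_%s.graphml",
                                   gsub("\\.", "", thr)),
                    taxonomy_a = tax_a, taxonomy_b = tax_b)
  cat(sprintf("threshold %.1f: %d of %d ASV pairs retained\n",
              thr, nrow(kept), nrow(edges)))
}
cat("wrote results/crossdomain/\n")
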