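#!/usr/bin/env Rscript
# Step 3: community structure. Alpha diversity per sample (richness,
# Shannon, Pielou; no rarefaction), Bray-Curtis dissimilarity on relative
# abundances, NMDS ordination, and one-way PERMANOVA by habitat with
# Bonferroni-adjusted pairwise follow-ups.

suppressPackageStartupMessages(library(pairnet))

meta <- read.delim("results/data/metadata.tsv")
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

for (view in c("A", "B")) {
  ct <- read_count_table(sprintf("results/filtered/counts_%s_diversity.tsv",
                                 view), metadata = meta)
  alpha <- alpha_diversity(ct)
  alpha$habitat <- meta$habitat[match(alpha$sample_id, meta$sample_id)]
  write.table(alpha, sprintf("results/diversity/alpha_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] mean richness by habitat: %s\n", view,
              paste(names(tapply(alpha$richness, alpha$habitat, mean)),
                    round(tapply(alpha$richness, alpha$habitat, mean), 1),
                    collapse = ", ", sep = "=")))

  d <- bray_curtis(ct)
  write.table(data.frame(sample_id = rownames(d), d, check.names = FALSE),
              sprintf("results/diversity/bray_curtis_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ord <- nmds(d, seed = 71)
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates,
                         habitat = meta$habitat[match(rownames(ord$coordinates),
                                                      meta$sample_id)]),
              sprintf("results/diversity/nmds_%s.tsv", view),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] NMDS stress: %.4f\n", view, ord$stress))

  g <- setNames(meta$habitat, meta$sample_id)
  fit <- permanova(d, g, n_permutations = 999, seed = 72)
  pw <- pairwise_permanova(d, g, n_permutations = 999, seed = 73)
  cat(sprintf("[%s] PERMANOVA habitat: F = %.2f, R2 = %.2f, p = %.3f\n",
              view, fit$pseudo_F, fit$R2, fit$p_value))
  print(pw, digits = 3)
  jsonlite::write_json(
    list(overall = fit[c("pseudo_F", "R2", "p_value", "n_permutations")],
         pairwise = pw),
    sprintf("results/diversity/permanova_%s.json", view),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
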