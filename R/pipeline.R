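#' Run the full cross-domain co-occurrence pipeline on a paired dataset
#'
#' Executes, for two ASV tables over shared samples, the whole analysis
#' chain: optional taxonomy restriction of table B (e.g. keep only ASVs
#' classified as Fungi), singleton removal, prevalence filtering
#' (< `min_prevalence` or present in < `min_samples` samples removed),
#' sample alignment, SparCC correlation inference per dataset, conversion
#' to adjacency and TOM, dynamic-tree-cut module detection per dataset,
#' module eigenprofiles and memberships, cross-domain module Spearman
#' correlations, and the ASV-pair product score. Modules are detected per
#' dataset (the two views' ASV sets are disjoint, so a pmin consensus TOM
#' is undefined across them; [consensus_tom()] is available for matched
#' node sets). Fully deterministic given `seed`.
#'
#' @param table_a,table_b [count_table()]s sharing >= 3 samples
#' @param keep_rank,keep_taxa optional taxonomy filter applied to
#'   `table_b` first (e.g. `"Kingdom"`, `"Fungi"`)
#' @param min_prevalence,min_samples prevalence filter parameters
#'   (defaults 0.10 and 3)
#' @param n_dirichlet,exclusion_threshold,max_exclusion_rounds SparCC
#'   parameters, see [sparcc()]
#' @param adjacency_mode,beta correlation-to-adjacency parameters
#' @param deep_split,min_module_size dynamic tree cut parameters
#'   (defaults 2 and 5)
#' @param edge_threshold weight threshold for the exported network
#'   (default 0.5)
#' @param threshold_mode `"absolute"` or `"positive"`
#' @param seed integer master seed; stage seeds are derived from it
#' @param out_dir if non-`NULL`, writes partition/eigenprofile/membership
#'   TSVs, the module correlation table, full and thresholded edge lists,
#'   a GraphML network and a run-manifest JSON into this directory
#' @return list with the filtered tables, correlation matrices,
#'   partitions, eigenprofile sets, `module_correlations`, `edges` (all
#'   scored pairs) and `edges_kept` (thresholded)
#' @export
run_pipeline <- function(table_a, table_b,
                         keep_rank = NULL, keep_taxa = NULL,
                         min_prevalence = 0.10, min_samples = 3,
                         n_dirichlet = 20, exclusion_threshold = 0.1,
                         max_exclusion_rounds = 10,
                         adjacency_mode = "unsigned", beta = 1,
                         deep_split = 2, min_module_size = 5,
                         edge_threshold = 0.5,
                         threshold_mode = "absolute",
                         seed = 1, out_dir = NULL) {
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  if (!is.null(keep_rank)) {
    table_b <- filter_by_taxonomy(table_b, keep_rank, keep_values = keep_taxa)
    log_stage("taxonomy", "table B restricted to %s=%s: %d ASVs",
              keep_rank, paste(keep_taxa, collapse = ","), n_asvs(table_b))
  }
  prep <- function(t, label) {
    t1 <- remove_singletons(t)
    t2 <- filter_low_prevalence(t1, min_prevalence, min_samples)
    log_stage("filter", "%s: %d -> %d (singletons) -> %d (prevalence) ASVs",
              label, n_asvs(t), n_asvs(t1), n_asvs(t2))
    t2
  }
  table_a <- prep(table_a, "A")
  table_b <- prep(table_b, "B")
  al <- align_samples(table_a, table_b)
  log_stage("align", "%d shared samples", n_samples(al$a))

  analyse_view <- function(t, label, stage_seed) {
    rho <- sparcc(t, n_dirichlet = n_dirichlet,
                  exclusion_threshold = exclusion_threshold,
                  max_exclusion_rounds = max_exclusion_rounds,
                  seed = stage_seed)
    tom <- tom_similarity(adjacency_from_correlation(rho, adjacency_mode,
                                                     beta))
    part <- detect_modules(tom, deep_split = deep_split,
                           min_module_size = min_module_size)
    log_stage("modules", "%s: %d modules (%d taxa unassigned)", label,
              length(unique(part$labels[part$labels > 0])),
              sum(part$labels == 0))
    ep <- module_eigenprofiles(t, part)
    list(rho = rho, tom = tom, partition = part, eigenprofiles = ep)
  }
  va <- analyse_view(al$a, "A", .child_seed(seed, 1))
  vb <- analyse_view(al$b, "B", .child_seed(seed, 2))

  mc <- module_correlations(va$eigenprofiles, vb$eigenprofiles)
  edges <- asv_pair_scores(mc, va$eigenprofiles, vb$eigenprofiles)
  kept <- filter_and_export(edges, threshold = edge_threshold,
                            mode = threshold_mode)
  log_stage("crossnet", "%d module pairs, %d ASV pairs, %d edges > %.2f",
            nrow(mc), nrow(edges), nrow(kept), edge_threshold)

  result <- list(table_a = al$a, table_b = al$b,
                 rho_a = va$rho, rho_b = vb$rho,
                 partition_a = va$partition, partition_b = vb$partition,
                 eigenprofiles_a = va$eigenprofiles,
                 eigenprofiles_b = vb$eigenprofiles,
                 module_correlations = mc,
                 edges = edges, edges_kept = kept, seed = seed)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir,
                                                 edge_threshold,
                                                 threshold_mode)
  result
}

.write_pipeline_outputs <- function(res, out_dir, edge_threshold,
                                    threshold_mode) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  for (v in c("a", "b")) {
    part <- res[[paste0("partition_", v)]]$labels
    wt(data.frame(asv_id = names(part), module = unname(part)),
       sprintf("partition_%s.tsv", toupper(v)))
    ep <- res[[paste0("eigenprofiles_", v)]]
    wt(data.frame(sample_id = rownames(ep$eigenprofiles),
                  ep$eigenprofiles, check.names = FALSE),
       sprintf("eigenprofiles_%s.tsv", toupper(v)))
    wt(data.frame(asv_id = names(ep$membership),
                  membership = unname(ep$membership)),
       sprintf("membership_%s.tsv", toupper(v)))
  }
  wt(res$module_correlations, "module_correlations.tsv")
  wt(res$edges, "edges_all.tsv")
  wt(res$edges_kept, "edges_kept.tsv")
  filter_and_export(res$edges, threshold = edge_threshold,
                    mode = threshold_mode, format = "graphml",
                    path = file.path(out_dir, "network.graphml"),
                    taxonomy_a = res$table_a$taxonomy,
                    taxonomy_b = res$table_b$taxonomy)
  manifest <- list(seed = res$seed,
                   n_samples = n_samples(res$table_a),
                   n_asvs_a = n_asvs(res$table_a),
                   n_asvs_b = n_asvs(res$table_b),
                   n_modules_a = length(unique(
                     res$partition_a$labels[res$partition_a$labels > 0])),
                   n_modules_b = length(unique(
                     res$partition_b$labels[res$partition_b$labels > 0])),
                   edge_threshold = edge_threshold,
                   threshold_mode = threshold_mode,
                   n_edges_kept = nrow(res$edges_kept))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
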