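#' Spearman correlations between module eigenprofiles of two datasets
#'
#' The two marker-gene views stay independent up to this point; here every
#' module pair's eigenprofiles are rank-correlated over the shared samples
#' (average ranks for ties), giving the module-level co-occurrence map.
#'
#' @param ep_a,ep_b `eigenprofile_set`s (see [module_eigenprofiles()])
#'   whose eigenprofiles share at least `min_shared` samples
#' @param min_shared minimum shared samples (default 5)
#' @return data.frame with columns `module_a`, `module_b`, `rho`, `n`
#' @export
module_correlations <- function(ep_a, ep_b, min_shared = 5) {
  ea <- ep_a$eigenprofiles
  eb <- ep_b$eigenprofiles
  shared <- intersect(rownames(ea), rownames(eb))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared samples (need >= ", min_shared, ")")
  ea <- ea[shared, , drop = FALSE]
  eb <- eb[shared, , drop = FALSE]
  if (any(apply(ea, 2, stats::sd) == 0) || any(apply(eb, 2, stats::sd) == 0))
    stop("constant eigenprofile")
  rho <- stats::cor(ea, eb, method = "spearman")
  out <- expand.grid(module_a = colnames(ea), module_b = colnames(eb),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- as.vector(rho)
  out$n <- length(shared)
  out
}

#' Cross-domain ASV-pair association scores
#'
#' The ASV-level rule linking taxa across the two views: for
#' every ASV i in module M of dataset A and ASV j in module N of dataset
#' B, `weight = rho_MN * MM_i * MM_j` — the between-module Spearman
#' correlation damped by both module memberships. Within each module pair
#' the strongest edge therefore joins the two highest-membership ASVs, and
#' weights decay with decreasing membership. Unassigned taxa (label 0) are
#' excluded.
#'
#' @param mc module correlation table from [module_correlations()]
#' @param ep_a,ep_b the `eigenprofile_set`s (supplying partitions and
#'   memberships)
#' @return data.frame of class `cross_domain_edges`: `asv_a`, `asv_b`,
#'   `module_a`, `module_b`, `module_rho`, `mm_a`, `mm_b`, `weight`
#' @export
asv_pair_scores <- function(mc, ep_a, ep_b) {
  part_a <- ep_a$partition[ep_a$partition > 0]
  part_b <- ep_b$partition[ep_b$partition > 0]
  if (any(is.na(ep_a$membership[names(part_a)])) ||
      any(is.na(ep_b$membership[names(part_b)])))
    stop("taxon with missing module membership")
  rows <- vector("list", nrow(mc))
  for (r in seq_len(nrow(mc))) {
    ma <- as.integer(sub("^ME", "", mc$module_a[r]))
    mb <- as.integer(sub("^ME", "", mc$module_b[r]))
    ia <- names(part_a)[part_a == ma]
    ib <- names(part_b)[part_b == mb]
    if (!length(ia) || !length(ib)) next
    g <- expand.grid(asv_a = ia, asv_b = ib, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    g$module_a <- mc$module_a[r]
    g$module_b <- mc$module_b[r]
    g$module_rho <- mc$rho[r]
    g$mm_a <- unname(ep_a$membership[g$asv_a])
    g$mm_b <- unname(ep_b$membership[g$asv_b])
    g$weight <- g$module_rho * g$mm_a * g$mm_b
    rows[[r]] <- g
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(asv_a = character(0), asv_b = character(0),
                      module_a = character(0), module_b = character(0),
                      module_rho = numeric(0), mm_a = numeric(0),
                      mm_b = numeric(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cross_domain_edges", "data.frame")
  out
}

#' Threshold and export the cross-domain network
#'
#' Retains edges with `|weight| > threshold` (`mode = "absolute"`, the
#' default) or `weight > threshold` (`mode = "positive"`), and writes the
#' network as a plain edge TSV and/or GraphML loadable by Cytoscape.
#' Nodes are annotated with their dataset of origin, module label and
#' (when provided) a taxonomy string.
#'
#' @param edges a `cross_domain_edges` table from [asv_pair_scores()]
#' @param threshold weight threshold in \[0, 1\] (default 0.5; the
#'   companion display threshold 0.2 yields a superset)
#' @param mode `"absolute"` or `"positive"`
#' @param format `"edge_tsv"` or `"graphml"`
#' @param path output file; `NULL` returns the filtered table only
#' @param taxonomy_a,taxonomy_b optional data.frames with `asv_id` plus
#'   lineage columns used to annotate nodes
#' @return the filtered edge table, invisibly when writing
#' @export
filter_and_export <- function(edges, threshold = 0.5,
                              mode = c("absolute", "positive"),
                              format = c("edge_tsv", "graphml"),
                              path = NULL,
                              taxonomy_a = NULL, taxonomy_b = NULL) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  keep <- if (mode == "absolute") abs(edges$weight) > threshold
          else edges$weight > threshold
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (is.null(path)) return(kept)
  if (format == "edge_tsv") {
    utils::write.table(kept, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- .edges_to_igraph(kept, taxonomy_a, taxonomy_b)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(kept)
}

.lineage_string <- function(tax, ids) {
  if (is.null(tax)) return(rep(NA_character_, length(ids)))
  ranks <- setdiff(names(tax), "asv_id")
  idx <- match(ids, tax$asv_id)
  vapply(idx, function(i) {
    if (is.na(i)) return(NA_character_)
    v <- unlist(tax[i, ranks, drop = TRUE])
    paste(v[!is.na(v) & v != ""], collapse = ";")
  }, character(1))
}

.edges_to_igraph <- function(kept, taxonomy_a, taxonomy_b) {
  na <- unique(kept$asv_a)
  nb <- unique(kept$asv_b)
  nodes <- data.frame(
    name = c(na, nb),
    dataset = c(rep("A", length(na)), rep("B", length(nb))),
    module = c(kept$module_a[match(na, kept$asv_a)],
               kept$module_b[match(nb, kept$asv_b)]),
    taxonomy = c(.lineage_string(taxonomy_a, na),
                 .lineage_string(taxonomy_b, nb)),
    stringsAsFactors = FALSE)
  nodes$taxonomy[is.na(nodes$taxonomy)] <- ""
  el <- data.frame(from = kept$asv_a, to = kept$asv_b,
                   weight = kept$weight, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
}
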