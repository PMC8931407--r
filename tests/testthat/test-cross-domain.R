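make_ep <- function(prefix, n = 10, modules = 2, seed = 1) {
  set.seed(seed)
  e <- matrix(rnorm(n * modules), n, modules,
              dimnames = list(sprintf("S%02d", 1:n),
                              paste0("ME", seq_len(modules))))
  taxa <- paste0(prefix, "_t", 1:(3 * modules))
  part <- setNames(rep(seq_len(modules), each = 3), taxa)
  mm <- setNames(runif(length(taxa)), taxa)
  ep_stub(e, part, mm)
}

test_that("module correlations are Spearman over shared samples", {
  ep_a <- make_ep("A", seed = 1)
  ep_b <- make_ep("B", seed = 2)
  ep_b$eigenprofiles[, 1] <- ep_a$eigenprofiles[, 1]          # identical
  ep_b$eigenprofiles[, 2] <- -ep_a$eigenprofiles[, 2]         # reversed
  mc <- module_correlations(ep_a, ep_b)
  expect_equal(mc$rho[mc$module_a == "ME1" & mc$module_b == "ME1"], 1)
  expect_equal(mc$rho[mc$module_a == "ME2" & mc$module_b == "ME2"], -1)
  expect_equal(unique(mc$n), 10)
  expect_equal(nrow(mc), 4)

  # fewer than 5 shared samples is refused
  ep_c <- make_ep("B", n = 4, seed = 3)
  expect_error(module_correlations(ep_a, ep_c), "shared samples")
  ep_d <- make_ep("B", seed = 4)
  ep_d$eigenprofiles[, 1] <- 0
  expect_error(module_correlations(ep_a, ep_d), "constant")
})

test_that("pair scores follow the product rule exactly", {
  ep_a <- make_ep("A", seed = 5)
  ep_b <- make_ep("B", seed = 6)
  ep_a$membership[] <- c(0.9, 0.5, 0.2, 0.8, 0.6, 0.4)
  ep_b$membership[] <- c(0.5, 1.0, 0.0, 0.7, 0.3, 0.1)
  mc <- module_correlations(ep_a, ep_b)
  edges <- asv_pair_scores(mc, ep_a, ep_b)
  expect_equal(nrow(edges), 4 * 9)

  rho11 <- mc$rho[mc$module_a == "ME1" & mc$module_b == "ME1"]
  e1 <- edges[edges$asv_a == "A_t1" & edges$asv_b == "B_t1", ]
  expect_equal(e1$weight, rho11 * 0.9 * 0.5)
  # MM = 0 kills the edge
  expect_true(all(edges$weight[edges$asv_b == "B_t3"] == 0))
  # weight equals rho when both memberships are 1
  ep_a$membership[] <- 1
  ep_b$membership[] <- 1
  full <- asv_pair_scores(mc, ep_a, ep_b)
  expect_equal(full$weight, full$module_rho)
  # |weight| never exceeds |module rho|
  expect_true(all(abs(edges$weight) <= abs(edges$module_rho) + 1e-12))
})

test_that("the strongest edge in a module pair joins the max-MM ASVs", {
  for (seed in 1:10) {
    ep_a <- make_ep("A", seed = seed)
    ep_b <- make_ep("B", seed = seed + 100)
    mc <- module_correlations(ep_a, ep_b)
    edges <- asv_pair_scores(mc, ep_a, ep_b)
    for (pair in split(edges, list(edges$module_a, edges$module_b))) {
      if (!nrow(pair) || abs(pair$module_rho[1]) < 1e-12) next
      top <- pair[which.max(abs(pair$weight)), ]
      expect_equal(top$mm_a, max(pair$mm_a))
      expect_equal(top$mm_b, max(pair$mm_b))
    }
  }
})

test_that("thresholding retains |weight| > t and nests across thresholds", {
  edges <- data.frame(asv_a = paste0("A", 1:3), asv_b = paste0("B", 1:3),
                      module_a = "ME1", module_b = "ME1",
                      module_rho = 0.9, mm_a = 1, mm_b = 1,
                      weight = c(0.6, 0.45, -0.7))
  class(edges) <- c("cross_domain_edges", "data.frame")
  kept <- filter_and_export(edges, threshold = 0.5)
  expect_setequal(kept$weight, c(0.6, -0.7))
  pos <- filter_and_export(edges, threshold = 0.5, mode = "positive")
  expect_equal(pos$weight, 0.6)

  k02 <- filter_and_export(edges, threshold = 0.2)
  expect_true(all(do.call(paste, kept[1:2]) %in% do.call(paste, k02[1:2])))
  expect_error(filter_and_export(edges, threshold = 2), "threshold")
})

test_that("exports are loadable: edge TSV and GraphML, including empty nets", {
  edges <- data.frame(asv_a = c("A1", "A2"), asv_b = c("B1", "B1"),
                      module_a = "ME1", module_b = "ME2",
                      module_rho = 0.8, mm_a = c(0.9, 0.7), mm_b = 0.95,
                      weight = c(0.684, 0.532))
  class(edges) <- c("cross_domain_edges", "data.frame")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  filter_and_export(edges, threshold = 0.5, path = tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 2)

  gml <- withr::local_tempfile(fileext = ".graphml")
  tax <- data.frame(asv_id = c("A1", "A2"), Kingdom = "Eukaryota",
                    Genus = c("Navicula", "Fragilariopsis"))
  filter_and_export(edges, threshold = 0.5, format = "graphml", path = gml,
                    taxonomy_a = tax)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$dataset, c("A", "A", "B"))
  expect_true("Eukaryota;Navicula" %in% igraph::V(g)$taxonomy)

  gml0 <- withr::local_tempfile(fileext = ".graphml")
  filter_and_export(edges, threshold = 1, format = "graphml", path = gml0)
  g0 <- igraph::read_graph(gml0, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})
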