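test_that("correlation-to-adjacency follows the unsigned/signed formulas", {
  rho <- matrix(c(1, -0.6, -0.6, 1), 2, 2)
  expect_equal(adjacency_from_correlation(rho, "unsigned")[1, 2], 0.6)
  expect_equal(adjacency_from_correlation(rho, "signed")[1, 2], 0.2)
  one <- matrix(1, 2, 2)
  expect_equal(adjacency_from_correlation(one, "unsigned"), one)
  expect_equal(adjacency_from_correlation(one, "signed"), one)
  expect_equal(adjacency_from_correlation(rho, "unsigned", beta = 2)[1, 2],
               0.36)
  expect_error(adjacency_from_correlation(rho, beta = 0.5), "beta")
})

test_that("TOM matches hand evaluation and the brute-force oracle", {
  # 3 nodes: A12 = A13 = 0.5, A23 = 0
  a <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0, 0.5, 0, 1), 3, 3)
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(tom[2, 3], (0.25 + 0) / (min(0.5, 0.5) + 1 - 0))

  # no off-diagonal adjacency -> no off-diagonal overlap
  expect_equal(tom_similarity(diag(4)), diag(4))
  # complete graph -> all 1
  expect_equal(tom_similarity(matrix(1, 5, 5)), matrix(1, 5, 5))

  for (seed in 1:5) {
    a <- random_adjacency(10, seed)
    tom <- tom_similarity(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("consensus TOM is the element-wise minimum over matched nodes", {
  t1 <- random_adjacency(6, 1)
  t2 <- random_adjacency(6, 2)
  cons <- consensus_tom(list(t1, t2))
  expect_equal(cons, pmin(t1, t2))
  expect_equal(consensus_tom(list(t1, t1)), t1)
  expect_true(all(cons <= t1) && all(cons <= t2))
  t3 <- t2[1:5, 1:5]
  expect_error(consensus_tom(list(t1, t3)), "identical")
})

test_that("dynamic cut separates planted blocks and respects the size rule", {
  blocks <- matrix(0.05, 20, 20)
  blocks[1:10, 1:10] <- 0.9
  blocks[11:20, 11:20] <- 0.9
  diag(blocks) <- 1
  dimnames(blocks) <- list(paste0("t", 1:20), paste0("t", 1:20))
  part <- detect_modules(blocks)
  truth <- rep(1:2, each = 10)
  expect_equal(length(unique(part$labels)), 2)
  expect_equal(adjusted_rand_index(part$labels, truth), 1)
  expect_true(all(table(part$labels[part$labels > 0]) >= 5))

  # permuting node order relabels but does not change the partition
  perm <- sample(20)
  part_p <- detect_modules(blocks[perm, perm])
  expect_equal(adjusted_rand_index(part_p$labels[paste0("t", 1:20)],
                                   part$labels), 1)

  iso <- diag(4)
  dimnames(iso) <- list(paste0("n", 1:4), paste0("n", 1:4))
  expect_warning(p0 <- detect_modules(iso, min_module_size = 5), "fewer")
  expect_true(all(p0$labels == 0))
})

test_that("eigenprofile equals the first singular vector and MM behaves", {
  set.seed(21)
  # rank-1 module: identical standardized profiles
  base <- rnorm(12)
  m <- sapply(1:5, function(i) 1e4 * 2^i * exp(base))  # proportional columns
  ct <- toy_table(m)
  labels <- setNames(rep(1L, 5), colnames(ct$counts))
  ep <- module_eigenprofiles(ct, labels, transform = "log10")
  expect_equal(unname(ep$membership), rep(1, 5), tolerance = 1e-6)
  expect_equal(ep$variance_explained[["ME1"]], 1, tolerance = 1e-6)
  expect_equal(sum(ep$eigenprofiles[, 1]^2), 1)

  # random module: agreement with a full SVD oracle, membership in [0, 1]
  ct2 <- random_table(15, 6, lambda = 50, seed = 22)
  labels2 <- setNames(rep(1L, 6), colnames(ct2$counts))
  ep2 <- module_eigenprofiles(ct2, labels2)
  xs <- scale(clr_transform(ct2$counts, 0.5))
  u1 <- svd(xs)$u[, 1]
  cosine <- abs(sum(ep2$eigenprofiles[, 1] * u1)) /
    sqrt(sum(ep2$eigenprofiles[, 1]^2) * sum(u1^2))
  expect_gte(cosine, 1 - 1e-10)
  expect_true(all(ep2$membership >= 0 & ep2$membership <= 1))
})

test_that("eigenprofile optimality: no member profile explains more variance", {
  ct <- random_table(20, 8, lambda = 40, seed = 31)
  labels <- setNames(rep(1L, 8), colnames(ct$counts))
  ep <- module_eigenprofiles(ct, labels)
  xs <- scale(clr_transform(ct$counts, 0.5))
  # variance explained by projecting members on a unit vector v is
  # sum_j cor-like squared loadings; compare eigenprofile vs each member
  total <- sum(xs^2)
  v_eig <- sum((t(xs) %*% ep$eigenprofiles[, 1])^2) / total
  for (j in seq_len(ncol(xs))) {
    vj <- xs[, j] / sqrt(sum(xs[, j]^2))
    expect_gte(v_eig + 1e-10, sum((t(xs) %*% vj)^2) / total)
  }
})

test_that("constant member profiles are dropped with MM = 0", {
  m <- cbind(matrix(rpois(24, 30), 12, 2), rep(5, 12), rep(7, 12))
  ct <- toy_table(m)
  labels <- setNames(rep(1L, 4), colnames(ct$counts))
  expect_message(ep <- module_eigenprofiles(ct, labels, transform = "log10"),
                 "constant")
  expect_equal(unname(ep$membership[c("asv3", "asv4")]), c(0, 0))
})
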