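# shared fixture builders: everything is generated in code, no data files

toy_table <- function(counts, sample_ids = NULL, asv_ids = NULL,
                      taxonomy = NULL, metadata = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  if (is.null(asv_ids)) asv_ids <- paste0("asv", seq_len(ncol(counts)))
  dimnames(counts) <- list(sample_ids, asv_ids)
  count_table(counts, metadata = metadata, taxonomy = taxonomy)
}

random_table <- function(n_samples, n_taxa, lambda = 10, seed = 1) {
  set.seed(seed)
  toy_table(matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa))
}

# symmetric random adjacency in [0, 1] with unit diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

# independent TOM oracle: literal triple loop over the formula
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# independent ARI oracle from the four pair-counts
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}

# independent PERMANOVA pseudo-F via Gower-centred trace partition
permanova_f_oracle <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  x <- stats::model.matrix(~ factor(groups) - 1)
  h <- x %*% solve(crossprod(x)) %*% t(x)
  ssb <- sum(diag(h %*% g %*% h))
  ssw <- sum(diag((diag(n) - h) %*% g %*% (diag(n) - h)))
  (ssb / (a - 1)) / (ssw / (n - a))
}

# minimal eigenprofile_set stub for cross-domain unit tests
ep_stub <- function(eigenprofiles, partition, membership) {
  structure(list(eigenprofiles = eigenprofiles, membership = membership,
                 variance_explained = NULL, partition = partition,
                 transform = "clr"),
            class = "eigenprofile_set")
}
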