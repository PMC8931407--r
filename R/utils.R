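#' Centered log-ratio transform
#'
#' Per-sample clr of a counts (or proportions) matrix after adding a
#' pseudocount; the per-sample geometric mean is divided out, so the result
#' is invariant to library size.
#'
#' @param x samples x taxa matrix, non-negative
#' @param pseudocount added before taking logs (default 0.5)
#' @return matrix of the same shape
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  stopifnot(is.matrix(x), all(x >= 0))
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to score recovery of planted modules.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @return numeric in \[-1, 1\]
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# deterministic child seed: keep within 32-bit integer range
.child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k * 7919) %% 2147483647
}
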