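#' Per-sample alpha diversity
#'
#' Observed ASV richness, Shannon diversity H (natural log) and Pielou's
#' evenness J = H / ln(richness). J is reported as `NA` for samples with a
#' single taxon. Counts are not rarefied; H is computed on each sample's
#' relative abundances, so it is depth-invariant.
#'
#' @param t a [count_table()] of counts or proportions; all samples must
#'   have a positive total.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`.
#' @export
alpha_diversity <- function(t) {
  stopifnot(inherits(t, "count_table"))
  tot <- rowSums(t$counts)
  if (any(tot <= 0))
    stop("zero-sum sample(s): ",
         paste(rownames(t$counts)[tot <= 0], collapse = ", "))
  p <- t$counts / tot
  richness <- rowSums(t$counts > 0)
  shannon <- apply(p, 1, function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  })
  pielou <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  data.frame(sample_id = rownames(t$counts), richness = richness,
             shannon = shannon, pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on relative
#' abundances so that uneven library sizes do not masquerade as community
#' differences (no rarefaction is performed anywhere in the pipeline).
#'
#' @param t a [count_table()]
#' @param relative normalise each sample to proportions first (default
#'   `TRUE`).
#' @return symmetric `dist`-convertible matrix with sample ids, zero
#'   diagonal, entries in \[0, 1\]
#' @export
bray_curtis <- function(t, relative = TRUE) {
  stopifnot(inherits(t, "count_table"))
  if (relative) t <- to_relative_abundance(t)
  d <- as.matrix(vegan::vegdist(t$counts, method = "bray"))
  dimnames(d) <- list(rownames(t$counts), rownames(t$counts))
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's NMDS (stress-1, monotone regression) on a dissimilarity
#' matrix, taking the best configuration over one metric-MDS start plus
#' `n_restarts` random starts. Deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix (as from [bray_curtis()])
#' @param k target dimension (default 2; must be < number of samples)
#' @param n_restarts random restarts in addition to the metric start
#' @param max_iter,tol iteration cap and stress convergence tolerance per
#'   start
#' @param seed integer seed
#' @return list of class `ordination_result`: `coordinates` (samples x k,
#'   centred), `stress` (Kruskal stress-1, in \[0, 1\]), `n_restarts_used`,
#'   `seed`
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, tol = 1e-6,
                 seed = 1) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples")
  dd <- stats::as.dist(d)
  set.seed(seed)
  run <- function(init) {
    fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          maxit = max_iter, smin = tol, sfgrmin = 1e-7)
    list(points = fit$points, stress = fit$stress)
  }
  # metric start; add tiny jitter so degenerate cmdscale solutions move
  cmd <- stats::cmdscale(dd, k = k)
  if (ncol(cmd) < k)
    cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), 0, 1e-4),
                             n, k - ncol(cmd)))
  best <- run(cmd)
  for (r in seq_len(n_restarts)) {
    cand <- run(matrix(stats::rnorm(n * k), n, k))
    if (cand$stress < best$stress) best <- cand
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = coords, stress = best$stress,
                 n_restarts_used = n_restarts + 1L, seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "dimensions; stress =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}

# one-way sums of squares of a squared-distance matrix given group labels:
# SST = sum_{i<j} d^2/n ; SSW = sum over groups of within-group d^2/n_g
.permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssb <- sst - ssw
  list(F = (ssb / (a - 1)) / (ssw / (n - a)), R2 = ssb / sst)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the pseudo-F statistic partitions the total squared inter-sample
#' distance between and within groups, and significance is assessed by
#' permuting sample labels. The observed statistic counts toward the null
#' set, so with m permutations the smallest attainable p is 1/(m + 1).
#' With `exact = TRUE` all n! label orderings are enumerated instead and
#' p is the exact proportion of orderings with F >= F observed.
#'
#' @param d symmetric distance matrix
#' @param grouping factor-like vector of group labels, aligned with the
#'   rows of `d` (or named by sample id)
#' @param n_permutations number of random permutations (default 999)
#' @param seed integer seed for the permutations
#' @param exact enumerate all permutations (only feasible for small n)
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `variable`
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = 1,
                      exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(grouping)) && !is.null(rownames(d)))
    grouping <- grouping[rownames(d)]
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match samples")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  d2 <- d^2
  obs <- .permanova_f(d2, grouping)
  if (exact) {
    perms <- .all_permutations(n)
    fs <- vapply(seq_len(nrow(perms)),
                 function(i) .permanova_f(d2, grouping[perms[i, ]])$F,
                 numeric(1))
    p <- mean(fs >= obs$F - 1e-12)
    m <- nrow(perms)
  } else {
    set.seed(seed)
    fs <- vapply(seq_len(n_permutations),
                 function(i) .permanova_f(d2, grouping[sample.int(n)])$F,
                 numeric(1))
    p <- (1 + sum(fs >= obs$F - 1e-12)) / (1 + n_permutations)
    m <- n_permutations
  }
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p_value = p,
                 n_permutations = m, variable = deparse(substitute(grouping))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

.all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))  # prefix k, relabel the rest to skip k
  }))
}

#' Pairwise PERMANOVA with Bonferroni adjustment
#'
#' Reruns [permanova()] on every pair of groups' sub-distance-matrix and
#' Bonferroni-adjusts the raw p-values by the number of pairs (capped at
#' 1), the usual post hoc follow-up to a significant overall test.
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adjusted`
#' @export
pairwise_permanova <- function(d, grouping, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  if (!is.null(names(grouping)) && !is.null(rownames(d)))
    grouping <- grouping[rownames(d)]
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    keep <- grouping %in% pairs[, j]
    fit <- permanova(d[keep, keep, drop = FALSE], grouping[keep],
                     n_permutations = n_permutations,
                     seed = .child_seed(seed, j))
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               pseudo_F = fit$pseudo_F, R2 = fit$R2, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * ncol(pairs))
  out
}
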