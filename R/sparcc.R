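#' Log-ratio variance matrix
#'
#' T_ij = sample variance (n - 1 denominator) of log(f_i / f_j) across
#' samples — the compositionally well-defined dispersion statistic SparCC
#' is built on. Computed from the log-fraction covariance matrix C as
#' T_ij = C_ii + C_jj - 2 C_ij.
#'
#' @param fractions samples x taxa matrix, strictly positive rows on the
#'   simplex (e.g. a Dirichlet resample of counts)
#' @return symmetric taxa x taxa matrix with zero diagonal
#' @export
log_ratio_variance <- function(fractions) {
  if (nrow(fractions) < 2) stop("need at least 2 samples")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  cv <- stats::cov(log(fractions))
  v <- diag(cv)
  tm <- outer(v, v, "+") - 2 * cv
  tm[tm < 0] <- 0  # numerical noise
  diag(tm) <- 0
  dimnames(tm) <- list(colnames(fractions), colnames(fractions))
  tm
}

#' Solve for basis variances and correlations (SparCC linear system)
#'
#' Under the sparsity assumption (most taxa uncorrelated) the row sums of
#' the log-ratio variance matrix T are linear in the unknown basis
#' variances omega: sum_{j != i} T_ij ~= (d - 1) omega_i + sum_{j != i}
#' omega_j. Pairs flagged as strongly correlated are excluded: their T
#' entry is dropped from both rows and the coefficient matrix adjusted
#' accordingly. Correlations follow as
#' rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i omega_j)),
#' clipped to \[-1, 1\].
#'
#' @param tm log-ratio variance matrix from [log_ratio_variance()]
#' @param excluded_pairs 2-column integer matrix of taxon index pairs whose
#'   equations are removed (may be `NULL`)
#' @return list with `omega` (basis variances; non-positive solutions are
#'   clipped to 1e-6 with a warning) and `rho` (correlation matrix, unit
#'   diagonal)
#' @export
basis_correlations <- function(tm, excluded_pairs = NULL) {
  d <- nrow(tm)
  if (d < 4) stop("basis system needs at least 4 taxa")
  m <- matrix(1, d, d)
  diag(m) <- d - 1
  tvec <- rowSums(tm)
  if (!is.null(excluded_pairs) && nrow(excluded_pairs)) {
    for (r in seq_len(nrow(excluded_pairs))) {
      i <- excluded_pairs[r, 1]; j <- excluded_pairs[r, 2]
      m[i, i] <- m[i, i] - 1
      m[j, j] <- m[j, j] - 1
      m[i, j] <- m[j, i] <- 0
      tvec[i] <- tvec[i] - tm[i, j]
      tvec[j] <- tvec[j] - tm[i, j]
    }
  }
  omega <- tryCatch(solve(m, tvec), error = function(e)
    stop("basis variance system is singular"))
  if (any(omega <= 0)) {
    warning(sum(omega <= 0), " non-positive basis variance(s) clipped")
    omega[omega <= 0] <- 1e-6
  }
  rho <- (outer(omega, omega, "+") - tm) / (2 * sqrt(outer(omega, omega)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(tm)
  list(omega = omega, rho = rho)
}

# one SparCC estimate from a single fraction matrix: iterative exclusion
# of the strongest pair per round, as in the original sequential scheme
.sparcc_once <- function(fractions, exclusion_threshold, max_rounds) {
  tm <- log_ratio_variance(fractions)
  d <- nrow(tm)
  excluded <- matrix(integer(0), 0, 2)
  fit <- basis_correlations(tm)
  for (round in seq_len(max_rounds)) {
    cand <- abs(fit$rho)
    diag(cand) <- 0
    if (nrow(excluded)) cand[excluded] <- 0
    cand[lower.tri(cand)] <- 0
    top <- arrayInd(which.max(cand), dim(cand))
    if (cand[top] <= exclusion_threshold) break
    excluded <- rbind(excluded, top)  # rows always i < j
    refit <- tryCatch(basis_correlations(tm, excluded), error = identity)
    if (inherits(refit, "error")) break  # over-excluded: keep previous fit
    fit <- refit
  }
  fit$rho
}

#' SparCC correlation inference from a count table
#'
#' Estimates taxon-taxon basis correlations from compositional counts:
#' for each of `n_dirichlet` resamples, per-sample fractions are drawn
#' from Dirichlet(counts + 1); per resample the basis-variance system is
#' solved with iterative exclusion of the strongest correlated pair above
#' `exclusion_threshold` (up to `max_exclusion_rounds` rounds, one pair
#' per round); the final estimate is the element-wise median across
#' resamples. Deterministic given `seed`.
#'
#' @param t a [count_table()] with at least 4 taxa and 2 samples; all-zero
#'   taxa must be filtered out beforehand
#' @param n_dirichlet number of Dirichlet resamples (default 20)
#' @param exclusion_threshold |rho| above which a pair's equations are
#'   excluded from the basis system (default 0.1)
#' @param max_exclusion_rounds exclusion iterations per resample
#' @param seed integer seed
#' @return symmetric correlation matrix of class `sparcc_correlation`
#'   (taxa x taxa, unit diagonal, entries in \[-1, 1\])
#' @export
sparcc <- function(t, n_dirichlet = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, seed = 1) {
  stopifnot(inherits(t, "count_table"))
  counts <- t$counts
  if (ncol(counts) < 4) stop("SparCC needs at least 4 taxa")
  if (nrow(counts) < 2) stop("SparCC needs at least 2 samples")
  if (any(colSums(counts) == 0))
    stop("all-zero taxa present; filter them out first")
  set.seed(seed)
  d <- ncol(counts)
  estimates <- array(NA_real_, c(d, d, n_dirichlet))
  for (b in seq_len(n_dirichlet)) {
    g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
                nrow(counts), d)
    fractions <- g / rowSums(g)
    dimnames(fractions) <- dimnames(counts)
    estimates[, , b] <- .sparcc_once(fractions, exclusion_threshold,
                                     max_exclusion_rounds)
  }
  rho <- apply(estimates, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(rho, class = c("sparcc_correlation", "matrix", "array"))
}

#' @export
print.sparcc_correlation <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat("SparCC correlations: ", nrow(x), " taxa; |rho| median ",
      format(stats::median(abs(off)), digits = 3), ", max ",
      format(max(abs(off)), digits = 3), "\n", sep = "")
  invisible(x)
}
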