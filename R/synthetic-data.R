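#' Configuration for the paired synthetic amplicon generator
#'
#' Describes the "stated world" the generator emulates: a small survey
#' (default 17 samples in 3 habitat groups, as in a benthic transect of 9
#' marine, 3 brackish and 5 limnic sites), two marker-gene views over
#' disjoint ASV sets sharing all samples, compositional counts of fixed
#' sequencing depth, planted co-occurring modules within each view, and
#' latent coupling between selected module pairs across the views (the
#' host-parasite structure the downstream network analysis must recover).
#'
#' @param n_samples total number of samples; must equal the sum of
#'   `habitat_sizes`.
#' @param habitat_sizes named integer vector, samples per habitat group.
#' @param n_taxa_A,n_taxa_B taxa per view (module members + background).
#' @param module_sizes_A,module_sizes_B integer vectors of planted module
#'   sizes; their sum must not exceed the view's taxon count.
#' @param coupling list of `c(module_A, module_B, r)` triples: the latent
#'   factors of module `module_A` (view A) and `module_B` (view B) are
#'   drawn bivariate normal with correlation `r` (|r| <= 1). A module may
#'   appear in at most one coupling.
#' @param within_module_corr target pairwise correlation of member latent
#'   log-abundances within a module, in (0, 1).
#' @param depth sequencing depth: every sample's counts sum to `depth`.
#' @param dispersion SD of the log-scale stochastic part of each taxon's
#'   abundance (factor + noise are scaled to this SD).
#' @param habitat_effect SD of per-taxon habitat offsets applied to
#'   *background* taxa (module members are habitat-neutral so that module
#'   coupling is governed by `coupling` alone).
#' @param seed integer seed; all randomness derives from it.
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_samples = 17,
                              habitat_sizes = c(marine = 9, brackish = 3,
                                                limnic = 5),
                              n_taxa_A = 120, n_taxa_B = 60,
                              module_sizes_A = c(12, 10, 10),
                              module_sizes_B = c(10, 8, 6),
                              coupling = list(c(1, 1, 0.8)),
                              within_module_corr = 0.8,
                              depth = 5000,
                              dispersion = 1,
                              habitat_effect = 1,
                              seed = 1) {
  if (sum(habitat_sizes) != n_samples)
    stop("`habitat_sizes` must sum to `n_samples`")
  if (depth <= 0) stop("`depth` must be positive")
  if (within_module_corr <= 0 || within_module_corr >= 1)
    stop("`within_module_corr` must be in (0, 1)")
  if (sum(module_sizes_A) > n_taxa_A || sum(module_sizes_B) > n_taxa_B)
    stop("module sizes exceed the view's taxon count")
  if (any(module_sizes_A < 2) || any(module_sizes_B < 2))
    stop("modules need at least 2 members")
  for (cp in coupling) {
    if (length(cp) != 3 || abs(cp[3]) > 1)
      stop("each coupling is c(module_A, module_B, r) with |r| <= 1")
    if (cp[1] > length(module_sizes_A) || cp[2] > length(module_sizes_B))
      stop("coupling refers to a module that does not exist")
  }
  if (length(coupling)) {
    if (anyDuplicated(vapply(coupling, `[`, 0, 1)) ||
        anyDuplicated(vapply(coupling, `[`, 0, 2)))
      stop("a module may appear in at most one coupling")
  }
  structure(list(n_samples = n_samples, habitat_sizes = habitat_sizes,
                 n_taxa_A = n_taxa_A, n_taxa_B = n_taxa_B,
                 module_sizes_A = module_sizes_A,
                 module_sizes_B = module_sizes_B,
                 coupling = coupling,
                 within_module_corr = within_module_corr,
                 depth = depth, dispersion = dispersion,
                 habitat_effect = habitat_effect, seed = seed),
            class = "simulation_config")
}

#' Simulate a paired amplicon dataset with planted structure
#'
#' Latent model: each planted module m has one standard-normal factor per
#' sample; a member's log-abundance is `loading * factor + noise` with
#' `loading = sqrt(within_module_corr)`, so member pairs have latent
#' correlation `within_module_corr`. Coupled module pairs draw their
#' factors from a bivariate normal with the configured correlation;
#' all other factors and all background taxa are independent. Background
#' taxa additionally carry per-taxon habitat offsets (mean shifts), which
#' is what the ordination/PERMANOVA stage sees as habitat structure.
#' Counts are multinomial draws of size `depth` from the softmax-closed
#' exponentiated latents, so every sample row sums exactly to `depth`.
#'
#' @param config a [simulation_config()]
#' @return list with elements `a`, `b` (two [count_table()]s over disjoint
#'   taxon sets and identical samples/metadata) and `truth`: the planted
#'   partitions (`partition_a`, `partition_b`; 0 = background), the
#'   per-sample module factor matrices (`latents_a`, `latents_b`) and
#'   `coupled_pairs`.
#' @export
simulate_paired_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples

  habitat <- rep(names(config$habitat_sizes), config$habitat_sizes)
  sample_ids <- sprintf("S%02d", seq_len(n))
  sample_type <- sample(c("biofilm", "sediment", "water"), n, replace = TRUE,
                        prob = c(10, 5, 2) / 17)
  metadata <- data.frame(sample_id = sample_ids, habitat = habitat,
                         sample_type = sample_type,
                         stringsAsFactors = FALSE)

  # coupled module factors first, so both views share them
  ka <- length(config$module_sizes_A)
  kb <- length(config$module_sizes_B)
  fac_a <- matrix(stats::rnorm(n * ka), n, ka)
  fac_b <- matrix(stats::rnorm(n * kb), n, kb)
  for (cp in config$coupling) {
    r <- cp[3]
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    fac_a[, cp[1]] <- z1
    fac_b[, cp[2]] <- z2
  }

  gen_view <- function(prefix, n_taxa, module_sizes, factors) {
    part <- integer(n_taxa)
    idx <- 1
    for (m in seq_along(module_sizes)) {
      part[idx:(idx + module_sizes[m] - 1)] <- m
      idx <- idx + module_sizes[m]
    }
    ids <- sprintf("%s_ASV%03d", prefix, seq_len(n_taxa))
    names(part) <- ids

    a <- sqrt(config$within_module_corr)
    mu <- stats::rnorm(n_taxa, 0, 1)          # per-taxon baseline
    lat <- matrix(stats::rnorm(n * n_taxa), n, n_taxa)  # iid noise
    for (j in seq_len(n_taxa)) {
      m <- part[j]
      if (m > 0) {
        lat[, j] <- a * factors[, m] + sqrt(1 - a^2) * lat[, j]
      } else {
        # habitat mean shifts for background taxa only
        off <- stats::rnorm(length(config$habitat_sizes), 0,
                            config$habitat_effect)
        names(off) <- names(config$habitat_sizes)
        lat[, j] <- lat[, j] + off[habitat]
      }
    }
    logab <- sweep(config$dispersion * lat, 2, mu, "+")
    counts <- t(vapply(seq_len(n), function(i) {
      p <- exp(logab[i, ] - max(logab[i, ]))
      as.numeric(stats::rmultinom(1, config$depth, p / sum(p)))
    }, numeric(n_taxa)))
    dimnames(counts) <- list(sample_ids, ids)
    list(counts = counts, partition = part)
  }

  va <- gen_view("A", config$n_taxa_A, config$module_sizes_A, fac_a)
  vb <- gen_view("B", config$n_taxa_B, config$module_sizes_B, fac_b)

  tax_a <- data.frame(asv_id = colnames(va$counts), Kingdom = "Eukaryota",
                      stringsAsFactors = FALSE)
  tax_b <- data.frame(asv_id = colnames(vb$counts), Kingdom = "Fungi",
                      stringsAsFactors = FALSE)
  colnames(fac_a) <- paste0("A", seq_len(ka))
  colnames(fac_b) <- paste0("B", seq_len(kb))
  rownames(fac_a) <- rownames(fac_b) <- sample_ids

  list(a = count_table(va$counts, metadata, tax_a),
       b = count_table(vb$counts, metadata, tax_b),
       truth = list(partition_a = va$partition, partition_b = vb$partition,
                    latents_a = fac_a, latents_b = fac_b,
                    coupled_pairs = config$coupling))
}

#' Simulate compositional counts from known basis correlations
#'
#' Test harness for correlation-recovery experiments: log basis abundances
#' are multivariate normal with covariance
#' `diag(sqrt(basis_var)) %*% basis_corr %*% diag(sqrt(basis_var))`,
#' fractions are obtained by closure and counts by a multinomial draw of
#' size `depth` per sample, mirroring the generative model SparCC assumes.
#'
#' @param basis_corr symmetric positive semi-definite correlation matrix
#'   with unit diagonal.
#' @param basis_var positive basis variances (recycled if length 1).
#' @param n_samples,depth samples and reads per sample.
#' @param seed integer seed.
#' @param mean_log per-taxon mean log basis abundance (default 0).
#' @return a [count_table()]; the latent log-abundance matrix is attached
#'   as attribute `"latents"` for recovery tests.
#' @export
simulate_from_basis_correlations <- function(basis_corr, basis_var = 1,
                                             n_samples, depth, seed = 1,
                                             mean_log = 0) {
  d <- nrow(basis_corr)
  if (!isTRUE(all.equal(basis_corr, t(basis_corr), tolerance = 1e-8)) ||
      !isTRUE(all.equal(diag(basis_corr), rep(1, d), tolerance = 1e-8)))
    stop("`basis_corr` must be symmetric with unit diagonal")
  if (depth <= 0) stop("`depth` must be positive")
  basis_var <- rep_len(basis_var, d)
  sigma <- diag(sqrt(basis_var)) %*% basis_corr %*% diag(sqrt(basis_var))
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("`basis_corr` is not positive semi-definite")
  set.seed(seed)
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  logab <- sweep(z %*% t(root), 2, rep_len(mean_log, d), "+")
  counts <- t(vapply(seq_len(n_samples), function(i) {
    p <- exp(logab[i, ] - max(logab[i, ]))
    as.numeric(stats::rmultinom(1, depth, p / sum(p)))
  }, numeric(d)))
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                           sprintf("ASV%03d", seq_len(d)))
  dimnames(logab) <- dimnames(counts)
  out <- count_table(counts)
  attr(out, "latents") <- logab
  out
}

#' Write a simulated paired dataset to a directory
#'
#' Emits the two count tables (taxa as rows), taxonomy and metadata TSVs,
#' and the ground truth as JSON.
#'
#' @param sim result of [simulate_paired_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$a, file.path(dir, "counts_A.tsv"),
                    file.path(dir, "taxonomy_A.tsv"),
                    file.path(dir, "metadata.tsv"))
  write_count_table(sim$b, file.path(dir, "counts_B.tsv"),
                    file.path(dir, "taxonomy_B.tsv"))
  truth <- sim$truth
  truth$latents_a <- NULL
  truth$latents_b <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
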