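#' Correlation to adjacency
#'
#' Unsigned: A_ij = |rho_ij|^beta; signed: A_ij = ((1 + rho_ij)/2)^beta.
#' The default (unsigned, beta = 1) treats strong negative co-exclusion
#' like strong co-occurrence; no soft-threshold selection is performed.
#'
#' @param rho correlation matrix (unit diagonal, entries in \[-1, 1\])
#' @param mode `"unsigned"` or `"signed"`
#' @param beta soft-threshold power, >= 1
#' @return adjacency matrix in \[0, 1\] with unit diagonal
#' @export
adjacency_from_correlation <- function(rho, mode = c("unsigned", "signed"),
                                       beta = 1) {
  mode <- match.arg(mode)
  if (beta < 1) stop("`beta` must be >= 1")
  rho <- unclass(rho)
  a <- if (mode == "unsigned") abs(rho)^beta else ((1 + rho) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_{u != i,j} A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)
#' with connectivity k_i = sum_{u != i} A_iu: nodes are similar when they
#' are directly connected *and* share neighbours. Diagonal is set to 1;
#' 1 - TOM is the clustering dissimilarity.
#'
#' @param a symmetric adjacency matrix, entries in \[0, 1\], unit diagonal
#' @return TOM matrix in \[0, 1\]
#' @export
tom_similarity <- function(a) {
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must be in [0, 1]")
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0            # shared-neighbour sum includes no i,j terms
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Consensus TOM by parallel minimum
#'
#' Element-wise minimum of several TOMs over an identical, identically
#' ordered node set: the conservative shared topology. Note this is only
#' defined when the node sets match; TOMs of datasets with disjoint ASV
#' sets cannot be combined this way.
#'
#' @param toms list of >= 2 TOM matrices with identical dimnames
#' @return consensus TOM matrix
#' @export
consensus_tom <- function(toms) {
  if (length(toms) < 2) stop("need at least 2 TOMs")
  ref <- dimnames(toms[[1]])
  for (tm in toms[-1]) {
    if (!identical(dim(tm), dim(toms[[1]])) ||
        !identical(dimnames(tm), ref))
      stop("TOMs must share an identical, identically ordered node set")
  }
  Reduce(pmin, toms)
}

# ---- dynamic tree cut (tree-shape variant) --------------------------------

# node table from an hclust merge matrix: children, height, leaf members
.hc_nodes <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    get <- function(x) if (x < 0) -x else members[[x]]
    members[[i]] <- c(get(hc$merge[i, 1]), get(hc$merge[i, 2]))
  }
  members
}

# Branch-isolation module search. A branch (internal node) qualifies as a
# module candidate when it is large enough, compact (its top merge height
# h sits low in the height distribution, unlike gradually chaining
# background branches that top out near the cut) and "hangs isolated":
# the vertical gap between h and the height p at which the branch joins
# the rest of the tree is a large fraction of the room left above it,
# (min(p, cut) - h) / (cut - h) >= r_min. A candidate is accepted when it
# contains at most one other accepted branch (the larger one wins), so a
# tight core nested in a looser module does not shatter it; a branch
# spanning two or more accepted sub-branches is split instead. Maximal
# accepted branches become the modules. Returns a list of integer
# leaf-index vectors.
.module_branches <- function(hc, members, min_size, r_min, cut_height) {
  n_int <- length(hc$height)
  parent <- rep(NA_integer_, n_int)
  for (i in seq_len(n_int))
    for (x in hc$merge[i, ]) if (x > 0) parent[x] <- i
  h <- hc$height
  p <- pmin(ifelse(is.na(parent), Inf, h[pmax(parent, 1L)]), cut_height)
  size <- lengths(members)
  h_low <- stats::quantile(h, 0.05, names = FALSE)
  compact <- h <= h_low + 0.9 * (cut_height - h_low)
  qualifies <- size >= min_size & h < cut_height & compact &
    (p - h) >= r_min * (cut_height - h)
  # hclust guarantees child index < parent index: one ascending pass.
  # m[i] counts the accepted module roots inside subtree i.
  m <- integer(n_int)
  accepted <- logical(n_int)
  for (i in seq_len(n_int)) {
    inner <- 0L
    for (x in hc$merge[i, ]) if (x > 0) inner <- inner + m[x]
    accepted[i] <- qualifies[i] && inner <= 1L
    m[i] <- if (accepted[i]) 1L else inner
  }
  final <- logical(n_int)
  for (i in rev(seq_len(n_int))) {    # descending: ancestors first
    if (!accepted[i]) next
    j <- parent[i]
    covered <- FALSE
    while (!is.na(j)) {
      if (final[j]) { covered <- TRUE; break }
      j <- parent[j]
    }
    final[i] <- !covered
  }
  members[final]
}

#' Detect co-occurrence modules from a TOM
#'
#' Average-linkage hierarchical clustering of 1 - TOM followed by a
#' dynamic tree-shape cut. Merges above `cut_height` (default 0.99 of the
#' maximum merge height) are discarded; below it, a branch is accepted as
#' a module when it is large enough and clearly isolated from the rest of
#' the tree: the vertical gap between the branch's top merge and the
#' height at which it joins its surroundings must exceed a fraction
#' `r_min` of the room left above the branch. `deep_split` (0..4,
#' conservative to aggressive) maps to `r_min` = 0.50/0.40/0.30/0.22/0.15.
#' A branch spanning two or more qualifying sub-branches is split into
#' them; a branch containing at most one is kept whole. Taxa under no
#' qualifying branch, and branches smaller than `min_module_size`, are
#' left unassigned (label 0); modules are renumbered by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()] (or any similarity in
#'   \[0, 1\] with unit diagonal)
#' @param deep_split split sensitivity, integer 0..4 (default 2)
#' @param min_module_size smallest allowed module (default 5, >= 2)
#' @param cut_height static cut height; `NULL` for 0.99 x max merge height
#' @return list of class `module_partition`: `labels` (named integer
#'   vector, 0 = unassigned), `dendrogram` (the `hclust` object),
#'   `parameters`
#' @export
detect_modules <- function(tom, deep_split = 2, min_module_size = 5,
                           cut_height = NULL) {
  stopifnot(deep_split %in% 0:4, min_module_size >= 2)
  ids <- rownames(tom)
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer nodes than `min_module_size`: all unassigned")
    labels <- stats::setNames(integer(n), ids)
    return(structure(list(labels = labels, dendrogram = NULL,
                          parameters = list(deep_split = deep_split,
                                            min_module_size = min_module_size)),
                     class = "module_partition"))
  }
  diss <- 1 - tom
  diag(diss) <- 0
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  maxh <- max(hc$height)
  if (is.null(cut_height)) cut_height <- 0.99 * maxh
  r_min <- c(0.50, 0.40, 0.30, 0.22, 0.15)[deep_split + 1]

  labels <- stats::setNames(integer(n), ids)
  if (maxh <= 0) {
    labels[] <- 1L  # all distances zero: one module
  } else {
    members <- .hc_nodes(hc)
    clusters <- .module_branches(hc, members, min_module_size, r_min,
                                 cut_height)
    for (k in seq_along(order(lengths(clusters), decreasing = TRUE))) {
      ci <- order(lengths(clusters), decreasing = TRUE)[k]
      labels[clusters[[ci]]] <- k
    }
  }
  structure(list(labels = labels, dendrogram = hc,
                 parameters = list(deep_split = deep_split,
                                   min_module_size = min_module_size,
                                   cut_height = cut_height)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat("module partition: ", length(tab), " modules over ",
      length(x$labels), " taxa (", sum(x$labels == 0), " unassigned)\n",
      sep = "")
  if (length(tab))
    cat("  sizes:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Module eigenprofiles and module membership
#'
#' For each module, member abundance profiles are transformed (default:
#' centred log-ratio with pseudocount 0.5 on counts) and standardised per
#' taxon; the module eigenprofile is the first left singular vector of the
#' samples x members matrix — the module's representative per-sample
#' abundance profile (the "eigengene" of weighted correlation network
#' analysis). Its sign is oriented so the mean correlation with member
#' profiles is positive. Module membership of a taxon is the absolute
#' Pearson correlation between its standardised profile and its module's
#' eigenprofile, in \[0, 1\].
#'
#' @param t a [count_table()] covering the partition's taxa, >= 3 samples
#' @param partition a `module_partition` (or named integer vector);
#'   label 0 = unassigned, excluded
#' @param transform `"clr"` (default) or `"log10"` (log10(x + 0.5))
#' @return list of class `eigenprofile_set`: `eigenprofiles` (samples x
#'   modules, unit-norm columns), `membership` (named vector over assigned
#'   taxa), `variance_explained` (per module), `partition`
#' @export
module_eigenprofiles <- function(t, partition, transform = c("clr", "log10")) {
  stopifnot(inherits(t, "count_table"))
  transform <- match.arg(transform)
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  if (!all(names(labels) %in% colnames(t$counts)))
    stop("partition contains taxa absent from the count table")
  if (nrow(t$counts) < 3) stop("need at least 3 samples")

  x <- t$counts[, names(labels), drop = FALSE]
  xt <- if (transform == "clr") clr_transform(x, 0.5) else log10(x + 0.5)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("partition has no assigned modules")

  eig <- matrix(NA_real_, nrow(xt), length(mods),
                dimnames = list(rownames(xt), paste0("ME", mods)))
  varexp <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  mm <- stats::setNames(rep(NA_real_, sum(labels > 0)),
                        names(labels)[labels > 0])
  for (k in seq_along(mods)) {
    mem <- names(labels)[labels == mods[k]]
    if (length(mem) < 2) stop("module ", mods[k], " has fewer than 2 members")
    xm <- xt[, mem, drop = FALSE]
    sds <- apply(xm, 2, stats::sd)
    if (any(sds == 0)) {
      message("dropping ", sum(sds == 0), " constant profile(s) in module ",
              mods[k])
      mm[mem[sds == 0]] <- 0
      mem <- mem[sds > 0]
      xm <- xm[, mem, drop = FALSE]
    }
    xs <- scale(xm)
    sv <- svd(xs)
    u1 <- sv$u[, 1]
    if (mean(stats::cor(xs, u1)) < 0) u1 <- -u1
    eig[, k] <- u1
    varexp[k] <- sv$d[1]^2 / sum(sv$d^2)
    mm[mem] <- abs(as.numeric(stats::cor(xs, u1)))
  }
  structure(list(eigenprofiles = eig, membership = mm,
                 variance_explained = varexp, partition = labels,
                 transform = transform),
            class = "eigenprofile_set")
}

#' @export
print.eigenprofile_set <- function(x, ...) {
  cat("eigenprofile set: ", ncol(x$eigenprofiles), " modules x ",
      nrow(x$eigenprofiles), " samples\n", sep = "")
  cat("  variance explained:",
      paste(format(x$variance_explained, digits = 2), collapse = ", "), "\n")
  invisible(x)
}
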