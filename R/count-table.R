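#' ASV count table with sample metadata and taxonomy
#'
#' The central container of the package: a samples x ASVs abundance matrix
#' together with per-sample metadata (habitat, sample type, ...) and a
#' per-ASV ranked taxonomy. Counts are non-negative; after
#' [to_relative_abundance()] they are proportions summing to 1 per sample.
#'
#' @param counts numeric matrix, samples as rows, ASVs as columns, with
#'   unique non-empty dimnames. Entries must be non-negative and finite.
#' @param metadata data.frame keyed by `sample_id` (or with row names equal
#'   to the sample ids) covering every sample; `NULL` creates a stub.
#' @param taxonomy data.frame keyed by `asv_id` with ranked lineage columns
#'   (`Kingdom` .. `Genus`, possibly partial); `NULL` creates a stub.
#'
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @export
count_table <- function(counts, metadata = NULL, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x ASVs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")

  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(counts),
                           stringsAsFactors = FALSE)
  }
  metadata <- .key_by(metadata, "sample_id", rownames(counts), "metadata")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(asv_id = colnames(counts),
                           stringsAsFactors = FALSE)
  }
  taxonomy <- .key_by(taxonomy, "asv_id", colnames(counts), "taxonomy",
                      allow_missing = TRUE)

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "count_table")
}

# align an annotation data.frame to ids; metadata must cover all samples
.key_by <- function(df, key, ids, what, allow_missing = FALSE) {
  if (!is.data.frame(df)) stop("`", what, "` must be a data.frame")
  if (!key %in% names(df)) {
    df[[key]] <- rownames(df)
  }
  if (anyDuplicated(df[[key]]))
    stop("duplicate ids in ", what)
  missing <- setdiff(ids, df[[key]])
  if (length(missing)) {
    if (!allow_missing)
      stop(what, " does not cover: ", paste(utils::head(missing, 5), collapse = ", "))
    pad <- df[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad[[key]] <- missing
    df <- rbind(df, pad)
  }
  df <- df[match(ids, df[[key]]), , drop = FALSE]
  rownames(df) <- df[[key]]
  df[c(key, setdiff(names(df), key))]
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " ASVs\n", sep = "")
  cat("  total counts:", sum(x$counts), "\n")
  extra <- setdiff(names(x$metadata), "sample_id")
  if (length(extra))
    cat("  metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Number of samples / ASVs
#' @param t a `count_table`
#' @return integer
#' @export
n_samples <- function(t) nrow(t$counts)

#' @rdname n_samples
#' @export
n_asvs <- function(t) ncol(t$counts)

# subset keeping annotations in sync
.subset_table <- function(t, samples = NULL, asvs = NULL) {
  counts <- t$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  meta <- t$metadata[match(rownames(counts), t$metadata$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  tax <- t$taxonomy[match(colnames(counts), t$taxonomy$asv_id), , drop = FALSE]
  rownames(tax) <- tax$asv_id
  structure(list(counts = counts, metadata = meta, taxonomy = tax),
            class = "count_table")
}

#' Read an ASV count table from disk
#'
#' TSV dialect: tab-separated, taxa as rows, header row of sample ids,
#' first column the ASV id (the common amplicon convention; the table is
#' transposed to samples x ASVs internally). BIOM-format files are read
#' through the biomformat package when available.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param taxa_as_rows for TSV: are taxa the rows (default `TRUE`)?
#' @param metadata,taxonomy optional annotation data.frames, see
#'   [count_table()].
#' @return a [count_table()]
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             taxa_as_rows = TRUE,
                             metadata = NULL, taxonomy = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    counts <- t(m)
  } else {
    if (file.size(path) == 0) stop("empty file: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0 || ncol(df) < 2) stop("malformed count table: ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    counts <- if (taxa_as_rows) t(m) else m
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("negative counts in ", path)
  count_table(counts, metadata = metadata, taxonomy = taxonomy)
}

#' Write a count table, taxonomy and metadata as TSV
#'
#' Counts are written taxa-as-rows with an `asv_id` first column.
#'
#' @param t a `count_table`
#' @param counts_path,taxonomy_path,metadata_path output paths (taxonomy
#'   and metadata are skipped when `NULL`).
#' @return `t`, invisibly.
#' @export
write_count_table <- function(t, counts_path, taxonomy_path = NULL,
                              metadata_path = NULL) {
  out <- data.frame(asv_id = colnames(t$counts), t(t$counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path))
    utils::write.table(t$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(t$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(t)
}

#' Remove singleton ASVs
#'
#' Drops every ASV whose total count over all samples is 0 or 1, the usual
#' pre-filter before any diversity or network analysis. Idempotent.
#'
#' @param t a `count_table` with integer counts
#' @return filtered `count_table`
#' @export
remove_singletons <- function(t) {
  stopifnot(inherits(t, "count_table"))
  keep <- colSums(t$counts) > 1
  .subset_table(t, asvs = which(keep))
}

#' Remove low-prevalence ASVs
#'
#' Prevalence is the fraction of samples in which an ASV has count > 0.
#' Under `rule = "either"` (default) an ASV is removed when its prevalence
#' is below `min_prevalence` OR it occurs in fewer than `min_samples`
#' samples; under `rule = "both"` only when it fails both criteria.
#'
#' @param t a `count_table`
#' @param min_prevalence minimum fraction of samples with a nonzero count
#'   (default 0.10).
#' @param min_samples minimum number of samples with a nonzero count
#'   (default 3).
#' @param rule `"either"` or `"both"`, see Details.
#' @return filtered `count_table`; a warning is emitted if nothing survives.
#' @export
filter_low_prevalence <- function(t, min_prevalence = 0.10, min_samples = 3,
                                  rule = c("either", "both")) {
  stopifnot(inherits(t, "count_table"))
  rule <- match.arg(rule)
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("`min_prevalence` must be in [0, 1]")
  occ <- colSums(t$counts > 0)
  prev <- occ / nrow(t$counts)
  fail_prev <- prev < min_prevalence
  fail_occ <- occ < min_samples
  drop <- if (rule == "either") fail_prev | fail_occ else fail_prev & fail_occ
  if (all(drop)) warning("no ASVs pass the prevalence filter")
  .subset_table(t, asvs = which(!drop))
}

#' Filter ASVs by taxonomy at a given rank
#'
#' Used e.g. to restrict an LSU table to ASVs positively classified as
#' Fungi. With a keep set, ASVs unclassified (NA or empty) at `rank` are
#' dropped by default; with a drop set they are retained.
#'
#' @param t a `count_table`
#' @param rank taxonomy column name, e.g. `"Kingdom"`.
#' @param keep_values,drop_values character vectors; exactly one must be
#'   given.
#' @param keep_unclassified retain ASVs unclassified at `rank` when a keep
#'   set is active (default `FALSE`).
#' @return filtered `count_table`
#' @export
filter_by_taxonomy <- function(t, rank, keep_values = NULL,
                               drop_values = NULL,
                               keep_unclassified = FALSE) {
  stopifnot(inherits(t, "count_table"))
  if (!rank %in% names(t$taxonomy))
    stop("unknown taxonomy rank: ", rank)
  if (is.null(keep_values) == is.null(drop_values))
    stop("give exactly one of `keep_values`, `drop_values`")
  val <- as.character(t$taxonomy[[rank]])
  uncl <- is.na(val) | val == ""
  if (!is.null(keep_values)) {
    keep <- !uncl & val %in% keep_values
    if (keep_unclassified) keep <- keep | uncl
  } else {
    keep <- uncl | !(val %in% drop_values)
  }
  .subset_table(t, asvs = which(keep))
}

#' Convert counts to relative abundances
#'
#' Each sample's row is divided by its total so rows sum to 1. Safe to call
#' on already-normalised data (idempotent to numerical tolerance).
#'
#' @param t a `count_table`
#' @return `count_table` of proportions
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "count_table"))
  tot <- rowSums(t$counts)
  if (any(tot <= 0))
    stop("zero-sum sample(s): ",
         paste(rownames(t$counts)[tot <= 0], collapse = ", "))
  t$counts <- t$counts / tot
  t
}

#' Restrict two tables to their shared samples
#'
#' Both tables are subset to the intersection of their sample ids, in the
#' first table's order, so that per-sample profiles can be compared across
#' the two marker-gene views.
#'
#' @param a,b `count_table`s
#' @param min_shared minimum number of shared samples (default 3).
#' @return list of the two aligned `count_table`s
#' @export
align_samples <- function(a, b, min_shared = 3) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"))
  shared <- intersect(rownames(a$counts), rownames(b$counts))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared samples (need >= ", min_shared, ")")
  list(a = .subset_table(a, samples = shared),
       b = .subset_table(b, samples = shared))
}
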