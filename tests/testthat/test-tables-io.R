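test_that("TSV round trip preserves counts and ids, errors on bad input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\tsampleA\tsampleB",
               "asv1\t5\t0", "asv2\t2\t3", "asv3\t0\t7"), tmp)
  ct <- read_count_table(tmp)
  expect_equal(unname(rowSums(ct$counts)), c(7, 10))
  expect_equal(rownames(ct$counts), c("sampleA", "sampleB"))
  expect_equal(colnames(ct$counts), c("asv1", "asv2", "asv3"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, out)
  expect_equal(read_count_table(out)$counts, ct$counts)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_count_table(empty), "empty")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\ts1\ts2", "asv1\t1\t2", "asv1\t3\t4"), dup)
  expect_error(read_count_table(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\ts1", "asv1\t-3"), neg)
  expect_error(read_count_table(neg), "negative")
})

test_that("count_table validates ids and annotation coverage", {
  m <- matrix(1:4, 2, 2)
  expect_error(count_table(m), "names")
  dimnames(m) <- list(c("s1", "s1"), c("a", "b"))
  expect_error(count_table(m), "duplicate sample")
  dimnames(m) <- list(c("s1", "s2"), c("a", "b"))
  expect_error(count_table(m, metadata = data.frame(sample_id = "s1")),
               "cover")
  ct <- count_table(m)
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct), c(2L, 2L))
})

test_that("singleton removal drops totals <= 1, keeps 2, and is idempotent", {
  ct <- toy_table(rbind(c(1, 2, 0, 0, 5),
                        c(0, 0, 0, 1, 5)))
  f <- remove_singletons(ct)
  # totals: 1 (singleton), 2 (kept), 0 (empty), 1 (singleton), 10 (kept)
  expect_equal(colnames(f$counts), c("asv2", "asv5"))
  expect_equal(f$counts, ct$counts[, c("asv2", "asv5")])
  expect_equal(remove_singletons(f)$counts, f$counts)
})

test_that("prevalence filter applies the <10% / <3 samples rules", {
  set.seed(5)
  m <- matrix(0, 17, 4)
  m[1:2, 1] <- 5        # present in 2 samples: removed (2 < 3)
  m[1:3, 2] <- 5        # present in 3 (prevalence 0.176): retained
  m[, 3] <- 1           # present everywhere: retained
  m[1, 4] <- 9          # present in 1: removed
  ct <- toy_table(m)
  f <- filter_low_prevalence(ct)
  expect_equal(colnames(f$counts), c("asv2", "asv3"))

  # under rule="both" an ASV failing only one criterion survives
  m2 <- matrix(0, 40, 2)
  m2[1:3, 1] <- 1       # 3 samples but prevalence 0.075: fails only one rule
  m2[1:2, 2] <- 1       # fails both
  both <- filter_low_prevalence(toy_table(m2), rule = "both")
  expect_equal(colnames(both$counts), "asv1")

  # degenerate thresholds are the identity
  id <- filter_low_prevalence(ct, min_prevalence = 0, min_samples = 0)
  expect_equal(id$counts, ct$counts)
  expect_warning(filter_low_prevalence(toy_table(matrix(c(1, 0), 2, 1))),
                 "no ASVs")
})

test_that("taxonomy filter keeps/drops at a rank and handles unclassified", {
  tax <- data.frame(asv_id = c("asv1", "asv2", "asv3", "asv4"),
                    Kingdom = c("Fungi", "Metazoa", "Fungi", NA))
  ct <- toy_table(matrix(1, 2, 4), taxonomy = tax)
  keep <- filter_by_taxonomy(ct, "Kingdom", keep_values = "Fungi")
  expect_equal(colnames(keep$counts), c("asv1", "asv3"))  # NA dropped
  keepu <- filter_by_taxonomy(ct, "Kingdom", keep_values = "Fungi",
                              keep_unclassified = TRUE)
  expect_equal(colnames(keepu$counts), c("asv1", "asv3", "asv4"))
  drop <- filter_by_taxonomy(ct, "Kingdom", drop_values = "Metazoa")
  expect_equal(colnames(drop$counts), c("asv1", "asv3", "asv4"))
  expect_error(filter_by_taxonomy(ct, "Phylum", keep_values = "x"),
               "unknown")
})

test_that("relative abundance normalises rows, errors on zero-sum samples", {
  ct <- toy_table(rbind(c(2, 2, 4), c(1, 0, 0)))
  r <- to_relative_abundance(ct)
  expect_equal(unname(r$counts[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(r$counts)), c(1, 1), tolerance = 1e-12)
  expect_equal(to_relative_abundance(r)$counts, r$counts, tolerance = 1e-12)
  bad <- toy_table(rbind(c(1, 1), c(0, 0)), sample_ids = c("ok", "empty"))
  expect_error(to_relative_abundance(bad), "empty")
})

test_that("sample alignment intersects ids in order and enforces a minimum", {
  a <- toy_table(matrix(1, 4, 2), sample_ids = c("A", "B", "C", "D"))
  b <- toy_table(matrix(1, 4, 3), sample_ids = c("B", "C", "D", "E"))
  al <- align_samples(a, b)
  expect_equal(rownames(al$a$counts), c("B", "C", "D"))
  expect_equal(rownames(al$b$counts), c("B", "C", "D"))
  a2 <- toy_table(matrix(1, 3, 2), sample_ids = c("A", "B", "C"))
  b2 <- toy_table(matrix(1, 3, 2), sample_ids = c("B", "C", "D"))
  expect_error(align_samples(a2, b2), "shared")
})

test_that("filters commute with sample reordering and never invent ids", {
  set.seed(9)
  ct <- random_table(10, 30, lambda = 0.7)
  perm <- sample(10)
  reord <- toy_table(ct$counts[perm, ], sample_ids = rownames(ct$counts)[perm])
  for (fun in list(remove_singletons,
                   function(x) filter_low_prevalence(x, 0.2, 2))) {
    f1 <- fun(ct)
    f2 <- fun(reord)
    expect_setequal(colnames(f1$counts), colnames(f2$counts))
    expect_true(all(colnames(f1$counts) %in% colnames(ct$counts)))
  }
})
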