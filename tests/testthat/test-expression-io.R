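test_that("expression matrix TSV round-trip preserves values, IDs and order", {
  v <- matrix(c(1, 0, 5, 2, 4, 5), nrow = 3,
              dimnames = list(c("T1", "T2", "T3"), c("s1", "s2")))
  m <- expr_matrix(v, "TPM")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  m2 <- read_expression_matrix(f, "TPM")
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_identical(expr_metric(m2), "TPM")

  set.seed(101)
  for (i in 1:20) {
    m <- rand_expr_matrix(n_tx = sample(5:80, 1), n_samples = sample(2:8, 1))
    write_expression_matrix(m, f)
    m2 <- read_expression_matrix(f, "TPM")
    # writer rounds to 6 significant digits
    expect_equal(unclass(m2), unclass(signif(unclass(m), 6L)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("matrix validation rejects duplicates, negatives and non-numerics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\ts1\ts2", "T1\t1\t2", "T1\t3\t4"), f)
  expect_error(read_expression_matrix(f, "TPM"), "T1")
  writeLines(c("transcript_id\ts1\ts2", "T1\t1\t2", "T2\t-3\t4"), f)
  expect_error(read_expression_matrix(f, "TPM"), "T2.*s1")
  writeLines(c("transcript_id\ts1\ts2", "T1\t1\tabc", "T2\t3\t4"), f)
  expect_error(read_expression_matrix(f, "TPM"), "T1.*s2")
  v <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s", "s")))
  expect_error(expr_matrix(v, "TPM"), "duplicate sample")
  v <- matrix(c(1, -1, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expr_matrix(v, "TPM"), ">= 0")
})

test_that("subsetting an expr_matrix keeps class and metric", {
  m <- rand_expr_matrix(10, 4, metric = "FPKM")
  s <- m[1:3, 1:2]
  expect_s3_class(s, "expr_matrix")
  expect_identical(expr_metric(s), "FPKM")
})

test_that("RPKM normalization matches the per-cell formula", {
  # unit case: count 10, length 1000 bp, library of exactly 1e6 reads
  v <- matrix(c(10, 999990), 2, 1, dimnames = list(c("T1", "T2"), "s1"))
  lens <- c(T1 = 1000, T2 = 500)
  r <- rpkm_normalize(expr_matrix(v, "counts"), lens)
  expect_equal(r["T1", "s1"], 10)
  expect_identical(expr_metric(r), "FPKM")

  # zero count stays zero
  v["T1", 1] <- 0
  r <- rpkm_normalize(expr_matrix(v, "counts"), lens)
  expect_equal(r["T1", "s1"], 0)

  # random matrix against a direct loop oracle
  set.seed(7)
  cm <- rand_count_matrix(50, 4)
  lens <- stats::setNames(sample(200:5000, 50), rownames(cm))
  r <- rpkm_normalize(cm, lens)
  oracle <- matrix(NA_real_, 50, 4)
  for (i in 1:50) for (j in 1:4)
    oracle[i, j] <- cm[i, j] / ((lens[i] / 1000) * (sum(unclass(cm)[, j]) / 1e6))
  expect_equal(unclass(r), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("TPM normalization yields 1e6 column sums and matches its formula", {
  # two transcripts, equal counts and lengths -> 5e5 each
  v <- matrix(c(7, 7, 3, 3), 2, 2, dimnames = list(c("T1", "T2"), c("a", "b")))
  t1 <- tpm_normalize(expr_matrix(v, "counts"), c(T1 = 100, T2 = 100))
  expect_equal(unclass(t1), matrix(5e5, 2, 2), ignore_attr = TRUE)

  # single expressed transcript takes the whole million
  v <- matrix(c(9, 0), 2, 1, dimnames = list(c("T1", "T2"), "s1"))
  t2 <- tpm_normalize(expr_matrix(v, "counts"), c(T1 = 100, T2 = 100))
  expect_equal(t2["T1", "s1"], 1e6)

  set.seed(8)
  cm <- rand_count_matrix(50, 4)
  lens <- stats::setNames(sample(200:5000, 50), rownames(cm))
  tp <- tpm_normalize(cm, lens)
  expect_equal(colSums(unclass(tp)), rep(1e6, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  oracle <- matrix(NA_real_, 50, 4)
  for (j in 1:4) {
    rate <- unclass(cm)[, j] / lens
    oracle[, j] <- rate / sum(rate) * 1e6
  }
  expect_equal(unclass(tp), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalizations commute with transcript reordering", {
  set.seed(9)
  cm <- rand_count_matrix(30, 3)
  lens <- stats::setNames(sample(500:2000, 30), rownames(cm))
  perm <- sample(30)
  pm <- expr_matrix(unclass(cm)[perm, ], "counts")
  expect_equal(unclass(tpm_normalize(pm, lens)),
               unclass(tpm_normalize(cm, lens))[perm, ], ignore_attr = TRUE)
  expect_equal(unclass(rpkm_normalize(pm, lens)),
               unclass(rpkm_normalize(cm, lens))[perm, ], ignore_attr = TRUE)
})

test_that("normalization input errors are informative", {
  cm <- rand_count_matrix(5, 2)
  lens <- stats::setNames(rep(1000, 4), rownames(cm)[1:4])
  expect_error(rpkm_normalize(cm, lens), "T005")
  v <- unclass(rand_count_matrix(5, 2))
  v[, 2] <- 0
  expect_error(
    rpkm_normalize(expr_matrix(v, "counts"),
                   stats::setNames(rep(1000, 5), rownames(v))), "s2")
  tp <- rand_expr_matrix(5, 2, metric = "TPM")
  expect_error(tpm_normalize(tp, stats::setNames(rep(1000, 5), rownames(tp))),
               "counts")
})

test_that("pathway role tables validate and round-trip", {
  p <- pathway("PW1", c(geneA = 1, geneB = -1))
  expect_identical(length(p$roles), 2L)
  expect_error(pathway("PW1", c(geneA = 0.7)), "ARR")
  expect_error(pathway("PW1", c(geneA = 1, geneA = -1)), "duplicate")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tgene_id\tARR", "PW1\tgeneA\t0.7"), f)
  expect_error(read_pathways(f), "ARR")

  set.seed(10)
  pws <- lapply(1:5, function(i)
    pathway(sprintf("PW%d", i),
            stats::setNames(sample(c(-1, -0.5, 0, 0.5, 1), 8, replace = TRUE),
                            sprintf("g%d_%d", i, 1:8))))
  names(pws) <- sprintf("PW%d", 1:5)
  write_pathways(pws, f)
  pws2 <- read_pathways(f)
  expect_identical(names(pws2), names(pws))
  for (i in seq_along(pws))
    expect_equal(pws2[[i]]$roles, pws[[i]]$roles)
})

test_that("sample designs and feature lengths round-trip", {
  d <- two_group_design(3, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_design(d, f)
  expect_equal(as.data.frame(read_sample_design(f)), as.data.frame(d))
  expect_identical(group_samples(d, "case"), sprintf("case_%d", 1:3))
  expect_error(group_samples(d, "nope"), "unknown group")

  lens <- stats::setNames(c(100, 2500), c("T1", "T2"))
  write_feature_lengths(lens, f)
  expect_equal(read_feature_lengths(f), lens)
})

test_that("stage reference files round-trip through the long TSV format", {
  sr <- simulate_stage_reference(n_transcripts = 120, n_informative = 20,
                                 seed = 5)$ref
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stage_reference(sr, f)
  sr2 <- read_stage_reference(f)
  expect_identical(ref_stages(sr2), ref_stages(sr))
  expect_identical(ref_transcripts(sr2), ref_transcripts(sr))
  expect_equal(sr2$expr$TPM, signif(sr$expr$TPM, 6L), tolerance = 1e-9)
  expect_equal(sr2$pvals$TPM, signif(sr$pvals$TPM, 6L), tolerance = 1e-9)
})
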