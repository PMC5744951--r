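test_that("Welch t-test matches the closed-form computation", {
  # identical groups: no evidence at all
  r <- welch_t_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # frozen hand computation: t = (mx - my)/sqrt(s2x/n + s2y/m),
  # Welch-Satterthwaite df, two-sided Student-t tail
  r <- welch_t_test(c(10.1, 9.8, 10.4, 10.0), c(8.2, 8.5, 7.9, 8.8))
  expect_equal(r$t, 7.48410079474363, tolerance = 1e-10)
  expect_equal(r$df, 5.1301775147929, tolerance = 1e-10)
  expect_equal(r$p, 0.000600967597515334, tolerance = 1e-10)

  # group exchange flips the sign, keeps the p-value
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 0.9, 1.4)
  r1 <- welch_t_test(a, b); r2 <- welch_t_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)

  # shift invariance: adding a constant to both groups changes nothing
  r3 <- welch_t_test(a + 17.3, b + 17.3)
  expect_equal(r3$t, r1$t, tolerance = 1e-10)
  expect_equal(r3$p, r1$p, tolerance = 1e-10)
})

test_that("Welch t-test agrees with stats::t.test on random instances", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:9, 1); m <- sample(2:9, 1)
    x <- rnorm(n, 0, runif(1, 0.5, 3))
    y <- rnorm(m, runif(1, -2, 2), runif(1, 0.5, 3))
    r <- welch_t_test(x, y)
    tt <- stats::t.test(x, y)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Welch degenerate conventions and input checks hold", {
  r <- welch_t_test(c(2, 2), c(2, 2, 2))
  expect_equal(r, list(t = 0, df = 3, p = 1, degenerate = FALSE))
  r <- welch_t_test(c(5, 5), c(2, 2, 2))
  expect_identical(r$t, Inf)
  expect_identical(r$p, 0)
  expect_true(r$degenerate)
  r <- welch_t_test(c(1, 1), c(2, 2))
  expect_identical(r$t, -Inf)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("transcript classification applies group-zero and p-value rules", {
  v <- rbind(
    sw_off  = c(0, 0, 0, 2, 3, 1),
    excl    = c(0, 0, 0, 0, 0, 0),
    sw_on   = c(1, 2, 1, 0, 0, 0),
    de      = c(10, 11, 12, 2, 2.5, 2.2),
    flat    = c(5, 5.2, 4.9, 5.1, 5, 5.05))
  colnames(v) <- c(sprintf("case_%d", 1:3), sprintf("ctrl_%d", 1:3))
  m <- expr_matrix(v, "TPM")
  det <- classify_transcripts(m, two_group_design(3, 3))
  expect_identical(det$status,
                   c("switched_off", "excluded", "switched_on", "tested",
                     "tested"))
  # t/df/p only defined for tested transcripts
  expect_true(all(is.na(det$p[det$status != "tested"])))
  expect_true(all(!is.na(det$p[det$status == "tested"])))
  expect_true(det$det[4])
  expect_false(det$det[5])
  cts <- attr(det, "counts")
  expect_identical(unname(cts), c(1L, 0L, 1L, 1L))
  expect_error(classify_transcripts(m, sample_design(colnames(v),
    c("case", "case", "case", "case", "case", "control"))), "control")
})

test_that("classification partition is exhaustive and order-stable", {
  sim <- simulate_expression(n_transcripts = 500, seed = 31)
  det <- classify_transcripts(sim$matrix, sim$design)
  expect_identical(det$transcript_id, rownames(sim$matrix))
  expect_true(all(det$status %in%
    c("tested", "switched_on", "switched_off", "excluded")))
  # up/down counts are invariant to permuting samples within groups
  perm <- c(sample(1:6), 6 + sample(1:5))
  mp <- expr_matrix(unclass(sim$matrix)[, perm], "TPM")
  det2 <- classify_transcripts(mp, sim$design)
  expect_identical(attr(det2, "counts"), attr(det, "counts"))
  expect_equal(det2$p, det$p, tolerance = 1e-12)
})

test_that("planted effects are recovered with matching direction", {
  hits <- 0; total <- 0; dir_ok <- 0; dir_tot <- 0
  for (s in 1:5) {
    sim <- simulate_expression(seed = 400 + s)
    det <- classify_transcripts(sim$matrix, sim$design)
    tl <- sim$truth$labels
    planted <- tl %in% c("up", "down")
    total <- total + sum(planted)
    hits <- hits + sum(det$det[planted])
    rec <- planted & det$det
    dir_tot <- dir_tot + sum(rec)
    dir_ok <- dir_ok + sum(sign(det$mean_case - det$mean_control)[rec] ==
                             sign(sim$truth$effect_log2[rec]))
    expect_identical(det$status[tl == "switched_on"],
                     rep("switched_on", sum(tl == "switched_on")))
    expect_identical(det$status[tl == "switched_off"],
                     rep("switched_off", sum(tl == "switched_off")))
  }
  expect_gte(hits / total, 0.8)
  expect_identical(dir_ok, dir_tot)
})

test_that("BH adjustment is available and more conservative than nominal p", {
  sim <- simulate_expression(n_transcripts = 800, seed = 32)
  d1 <- classify_transcripts(sim$matrix, sim$design)
  d2 <- classify_transcripts(sim$matrix, sim$design, p_adjust = "BH")
  expect_true(all(d2$p_adj >= d2$p - 1e-15, na.rm = TRUE))
  expect_lte(sum(d2$det), sum(d1$det))
})

test_that("sample correlation matrices behave like correlations", {
  m <- rand_expr_matrix(100, 5)
  r <- sample_correlation_matrix(m, "pearson")
  expect_equal(diag(r), stats::setNames(rep(1, 5), colnames(m)))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))

  # perfectly anti-linear samples on the raw scale
  v <- cbind(s1 = c(1, 5, 9, 2), s2 = 10 - c(1, 5, 9, 2))
  rownames(v) <- paste0("T", 1:4)
  r <- sample_correlation_matrix(expr_matrix(v, "TPM"), "pearson",
                                 log2_transform = FALSE)
  expect_equal(r["s1", "s2"], -1)
})

test_that("Spearman correlations equal the rank-then-Pearson oracle", {
  set.seed(33)
  m <- rand_expr_matrix(200, 6)
  r <- sample_correlation_matrix(m, "spearman")
  ranks <- apply(unclass(m), 2L, rank)
  oracle <- stats::cor(ranks, method = "pearson")
  expect_equal(r, oracle, tolerance = 1e-10)
})

test_that("p-value filter restricts the correlation to significant transcripts", {
  sim <- simulate_expression(n_transcripts = 600, seed = 34)
  flt <- list(design = sim$design, alpha = 0.05)
  det <- classify_transcripts(sim$matrix, sim$design)
  keep <- det$status == "tested" & !is.na(det$p) & det$p <= 0.05
  r <- sample_correlation_matrix(sim$matrix, "pearson", p_filter = flt)
  manual <- stats::cor(log2(unclass(sim$matrix)[keep, ] + 1))
  expect_equal(r, manual, tolerance = 1e-12)
})

test_that("zero-variance samples trigger a warning and NA correlations", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(2, 2, 2), s3 = c(3, 1, 0))
  rownames(v) <- paste0("T", 1:3)
  expect_warning(r <- sample_correlation_matrix(expr_matrix(v, "TPM"),
                                                "pearson"), "s2")
  expect_true(is.na(r["s1", "s2"]))
  expect_equal(r["s2", "s2"], 1)
})

test_that("classical MDS recovers planar geometry exactly", {
  # identical samples collapse to identical coordinates
  v <- cbind(s1 = c(1, 4, 2), s2 = c(1, 4, 2), s3 = c(8, 0, 3))
  rownames(v) <- paste0("T", 1:3)
  co <- classical_mds(expr_matrix(v, "TPM"), dims = 2)
  expect_lt(sqrt(sum((co["s1", ] - co["s2", ])^2)), 1e-6)
  expect_equal(colMeans(co), c(MDS1 = 0, MDS2 = 0), tolerance = 1e-12)

  # points generated exactly in a 2-D plane: distances reproduced
  set.seed(35)
  z <- matrix(rnorm(6 * 2, 0, 5), 6, 2)           # sample coordinates
  a <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))     # orthonormal embedding
  v <- 100 + a %*% t(z)                           # keep values positive
  dimnames(v) <- list(paste0("T", 1:40), paste0("s", 1:6))
  co <- classical_mds(expr_matrix(v, "TPM"), dims = 2,
                      log2_transform = FALSE)
  expect_equal(as.matrix(stats::dist(co)), as.matrix(stats::dist(z)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # orientation rule: the largest-magnitude coordinate on each axis is >= 0
  for (j in 1:2) expect_gte(co[which.max(abs(co[, j])), j], 0)
  expect_error(classical_mds(expr_matrix(v[, 1:2], "TPM"), dims = 2),
               "at least 3 samples")
})

test_that("MDS separates strongly shifted groups on the first axis", {
  sep <- 0L
  for (s in 1:20) {
    sim <- simulate_expression(n_transcripts = 400, frac_de = 0.3,
                               effect_log2 = 3, frac_switched = 0,
                               seed = 500 + s)
    co <- classical_mds(sim$matrix, dims = 2)
    grp <- sim$design$group[match(rownames(co), sim$design$sample_id)]
    lo <- range(co[grp == "case", 1]); hi <- range(co[grp == "control", 1])
    if (lo[2] < hi[1] || hi[2] < lo[1]) sep <- sep + 1L
  }
  expect_gte(sep, 19L)
})
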