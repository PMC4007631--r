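test_that("log ratios equal log2(bound/input), with missingness rules", {
  expect_equal(compute_log_ratios(matrix(4), matrix(2), max_missing = 1)[1],
               1)
  expect_equal(compute_log_ratios(matrix(7), matrix(7), max_missing = 1)[1],
               0)
  set.seed(1)
  b <- matrix(rlnorm(60), 10, 6, dimnames = list(paste0("p", 1:10), NULL))
  i <- matrix(rlnorm(60), 10, 6, dimnames = dimnames(b))
  expect_equal(compute_log_ratios(b, i), log2(b) - log2(i))

  # non-positive intensity -> missing for that array only
  b2 <- b; b2[1, 1] <- -1
  m <- compute_log_ratios(b2, i, max_missing = 0.5)
  expect_true(is.na(m[1, 1]))
  expect_false(anyNA(m[1, -1]))

  # probes missing in > 20% of arrays are dropped
  b3 <- b; b3[2, 1:3] <- 0
  expect_message(m3 <- compute_log_ratios(b3, i), "dropping 1 probe")
  expect_false("p2" %in% rownames(m3))
})

test_that("quantile normalization matches its definition and is idempotent", {
  # hand example: columns (1,3) and (2,4) both become (1.5, 3.5)
  x <- cbind(c(1, 3), c(2, 4))
  expect_equal(quantile_normalize(x), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  # identical columns are a fixed point
  y <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(y), y)

  set.seed(2)
  z <- matrix(rnorm(500), 100, 5)
  qz <- quantile_normalize(z)
  # all columns share identical sorted values, hence equal means
  sorted <- apply(qz, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE)
  expect_equal(var(colMeans(qz)), 0, tolerance = 1e-20)
  # idempotent
  expect_equal(quantile_normalize(qz), qz, tolerance = 1e-12)
  # matches the definition oracle on complete tie-free data
  expect_equal(qz, qnorm_oracle(z), tolerance = 1e-10, ignore_attr = TRUE)

  # ties get the mean of the spanned reference values
  xt <- cbind(c(1, 1, 5), c(2, 4, 6))
  qt <- quantile_normalize(xt)
  ref <- rowMeans(cbind(sort(xt[, 1]), sort(xt[, 2])))
  expect_equal(qt[, 1], c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))

  # missing values stay missing and do not disturb the other columns
  xm <- matrix(rnorm(40), 10, 4)
  xm[3, 2] <- NA
  qm <- quantile_normalize(xm)
  expect_true(is.na(qm[3, 2]))
  expect_equal(sum(is.na(qm)), 1)

  expect_error(quantile_normalize(matrix(1:5, ncol = 1)), "at least 2")
  xbad <- matrix(rnorm(20), 5, 4)
  xbad[1:4, 2] <- NA
  expect_error(quantile_normalize(xbad), "non-missing")
})

test_that("quantile normalization agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(3)
  x <- matrix(rnorm(400), 100, 4)
  expect_equal(quantile_normalize(x),
               limma::normalizeQuantiles(x, ties = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("MvA QC summarizes channel ratios and flags injected dye bias", {
  ds <- small_dataset(n_promoters = 60, n_mirnas = 6, n_cluster_blocks = 0,
                      n_dm_mirnas = 2, n_consistent_mirnas = 1,
                      n_targets_per_mirna = 5)
  # equal channels -> median M = 0; doubled bound -> median M = 1
  eq <- ds$arrays
  eq$bound <- eq$input
  qc0 <- ma_qc(eq)
  expect_equal(qc0$median_m, rep(0, nrow(qc0)))
  eq$bound <- 2 * eq$input
  expect_equal(ma_qc(eq)$median_m, rep(1, nrow(qc0)))

  # |cor(M, A)| grows with the injected dye-bias amplitude
  amps <- c(0, 0.3, 0.8)
  cors <- vapply(amps, function(a) {
    d <- small_dataset(n_promoters = 60, n_mirnas = 6, n_cluster_blocks = 0,
                       n_dm_mirnas = 2, n_consistent_mirnas = 1,
                       n_targets_per_mirna = 5, dye_bias_amplitude = a)
    mean(abs(ma_qc(d$arrays)$cor_ma))
  }, 0)
  expect_true(all(diff(cors) > 0))
  dbig <- small_dataset(n_promoters = 60, n_mirnas = 6, n_cluster_blocks = 0,
                        n_dm_mirnas = 2, n_consistent_mirnas = 1,
                        n_targets_per_mirna = 5, dye_bias_amplitude = 1.5)
  expect_true(any(ma_qc(dbig$arrays)$flagged))
})

test_that("replicate averaging is a per-individual NA-aware mean", {
  x <- rbind(c(0.2, 0.4, 0.6, 1, 1, 1),
             c(0.2, NA, 0.6, 2, 2, 2))
  dimnames(x) <- list(c("p1", "p2"), paste0("A", 1:6))
  sheet <- data.frame(array_id = paste0("A", 1:6),
                      individual_id = rep(c("I1", "I2"), each = 3))
  avg <- average_replicates(x, sheet)
  expect_equal(avg, cbind(I1 = c(0.4, 0.4), I2 = c(1, 2)),
               ignore_attr = TRUE)
  expect_equal(colnames(avg), c("I1", "I2"))

  # permuting arrays within an individual leaves the result unchanged
  perm <- c(3, 1, 2, 6, 4, 5)
  expect_equal(average_replicates(x[, perm], sheet[perm, ]), avg)

  # 120 arrays -> 40 individual columns
  ds <- small_dataset(n_promoters = 20, n_mirnas = 2, n_cluster_blocks = 0,
                      n_dm_mirnas = 1, n_consistent_mirnas = 1,
                      n_targets_per_mirna = 5)
  m <- compute_log_ratios(ds$arrays)
  expect_equal(ncol(m), 120)
  expect_equal(ncol(average_replicates(m, ds$arrays$sheet)), 40)
})

test_that("variance explained by individual matches a hand ANOVA and its limits", {
  # 3-individual toy, 2 replicates each
  x <- matrix(c(1, 1.2, 3, 3.4, 5, 5.2), nrow = 1)
  colnames(x) <- paste0("A", 1:6)
  sheet <- data.frame(array_id = paste0("A", 1:6),
                      individual_id = rep(c("I1", "I2", "I3"), each = 2))
  v <- replicate_variance_explained(x, sheet, top_k = 1)
  grand <- mean(x)
  gm <- tapply(x[1, ], sheet$individual_id, mean)
  ssb <- sum(2 * (gm - grand)^2)
  sst <- sum((x - grand)^2)
  expect_equal(v$fraction, ssb / sst)

  # replicate_sd = 0 -> all variance is between individuals
  ds0 <- small_dataset(replicate_sd = 0, n_promoters = 40, n_mirnas = 4,
                       n_cluster_blocks = 0, n_dm_mirnas = 1,
                       n_consistent_mirnas = 1, n_targets_per_mirna = 5)
  m0 <- compute_log_ratios(ds0$arrays)
  expect_equal(replicate_variance_explained(m0, ds0$arrays$sheet,
                                            top_k = 100)$fraction, 1,
               tolerance = 1e-10)

  # individual_sd = 0 -> between-individual fraction is small
  ds1 <- small_dataset(individual_sd = 0, n_promoters = 40, n_mirnas = 4,
                       n_cluster_blocks = 0, n_dm_mirnas = 0,
                       n_consistent_mirnas = 0, n_targets_per_mirna = 5,
                       fraction_dm = 0)
  m1 <- compute_log_ratios(ds1$arrays)
  expect_lt(replicate_variance_explained(m1, ds1$arrays$sheet,
                                         top_k = 100)$fraction, 0.5)

  expect_warning(replicate_variance_explained(m1, ds1$arrays$sheet,
                                              top_k = 1e6), "capped")
})
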