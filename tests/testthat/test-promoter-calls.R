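test_that("the rank-sum shift test is exact for tiny samples", {
  r <- promoter_shift_test(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$direction, "hypo")

  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(3:8, 1))
    expect_equal(promoter_shift_test(x, y)$p.value, ranksum_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(promoter_shift_test(1, rnorm(5)), ">= 2")
})

test_that("the normal-approximation path matches wilcox.test and detects extremes", {
  set.seed(8)
  y <- rnorm(200)
  for (i in 1:5) {
    x <- rnorm(10, mean = runif(1, -1, 1))
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(promoter_shift_test(x, y)$p.value, wt$p.value,
                 tolerance = 1e-10)
  }
  # promoter entirely above the background maximum: extreme significance
  x_hi <- max(y) + 1:5
  r <- promoter_shift_test(x_hi, y)
  expect_lt(r$p.value, 1e-3)
  expect_equal(r$direction, "hyper")
  # values matching the background quantiles: p near 1
  r2 <- promoter_shift_test(quantile(y, c(0.3, 0.5, 0.7, 0.2, 0.8, 0.45, 0.55,
                                          0.35, 0.65)), y)
  expect_gt(r2$p.value, 0.5)
})

test_that("the vectorized genome-wide shift scan equals per-promoter wilcox.test", {
  set.seed(9)
  tmod <- rnorm(1300)
  prom <- rep(sprintf("P%03d", 1:100), each = 13)
  bulk <- medipdm:::.shift_tests_bulk(tmod, prom)
  for (p in sample(unique(prom), 8)) {
    sel <- prom == p
    wt <- suppressWarnings(wilcox.test(tmod[sel], tmod, exact = FALSE,
                                       correct = TRUE))
    expect_equal(bulk$shift_p[bulk$promoter_id == p], wt$p.value,
                 tolerance = 1e-10)
  }
  # the slow path (promoters of unequal size) agrees with the fast path
  prom2 <- prom
  prom2[1] <- "P002"  # P001 now has 12 probes, P002 has 14
  bulk2 <- medipdm:::.shift_tests_bulk(tmod, prom2)
  for (p in c("P001", "P002", "P050")) {
    sel <- prom2 == p
    wt <- suppressWarnings(wilcox.test(tmod[sel], tmod, exact = FALSE,
                                       correct = TRUE))
    expect_equal(bulk2$shift_p[bulk2$promoter_id == p], wt$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH follows the step-up definition and its monotonicity", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("two-tier promoter calls require both the probe and the FDR tier", {
  probe_stats <- data.frame(
    probe_id = paste0("pb", 1:6),
    promoter_id = rep(c("A", "B", "C"), each = 2),
    p = c(0.01, 0.5, 0.02, 0.6, 0.5, 0.9),
    beta = c(0.4, 0.1, 0.5, 0.1, 0.05, 0.01),
    called = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  shifts <- data.frame(
    promoter_id = c("A", "B", "C"),
    n_probes = 2,
    shift_p = c(0.0005, 0.5, 0.0001),  # BH q: A 0.00075, B 0.5, C 0.0003
    direction = c("hyper", "hyper", "hypo")
  )
  out <- call_promoters(probe_stats, shifts)
  expect_equal(out$called_default[out$promoter_id == "A"], TRUE)
  expect_equal(out$called_default[out$promoter_id == "B"], FALSE)  # q too big
  expect_equal(out$called_default[out$promoter_id == "C"], FALSE) # no DM probe
  # has DM probe but q just above the cut
  shifts2 <- shifts
  shifts2$shift_p <- c(0.15, 0.17, 0.2)  # q = 0.2..0.3 > 0.2 for A after BH
  out2 <- call_promoters(probe_stats, shifts2)
  expect_false(any(out2$called_default))
  # strict tier: probe p < 0.01 needed
  expect_equal(out$called_strict[out$promoter_id == "A"], FALSE)
  probe_stats$p[1] <- 0.005
  out3 <- call_promoters(probe_stats, shifts)
  expect_true(out3$called_strict[out3$promoter_id == "A"])
})

test_that("the representative probe is the most associated one", {
  s <- data.frame(probe_id = c("a", "b", "c"), promoter_id = "P",
                  p = c(0.5, 0.01, 0.2), beta = c(1, 0.1, 0.3))
  expect_equal(representative_probe(s)$representative_probe_id, "b")
  s2 <- data.frame(probe_id = c("a", "b"), promoter_id = "P",
                   p = c(0.01, 0.01), beta = c(0.3, 0.6))
  expect_equal(representative_probe(s2)$representative_probe_id, "b")
  s3 <- data.frame(probe_id = "only", promoter_id = "P", p = 0.9, beta = 0)
  expect_equal(representative_probe(s3)$representative_probe_id, "only")
})

test_that("sample clustering is Ward on 1 - Pearson correlation", {
  # identical columns merge first at height 0
  set.seed(12)
  base <- rnorm(20)
  x <- cbind(a = base, b = base, c = rnorm(20), d = rnorm(20))
  cl <- cluster_samples(x)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-7)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  # perfectly anti-correlated columns sit at distance 2
  y <- cbind(u = base, v = -base)
  expect_equal(1 - cor(y)[1, 2], 2, tolerance = 1e-12)

  # 4-column toy: merge heights match the Lance-Williams oracle
  z <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  d <- as.dist(1 - cor(z))
  cl2 <- cluster_samples(z)
  expect_equal(cl2$hclust$height, ward_d2_oracle(d), tolerance = 1e-10)

  # constant column flagged, distance forced to the stated maximum
  w <- cbind(k = rep(1, 10), m = rnorm(10), n = rnorm(10))
  cl3 <- cluster_samples(w)
  expect_equal(cl3$flagged, "k")
})
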