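test_that("the hypergeometric upper tail matches direct summation", {
  expect_equal(hypergeometric_tail(10, 5, 5, 0), 1)
  expect_equal(hypergeometric_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    N <- 2000; K <- 100; n <- 50
    k <- sample(0:50, 1)
    expect_equal(hypergeometric_tail(N, K, n, k), hyper_oracle(N, K, n, k),
                 tolerance = 1e-12)
  }
  # symmetry in (K, n) and monotonicity in k
  expect_equal(hypergeometric_tail(500, 60, 30, 10),
               hypergeometric_tail(500, 30, 60, 10), tolerance = 1e-14)
  p_seq <- hypergeometric_tail(200, 40, 30, 0:30)
  expect_true(all(diff(p_seq) < 0))
  # the point masses sum to one
  expect_equal(sum(dhyper(0:30, 40, 160, 30)), 1, tolerance = 1e-12)
  expect_error(hypergeometric_tail(10, 5, 5, 6), "inconsistent")
})

test_that("gene-set enrichment reports the three direction contexts", {
  # a collection with one 142-gene set holding 19 DM genes (15 hypo, 4 hyper)
  universe <- sprintf("G%04d", 1:2000)
  set.seed(14)
  in_set <- sample(universe, 142)
  hypo <- c(sample(in_set, 15), sample(setdiff(universe, in_set), 300))
  hyper <- c(sample(setdiff(in_set, hypo), 4),
             sample(setdiff(universe, c(in_set, hypo)), 100))
  called <- list(any = union(hypo, hyper), hypo = hypo, hyper = hyper)
  sets <- list(WNT = in_set, RANDOM = sample(universe, 80))
  res <- gene_set_enrichment(called, universe, sets)
  wnt <- res[res$unit_id == "WNT", ]
  expect_equal(wnt$n, rep(142, 3))
  expect_equal(wnt$k[wnt$context == "any"], 19)
  expect_equal(wnt$k[wnt$context == "hypo"], 15)
  expect_equal(wnt$k[wnt$context == "hyper"], 4)
  expect_true(all(res$p > 0 & res$p <= 1))

  # no DM genes -> all p = 1
  res0 <- gene_set_enrichment(list(any = character(0), hypo = character(0),
                                   hyper = character(0)), universe, sets)
  expect_true(all(res0$p == 1))
})

test_that("enrichment p-values are calibrated under random labels", {
  set.seed(15)
  universe <- sprintf("G%04d", 1:2000)
  sets <- lapply(1:200, function(i) sample(universe, 50))
  names(sets) <- paste0("S", 1:200)
  dm <- sample(universe, 150)
  res <- gene_set_enrichment(list(any = dm, hypo = dm, hyper = character(0)),
                             universe, sets)
  p <- res$p[res$context == "any"]
  # discrete p-values are stochastically >= uniform; check no inflation
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("miRNA-target consistency carries the exact overlap record", {
  # one hypermethylated DM miRNA with 49 profiled targets, 10 called hypo
  # and 1 called hyper among them
  genes <- sprintf("G%03d", 1:500)
  promoters <- data.frame(
    promoter_id = c(sprintf("PG%03d", 1:500), "PM001"),
    gene_id = c(genes, "mir-514x"),
    chrom = "chr1", tss = seq(2000, by = 3000, length.out = 501),
    strand = "+", class = c(rep("gene", 500), "miRNA"))
  layout <- structure(list(promoters = promoters), class = "genome_layout")

  hypo_genes <- sprintf("G%03d", 1:60)
  hyper_genes <- sprintf("G%03d", 61:80)
  calls <- data.frame(
    promoter_id = promoters$promoter_id,
    direction = c(rep("hypo", 60), rep("hyper", 20), rep("hypo", 420), "hyper"),
    called_default = c(rep(TRUE, 80), rep(FALSE, 420), TRUE),
    called_strict = FALSE)
  fit <- fake_fit(calls)

  targets <- c(sprintf("G%03d", 1:10),     # 10 hypo
               "G061",                     # 1 hyper
               sprintf("G%03d", 101:138))  # 38 uncalled
  map <- data.frame(mirna_id = "mir-514x", gene_id = targets)
  res <- mirna_target_consistency(fit, layout, map)
  expect_equal(res$n_targets, 49)
  expect_equal(res$k_hypo, 10)
  expect_equal(res$k_hyper, 1)
  expect_equal(res$N, 500)
  expect_equal(res$K, 60)
  expect_equal(res$p, hyper_oracle(500, 60, 49, 10), tolerance = 1e-12)
  expect_true(res$consistent)

  # no hypo targets -> p = 1, not consistent
  map0 <- data.frame(mirna_id = "mir-514x",
                     gene_id = sprintf("G%03d", 101:140))
  res0 <- mirna_target_consistency(fit, layout, map0)
  expect_equal(res0$p, 1)
  expect_false(res0$consistent)
})

test_that("planted consistent miRNAs are recovered from a strong generator", {
  ds <- small_dataset(seed = 31, n_promoters = 600, n_mirnas = 40,
                      fraction_dm = 0.12, n_dm_mirnas = 8,
                      n_consistent_mirnas = 3, n_targets_per_mirna = 60,
                      consistency_odds = 12)
  fit <- fit_dataset(ds)
  res <- mirna_target_consistency(fit, ds$layout, ds$target_map)
  planted <- attr(ds$target_map, "consistent_mirnas")
  expect_true(all(planted %in% res$mirna_id[res$consistent]))
})

test_that("intersection tests match the combinatorial oracle and flag nothing under independence", {
  universe <- sprintf("g%03d", 1:200)
  a <- universe[1:30]; b <- universe[21:60]
  r <- intersection_test(a, b, universe)
  expect_equal(r$k, 10)
  expect_equal(r$p, hyper_oracle(200, 30, 40, 10), tolerance = 1e-12)

  r0 <- intersection_test(universe[1:10], universe[50:60], universe)
  expect_equal(r0$k, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$no_confound)

  expect_warning(re <- intersection_test(character(0), b, universe), "empty")
  expect_equal(re$p, 1)

  set.seed(16)
  ps <- replicate(300, {
    intersection_test(sample(universe, 30), sample(universe, 30), universe)$p
  })
  expect_gt(mean(ps), 0.4)           # no systematic inflation
  expect_lt(mean(ps < 0.05), 0.1)
})
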