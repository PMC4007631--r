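test_that("window enrichment has the stated null and extreme behaviour", {
  ds <- small_dataset(seed = 41)
  fit <- fit_dataset(ds)

  # disjoint windows partition the promoters: per-chromosome counts add up
  win <- window_enrichment(fit, ds$layout, width = 1e6, step = 1e6)
  for (ch in unique(win$chrom)) {
    n_ch <- sum(ds$layout$promoters$chrom == ch)
    expect_equal(sum(win$n[win$chrom == ch & win$start %% 1e6 == 0 &
                             win$end <= ds$layout$chromosomes$length[
                               ds$layout$chromosomes$name == ch]]),
                 n_ch)
  }

  # no called promoters -> all p = 1
  null_fit <- fit
  null_fit$promoters$called_default <- FALSE
  win0 <- window_enrichment(null_fit, ds$layout)
  expect_true(all(win0$p == 1))

  # all calls inside one window -> that window has the genome-wide minimum p
  one <- fit
  target <- ds$layout$promoters$promoter_id[ds$layout$promoters$chrom == "chr1" &
    ds$layout$promoters$tss < 1e6]
  one$promoters$called_default <- one$promoters$promoter_id %in% target
  win1 <- window_enrichment(one, ds$layout, width = 1e6, step = 1e6)
  best <- win1[which.min(win1$p), ]
  expect_equal(best$chrom, "chr1")
  expect_equal(best$start, 0)

  # chromosome mode: one window per chromosome
  winc <- window_enrichment(fit, ds$layout, by_chromosome = TRUE)
  expect_equal(nrow(winc), nrow(ds$layout$chromosomes))
  expect_equal(sum(winc$n), nrow(ds$layout$promoters))
})

test_that("a planted dense block is recovered among FDR < 0.2 windows", {
  ds <- small_dataset(seed = 42, n_promoters = 400, block_promoters = 20,
                      cluster_dm_fraction = 0.6, fraction_dm = 0.06)
  fit <- fit_dataset(ds)
  win <- window_enrichment(fit, ds$layout)
  blk <- ds$truth$cluster_blocks
  hits <- win$q < 0.2 & win$chrom == blk$chrom[1] &
    win$start < blk$end[1] & win$end > blk$start[1]
  expect_true(any(hits))
})

test_that("distance correlation is 1 for duplicated statistics and sign-invariant", {
  # fabricate promoters in pairs 100 kb apart with identical statistics
  n <- 60
  tss <- sort(c(seq(1e6, by = 3e6, length.out = n / 2),
                seq(1e6, by = 3e6, length.out = n / 2) + 1e5))
  promoters <- data.frame(
    promoter_id = sprintf("P%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    chrom = "chr1", tss = tss, strand = "+", class = "gene")
  layout <- structure(list(promoters = promoters), class = "genome_layout")
  set.seed(17)
  stat_pair <- rnorm(n / 2)
  stat <- as.vector(rbind(stat_pair, stat_pair))  # identical within pairs
  pm <- data.frame(promoter_id = promoters$promoter_id,
                   representative_probe_id = paste0("rp", seq_len(n)))
  probes <- data.frame(probe_id = paste0("rp", seq_len(n)), t_mod = stat)
  fit <- fake_fit(pm, probes)
  dc <- distance_correlation(fit, layout, bin_width = 5e5, max_dist = 2e6,
                             min_pairs = 5)
  first <- dc[dc$bin_center == 2.5e5, ]
  expect_equal(first$r, 1, tolerance = 1e-12)
  expect_equal(first$n_pairs, n / 2)
  expect_true(all(dc$ci_low <= dc$r & dc$r <= dc$ci_high))

  # global sign flip leaves r unchanged
  probes2 <- probes; probes2$t_mod <- -probes2$t_mod
  dc2 <- distance_correlation(fake_fit(pm, probes2), layout,
                              bin_width = 5e5, max_dist = 2e6, min_pairs = 5)
  expect_equal(dc2$r, dc$r, tolerance = 1e-12)

  # independent statistics give r ~ 0
  probes3 <- probes; set.seed(18); probes3$t_mod <- rnorm(n)
  dc3 <- distance_correlation(fake_fit(pm, probes3), layout,
                              bin_width = 5e5, max_dist = 2e6, min_pairs = 5)
  expect_lt(abs(dc3$r[1]), 0.5)
})

test_that("CpG density follows the hand-count formula and its symmetries", {
  seqs <- Biostrings::DNAStringSet(c(a = "CGCGCG", b = "ACGT", c = "GGCCAA",
                                     d = "AAAACC"))
  expect_message(r <- cpg_density(seqs), "excluding 1 promoter")
  per <- setNames(r$per_promoter$cpg_ratio, r$per_promoter$promoter_id)
  expect_equal(unname(per["a"]), 3 * 6 / (3 * 3))  # = 2
  expect_equal(unname(per["b"]), 1 * 4 / (1 * 1))  # = 4
  expect_equal(unname(per["c"]), 0)
  # d has no G: excluded with a message
  expect_false("d" %in% names(per))

  # reverse complement leaves the normalized frequency unchanged
  set.seed(19)
  rand <- sapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""))
  fw <- Biostrings::DNAStringSet(setNames(rand, paste0("s", 1:10)))
  rc <- Biostrings::reverseComplement(fw)
  names(rc) <- names(fw)
  expect_equal(cpg_density(fw)$per_promoter$cpg_ratio,
               cpg_density(rc)$per_promoter$cpg_ratio, tolerance = 1e-12)
})

test_that("simulated promoter sequences separate the call groups by CpG density", {
  ds <- small_dataset(seed = 43, n_promoters = 300)
  seqs <- simulate_promoter_sequences(ds$layout, ds$truth, seed = 2)
  calls <- data.frame(
    promoter_id = ds$truth$dm$promoter_id,
    direction = ds$truth$dm$direction,
    called_default = TRUE, called_strict = FALSE)
  r <- cpg_density(seqs, calls = calls)
  expect_gt(r$group_means["hypo"], r$group_means["all"])
  expect_gt(r$group_means["all"], r$group_means["hyper"])
  expect_lt(r$tests$p[r$tests$comparison == "hypo_vs_hyper"], 0.01)
  # realized ratios track the configured targets
  expect_equal(unname(r$group_means["hypo"]), 0.86, tolerance = 0.15)
})

test_that("wiggle export uses 1-based positions and round-trips exactly", {
  ds <- small_dataset(seed = 44, n_promoters = 40, n_mirnas = 4,
                      n_cluster_blocks = 0, n_dm_mirnas = 1,
                      n_consistent_mirnas = 1, n_targets_per_mirna = 5)
  diff <- setNames(round(rnorm(nrow(ds$layout$probes)), 6),
                   ds$layout$probes$probe_id)
  path <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(diff, ds$layout, path)
  back <- read_wiggle(path)
  expect_equal(nrow(back), nrow(ds$layout$probes))

  pb <- ds$layout$probes
  pb <- pb[order(match(pb$chrom, ds$layout$chromosomes$name), pb$start), ]
  expect_equal(back$pos, pb$start + 1)           # 0-based -> 1-based
  expect_equal(back$value, unname(diff[pb$probe_id]))
  expect_equal(unique(back$span), 50L)

  # zero differences -> all zero values
  path0 <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(setNames(numeric(nrow(pb)), pb$probe_id), ds$layout, path0)
  expect_true(all(read_wiggle(path0)$value == 0))
})

test_that("emitted wiggle parses with rtracklayer", {
  skip_if_not_installed("rtracklayer")
  ds <- small_dataset(seed = 45, n_promoters = 10, n_mirnas = 1,
                      n_cluster_blocks = 0, n_dm_mirnas = 1, fraction_dm = 0.2,
                      n_consistent_mirnas = 1, n_targets_per_mirna = 3)
  diff <- setNames(seq_len(nrow(ds$layout$probes)) / 10,
                   ds$layout$probes$probe_id)
  path <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(diff, ds$layout, path)
  gr <- rtracklayer::import(path, format = "wig")
  expect_equal(length(gr), nrow(ds$layout$probes))
  own <- read_wiggle(path)
  expect_equal(BiocGenerics::start(gr), own$pos)
  expect_equal(gr$score, own$value, tolerance = 1e-9)
})
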