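#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in order: load annotation, sample sheet and
#' intensities; MvA QC; log ratios and quantile normalization; replicate
#' averaging; probe statistics; two-tier promoter calls (default and
#' strict); gene-set enrichment and miRNA-target consistency (when the
#' corresponding inputs are configured); window enrichment and
#' distance-correlation profiles; wiggle export; and, unless skipped, the
#' label-permutation check. All result tables are written to `out_dir` and a
#' summary with the headline counts is returned (and written to
#' `summary.txt`).
#'
#' @param config a named list or the path to a YAML file with entries:
#'   `annotation`, `intensities` (directory), `sample_sheet`, `out_dir`
#'   (required); `gene_sets` (GMT), `target_map`, `fasta` (optional inputs);
#'   `case` (case label, default "case"), `thresholds` (p_cut, fc_cut,
#'   q_cut, strict_p, strict_q), `window` (width, step), `distance`
#'   (bin_width, max_dist), `permutations` (count, 0 to skip), `seed`.
#' @return A list with the fit, the stage outputs and the summary counts,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("annotation", "intensities", "sample_sheet", "out_dir"))
    if (is.null(config[[f]])) .stopf("config lacks required field '%s'", f)
  for (f in c("annotation", "sample_sheet"))
    if (!file.exists(config[[f]])) .stopf("config: '%s' does not exist: %s",
                                          f, config[[f]])
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds %||% list()
  case <- config$case %||% "case"
  if (!is.null(config$seed)) set.seed(config$seed)

  .msgf("[1/8] loading inputs")
  layout <- read_probe_annotation(config$annotation)
  arrays <- load_arrays(config$intensities, config$sample_sheet)

  .msgf("[2/8] QC")
  qc <- ma_qc(arrays)
  write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  .msgf("[3/8] normalization and replicate averaging")
  m <- compute_log_ratios(arrays)
  m <- quantile_normalize(m)
  avg <- average_replicates(m, arrays$sheet)
  group <- arrays$sheet$group[match(colnames(avg),
                                    arrays$sheet$individual_id)]

  .msgf("[4/8] probe and promoter statistics")
  fit <- medip_fit(avg, group, layout,
                   p_cut = thr$p_cut %||% 0.05, fc_cut = thr$fc_cut %||% 0.25,
                   q_cut = thr$q_cut %||% 0.20,
                   strict_p = thr$strict_p %||% 0.01,
                   strict_q = thr$strict_q %||% 0.05, case = case)
  write_fit_tables(fit, out_dir)

  .msgf("[5/8] enrichment analyses")
  genes <- dm_genes(fit, layout)
  enr <- mirna <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- load_gene_sets(config$gene_sets, universe = genes$universe)
    enr <- gene_set_enrichment(genes, genes$universe, sets)
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$target_map)) {
    map <- load_mirna_targets(config$target_map)
    mirna <- mirna_target_consistency(fit, layout, map)
    if (!is.null(mirna))
      write.table(mirna, file.path(out_dir, "mirna_consistency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  .msgf("[6/8] genomic features")
  win <- config$window %||% list()
  windows <- window_enrichment(fit, layout,
                               width = win$width %||% 750000,
                               step = win$step %||% 250000)
  if (!is.null(windows))
    write.table(windows, file.path(out_dir, "windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  dc <- config$distance %||% list()
  dcorr <- distance_correlation(fit, layout,
                                bin_width = dc$bin_width %||% 500000,
                                max_dist = dc$max_dist %||% 2000000)
  if (!is.null(dcorr))
    write.table(dcorr, file.path(out_dir, "distance_correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_wiggle(coef(fit), layout, file.path(out_dir, "group_difference.wig"))
  cpg <- NULL
  if (!is.null(config$fasta))
    cpg <- cpg_density(config$fasta, calls = fit$promoters)

  perm <- NULL
  n_perm <- config$permutations %||% 0
  if (n_perm > 0) {
    .msgf("[7/8] permutation check (%d partitions)", n_perm)
    perm <- permutation_percentile(avg, group, layout,
                                   n_partitions = n_perm,
                                   seed = config$seed, case = case,
                                   p_cut = thr$p_cut %||% 0.05,
                                   fc_cut = thr$fc_cut %||% 0.25,
                                   q_cut = thr$q_cut %||% 0.20)
    write.table(data.frame(partition = seq_along(perm$null_counts),
                           call_count = perm$null_counts),
                file.path(out_dir, "permutation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else .msgf("[7/8] permutation check skipped")

  .msgf("[8/8] summary")
  s <- summary(fit)
  summary_lines <- c(
    sprintf("promoters tested: %d", s$n_promoters),
    sprintf("called (default, FDR < %d%%): %d (%d hyper / %d hypo)",
            round(100 * fit$thresholds["q_cut"]), s$n_called_default,
            s$n_hyper, s$n_hypo),
    sprintf("called (strict): %d", s$n_called_strict),
    if (!is.null(mirna))
      sprintf("DM miRNAs tested: %d; consistent: %d", nrow(mirna),
              sum(mirna$consistent)),
    if (!is.null(windows))
      sprintf("windows at FDR < 0.2: %d", sum(windows$q < 0.2)),
    if (!is.null(perm))
      sprintf("permutation percentile: %.3f (%d partitions)",
              perm$percentile, perm$n_partitions)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(fit = fit, qc = qc, enrichment = enr, mirna = mirna,
                 windows = windows, distance_correlation = dcorr,
                 cpg = cpg, permutation = perm, summary = s))
}
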