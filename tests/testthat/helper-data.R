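# small synthetic datasets for module tests (desk-scale defaults are used
# only in the acceptance suite)

small_config <- function(seed = 1L, ...) {
  args <- list(n_promoters = 150, n_mirnas = 15, n_cluster_blocks = 1,
               block_promoters = 12, chromosome_length = 2e7,
               n_dm_mirnas = 3, n_consistent_mirnas = 2,
               n_targets_per_mirna = 30, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

small_dataset <- function(seed = 1L, ...) {
  suppressMessages(simulate_medip_dataset(small_config(seed, ...)))
}

averaged_matrix <- function(ds) {
  m <- suppressMessages(quantile_normalize(compute_log_ratios(ds$arrays)))
  average_replicates(m, ds$arrays$sheet)
}

group_of <- function(ds, avg) {
  ds$arrays$sheet$group[match(colnames(avg), ds$arrays$sheet$individual_id)]
}

fit_dataset <- function(ds, ...) {
  avg <- averaged_matrix(ds)
  suppressMessages(medip_fit(avg, group_of(ds, avg), ds$layout, ...))
}

# a minimal hand-built fit object for functions that only consume the
# promoter table and probe statistics
fake_fit <- function(promoters, probes = NULL) {
  structure(list(promoters = promoters, probes = probes), class = "medip_fit")
}
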