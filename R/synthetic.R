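#' Simulation configuration for synthetic MeDIP-chip datasets
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' the study design the package targets: 12 case vs 28 control individuals
#' with 3 replicate arrays each, promoters tiled from 1000 bp upstream to
#' 250 bp downstream of the TSS at 100 bp spacing (13 probes per promoter),
#' about 5% of promoters differentially methylated with 31% of those
#' hypermethylated, and a planted effect of 0.5 on the log2 scale.
#'
#' Noise defaults reflect the replicate QC reported for such designs:
#' `individual_sd = 0.4` and `replicate_sd = 0.25` put roughly 70-75% of the
#' per-probe variance between individuals rather than between replicate
#' arrays. Individual (biological) effects are drawn independently per probe
#' and individual; promoter-level coherence enters through the per-promoter
#' baseline methylation level and through the planted effect, which is
#' uniform across a promoter's probes.
#'
#' @param n_case,n_control numbers of case and control individuals.
#' @param n_replicates replicate arrays per individual.
#' @param n_promoters total promoters on the design (genes + miRNAs).
#' @param n_mirnas number of miRNA promoters among `n_promoters`.
#' @param fraction_dm fraction of promoters that are differentially
#'   methylated.
#' @param fraction_hyper fraction of differentially methylated promoters that
#'   are hypermethylated in the case group.
#' @param effect_size planted |log2| group difference for DM promoters.
#' @param individual_sd SD of per-individual biological effects (log2 units).
#' @param replicate_sd SD of per-array replicate noise (log2 units).
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent dye
#'   bias added to each array's log-ratio (0 disables it).
#' @param baseline_mean,baseline_sd per-promoter baseline methylation level
#'   (log2 enrichment of bound over input).
#' @param probe_jitter_sd per-probe jitter around the promoter baseline.
#' @param input_meanlog,input_sdlog log-normal parameters of the input
#'   channel intensities.
#' @param n_chromosomes,chromosome_length genome layout: number of
#'   chromosomes and their common length in bp.
#' @param probe_offsets probe offsets from the TSS in bp.
#' @param probe_length probe length in bp.
#' @param n_cluster_blocks number of dense genomic blocks in which part of
#'   the DM promoters are concentrated (for spatial-clustering statistics).
#' @param block_width width of each block in bp.
#' @param block_promoters promoters placed inside each block.
#' @param cluster_dm_fraction fraction of DM promoters assigned to blocks.
#' @param n_dm_mirnas number of miRNA promoters planted as DM.
#' @param mirna_hyper_fraction fraction of DM miRNAs that are hypermethylated.
#' @param n_consistent_mirnas hypermethylated DM miRNAs whose target sets are
#'   enriched for hypomethylated DM genes.
#' @param n_targets_per_mirna target-set size per miRNA.
#' @param consistency_odds sampling odds favouring hypomethylated DM genes in
#'   the target sets of consistent miRNAs (1 = no planted signal).
#' @param seed integer seed fixing the whole dataset.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 12, n_control = 28, n_replicates = 3,
                       n_promoters = 2000, n_mirnas = 60,
                       fraction_dm = 0.05, fraction_hyper = 0.31,
                       effect_size = 0.5,
                       individual_sd = 0.4, replicate_sd = 0.25,
                       dye_bias_amplitude = 0,
                       baseline_mean = 0.5, baseline_sd = 0.5,
                       probe_jitter_sd = 0.1,
                       input_meanlog = log(1000), input_sdlog = 0.4,
                       n_chromosomes = 2, chromosome_length = 5e7,
                       probe_offsets = seq(-1000L, 200L, by = 100L),
                       probe_length = 50L,
                       n_cluster_blocks = 2, block_width = 750000,
                       block_promoters = 25, cluster_dm_fraction = 0.4,
                       n_dm_mirnas = 12, mirna_hyper_fraction = 0.75,
                       n_consistent_mirnas = 6, n_targets_per_mirna = 50,
                       consistency_odds = 5,
                       seed = 1L) {
  cfg <- list(
    n_case = .check_count(n_case, "n_case"),
    n_control = .check_count(n_control, "n_control"),
    n_replicates = .check_count(n_replicates, "n_replicates"),
    n_promoters = .check_count(n_promoters, "n_promoters"),
    n_mirnas = .check_count(n_mirnas, "n_mirnas", positive = FALSE),
    fraction_dm = .check_fraction(fraction_dm, "fraction_dm"),
    fraction_hyper = .check_fraction(fraction_hyper, "fraction_hyper"),
    effect_size = effect_size,
    individual_sd = individual_sd, replicate_sd = replicate_sd,
    dye_bias_amplitude = dye_bias_amplitude,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    probe_jitter_sd = probe_jitter_sd,
    input_meanlog = input_meanlog, input_sdlog = input_sdlog,
    n_chromosomes = .check_count(n_chromosomes, "n_chromosomes"),
    chromosome_length = chromosome_length,
    probe_offsets = as.integer(probe_offsets),
    probe_length = as.integer(probe_length),
    n_cluster_blocks = .check_count(n_cluster_blocks, "n_cluster_blocks",
                                    positive = FALSE),
    block_width = block_width,
    block_promoters = .check_count(block_promoters, "block_promoters",
                                   positive = FALSE),
    cluster_dm_fraction = .check_fraction(cluster_dm_fraction,
                                          "cluster_dm_fraction"),
    n_dm_mirnas = .check_count(n_dm_mirnas, "n_dm_mirnas", positive = FALSE),
    mirna_hyper_fraction = .check_fraction(mirna_hyper_fraction,
                                           "mirna_hyper_fraction"),
    n_consistent_mirnas = .check_count(n_consistent_mirnas,
                                       "n_consistent_mirnas", positive = FALSE),
    n_targets_per_mirna = .check_count(n_targets_per_mirna,
                                       "n_targets_per_mirna"),
    consistency_odds = consistency_odds,
    seed = .check_count(seed, "seed", positive = FALSE)
  )
  if (any(cfg$probe_offsets < -1000L) || any(cfg$probe_offsets > 250L))
    .stopf("probe offsets must lie in [-1000, 250]")
  if (cfg$n_mirnas >= cfg$n_promoters)
    .stopf("n_mirnas must be smaller than n_promoters")
  if (cfg$n_dm_mirnas > cfg$n_mirnas)
    .stopf("n_dm_mirnas cannot exceed n_mirnas")
  if (cfg$individual_sd < 0 || cfg$replicate_sd < 0)
    .stopf("noise standard deviations must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a promoter tiling-array genome layout
#'
#' Lays out `n_promoters` promoters on `n_chromosomes` chromosomes, each
#' tiled with one probe per offset in `probe_offsets` (by default 13 probes,
#' -1000..+200 bp from the TSS at 100 bp spacing). A configurable number of
#' dense blocks each receive `block_promoters` promoters so that spatial
#' clustering statistics have structure to detect; remaining promoters are
#' placed uniformly. miRNA promoters are interleaved among the non-block
#' promoters. TSS positions are strictly increasing within a chromosome.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `genome_layout` with elements `chromosomes`
#'   (name, length), `promoters` (promoter_id, gene_id, chrom, tss, strand,
#'   class), `probes` (probe_id, promoter_id, chrom, start, end, offset;
#'   0-based half-open coordinates) and `blocks` (the dense intervals).
#' @export
generate_genome_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- data.frame(
    name = paste0("chr", seq_len(config$n_chromosomes)),
    length = rep(config$chromosome_length, config$n_chromosomes),
    stringsAsFactors = FALSE
  )
  n_block_prom <- config$n_cluster_blocks * config$block_promoters
  if (n_block_prom > config$n_promoters)
    .stopf("cluster blocks require more promoters than n_promoters")

  # place disjoint dense blocks, keeping them well separated (> 4 Mb) so
  # short-range and long-range distance statistics do not mix
  blocks <- NULL
  if (config$n_cluster_blocks > 0) {
    margin <- 4e6
    bchrom <- rep_len(chroms$name, config$n_cluster_blocks)
    bstart <- numeric(config$n_cluster_blocks)
    for (i in seq_len(config$n_cluster_blocks)) {
      repeat {
        s <- floor(runif(1, 2e6, chroms$length[1] - config$block_width - 2e6))
        same <- which(bchrom[seq_len(i - 1)] == bchrom[i])
        if (!length(same) ||
            all(abs(bstart[same] - s) > config$block_width + margin)) {
          bstart[i] <- s
          break
        }
      }
    }
    blocks <- data.frame(chrom = bchrom, start = bstart,
                         end = bstart + config$block_width,
                         stringsAsFactors = FALSE)
  }

  # TSS positions on a 500 bp grid, sampled without replacement
  pos_chrom <- character(config$n_promoters)
  pos_tss <- numeric(config$n_promoters)
  in_block <- logical(config$n_promoters)
  k <- 0L
  if (!is.null(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      grid <- seq(blocks$start[i] + 1000, blocks$end[i] - 1000, by = 500)
      idx <- k + seq_len(config$block_promoters)
      pos_chrom[idx] <- blocks$chrom[i]
      pos_tss[idx] <- sort(sample(grid, config$block_promoters))
      in_block[idx] <- TRUE
      k <- k + config$block_promoters
    }
  }
  n_rest <- config$n_promoters - k
  per_chrom <- tabulate(sample.int(nrow(chroms), n_rest, replace = TRUE),
                        nbins = nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    if (per_chrom[i] == 0) next
    grid <- seq(2000, chroms$length[i] - 2000, by = 500)
    idx <- k + seq_len(per_chrom[i])
    pos_chrom[idx] <- chroms$name[i]
    pos_tss[idx] <- sample(grid, per_chrom[i])
    in_block[idx] <- FALSE
    k <- k + per_chrom[i]
  }

  # avoid collisions between block and background placements
  key <- paste(pos_chrom, pos_tss)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key) & !in_block)
    if (!length(dup)) dup <- which(duplicated(key))
    pos_tss[dup] <- pos_tss[dup] + 250
    key <- paste(pos_chrom, pos_tss)
  }

  ord <- order(match(pos_chrom, chroms$name), pos_tss)
  pos_chrom <- pos_chrom[ord]; pos_tss <- pos_tss[ord]
  in_block <- in_block[ord]

  n <- config$n_promoters
  promoter_id <- sprintf("P%05d", seq_len(n))
  cls <- rep("gene", n)
  if (config$n_mirnas > 0) {
    eligible <- which(!in_block)
    if (length(eligible) < config$n_mirnas) eligible <- seq_len(n)
    cls[sample(eligible, config$n_mirnas)] <- "miRNA"
  }
  gene_id <- character(n)
  gene_id[cls == "gene"] <- sprintf("G%05d", seq_len(sum(cls == "gene")))
  gene_id[cls == "miRNA"] <- sprintf("mir-%03d", seq_len(sum(cls == "miRNA")))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  promoters <- data.frame(promoter_id = promoter_id, gene_id = gene_id,
                          chrom = pos_chrom, tss = pos_tss, strand = strand,
                          class = cls, in_block = in_block,
                          stringsAsFactors = FALSE)

  offs <- config$probe_offsets
  m <- length(offs)
  pl <- config$probe_length
  rep_idx <- rep(seq_len(n), each = m)
  off_all <- rep(offs, times = n)
  plus <- strand[rep_idx] == "+"
  start <- ifelse(plus, pos_tss[rep_idx] + off_all,
                  pos_tss[rep_idx] - off_all - pl)
  probes <- data.frame(
    probe_id = paste0(promoter_id[rep_idx], sprintf("_p%02d", rep(seq_len(m), n))),
    promoter_id = promoter_id[rep_idx],
    chrom = pos_chrom[rep_idx],
    start = as.numeric(start),
    end = as.numeric(start + pl),
    offset = off_all,
    stringsAsFactors = FALSE
  )

  layout <- list(chromosomes = chroms, promoters = promoters,
                 probes = probes, blocks = blocks)
  class(layout) <- "genome_layout"
  validate_genome_layout(layout)
  layout
}

#' Validate a genome layout
#'
#' Checks the structural invariants of a layout: probe offsets within
#' \[-1000, 250\], adjacent probes of a promoter 100 bp apart in offset,
#' every probe mapped to exactly one known promoter, unique probe ids, and
#' strictly increasing TSS positions within each chromosome.
#'
#' @param layout a `genome_layout`.
#' @return The layout, invisibly; errors describe the first violation.
#' @export
validate_genome_layout <- function(layout) {
  p <- layout$probes; pr <- layout$promoters
  if (anyDuplicated(p$probe_id)) .stopf("duplicate probe ids")
  if (anyDuplicated(pr$promoter_id)) .stopf("duplicate promoter ids")
  if (any(p$offset < -1000 | p$offset > 250))
    .stopf("probe offsets outside [-1000, 250]")
  if (!all(p$promoter_id %in% pr$promoter_id))
    .stopf("probes mapped to unknown promoters")
  if (any(p$start >= p$end)) .stopf("probe start >= end")
  d <- unlist(tapply(p$offset, p$promoter_id,
                     function(o) diff(sort(o)), simplify = FALSE),
              use.names = FALSE)
  if (length(d) && any(d != 100))
    .stopf("adjacent probes within a promoter must be 100 bp apart")
  for (ch in unique(pr$chrom)) {
    tss <- pr$tss[pr$chrom == ch]
    if (any(diff(tss) <= 0))
      .stopf("TSS positions not strictly increasing on %s", ch)
  }
  invisible(layout)
}

#' Plant ground truth: differentially methylated promoters
#'
#' Selects the promoters that carry a planted group effect. A configurable
#' fraction of the DM promoters is concentrated inside the layout's dense
#' blocks (one coherent direction per block, alternating hyper/hypo across
#' blocks); `n_dm_mirnas` miRNA promoters are planted DM with
#' `mirna_hyper_fraction` of them hypermethylated; the remainder is scattered
#' uniformly over the other gene promoters, with signs chosen so the overall
#' hypermethylated fraction matches `fraction_hyper` as closely as the block
#' and miRNA quotas allow.
#'
#' @param layout a `genome_layout`.
#' @param config the [sim_config()] used to build the layout.
#' @return A list of class `sim_truth` with `dm` (promoter_id, gene_id,
#'   class, delta, direction), `dm_mirnas`, and `cluster_blocks` (intervals
#'   that received concentrated DM promoters).
#' @export
simulate_truth <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pr <- layout$promoters
  n_dm <- round(config$fraction_dm * config$n_promoters)
  n_hyper <- round(config$fraction_hyper * n_dm)

  dm_id <- character(0); dm_dir <- character(0)

  # block-concentrated DM promoters, coherent direction per block
  n_block_dm_total <- round(config$cluster_dm_fraction * n_dm)
  used_blocks <- NULL
  if (!is.null(layout$blocks) && n_block_dm_total > 0) {
    nb <- nrow(layout$blocks)
    per_block <- diff(round(seq(0, n_block_dm_total, length.out = nb + 1)))
    dirs <- rep(c("hyper", "hypo"), length.out = nb)
    for (i in seq_len(nb)) {
      b <- layout$blocks[i, ]
      cand <- pr$promoter_id[pr$in_block & pr$chrom == b$chrom &
                               pr$tss >= b$start & pr$tss < b$end &
                               pr$class == "gene"]
      take <- min(per_block[i], length(cand))
      if (take > 0) {
        dm_id <- c(dm_id, sample(cand, take))
        dm_dir <- c(dm_dir, rep(dirs[i], take))
      }
    }
    used_blocks <- layout$blocks
  }

  # miRNA DM promoters
  dm_mirnas <- character(0)
  if (config$n_dm_mirnas > 0) {
    mir <- pr$promoter_id[pr$class == "miRNA"]
    dm_mirnas <- sample(mir, config$n_dm_mirnas)
    n_mir_hyper <- round(config$mirna_hyper_fraction * config$n_dm_mirnas)
    mdir <- c(rep("hyper", n_mir_hyper),
              rep("hypo", config$n_dm_mirnas - n_mir_hyper))
    dm_id <- c(dm_id, dm_mirnas)
    dm_dir <- c(dm_dir, mdir)
  }

  # scattered gene DM promoters fill the remaining quota
  n_rest <- n_dm - length(dm_id)
  if (n_rest < 0) .stopf("block and miRNA DM quotas exceed total DM count")
  if (n_rest > 0) {
    cand <- setdiff(pr$promoter_id[pr$class == "gene" & !pr$in_block], dm_id)
    rest <- sample(cand, n_rest)
    hyper_left <- max(0, min(n_rest, n_hyper - sum(dm_dir == "hyper")))
    rdir <- c(rep("hyper", hyper_left), rep("hypo", n_rest - hyper_left))
    dm_id <- c(dm_id, rest)
    dm_dir <- c(dm_dir, rdir)
  }

  i <- match(dm_id, pr$promoter_id)
  dm <- data.frame(promoter_id = dm_id, gene_id = pr$gene_id[i],
                   class = pr$class[i],
                   delta = ifelse(dm_dir == "hyper", 1, -1) * config$effect_size,
                   direction = dm_dir, stringsAsFactors = FALSE)
  truth <- list(dm = dm, dm_mirnas = dm_mirnas, cluster_blocks = used_blocks)
  class(truth) <- "sim_truth"
  truth
}

#' Simulate raw two-channel MeDIP arrays
#'
#' For every array and probe, the input (Cy3) channel is drawn log-normal and
#' the bound (Cy5) channel is `input * 2^level`, where the log2 level is the
#' promoter baseline plus per-probe jitter, the planted group effect for DM
#' promoters in case individuals, an independent per-individual biological
#' effect, per-array replicate noise, and (optionally) a smooth
#' intensity-dependent dye bias. Each individual gets `n_replicates` arrays.
#'
#' @param layout a `genome_layout`.
#' @param truth a `sim_truth` (use `simulate_truth`); its promoters must all
#'   exist in the layout.
#' @param config a [sim_config()].
#' @return A list of class `medip_arrays` with `bound` and `input` matrices
#'   (probes x arrays) and a `sheet` data frame (array_id, individual_id,
#'   replicate, group, child_SEP, adult_SEP).
#' @export
simulate_arrays <- function(layout, truth, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (!all(truth$dm$promoter_id %in% layout$promoters$promoter_id))
    .stopf("truth refers to promoters absent from the layout")
  set.seed(config$seed + 2L)

  n_ind <- config$n_case + config$n_control
  ind_id <- sprintf("I%03d", seq_len(n_ind))
  group <- c(rep("case", config$n_case), rep("control", config$n_control))
  n_arr <- n_ind * config$n_replicates
  sheet <- data.frame(
    array_id = sprintf("A%03d", seq_len(n_arr)),
    individual_id = rep(ind_id, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), n_ind),
    group = rep(group, each = config$n_replicates),
    child_SEP = rep(sample(c("low", "high"), n_ind, replace = TRUE),
                    each = config$n_replicates),
    adult_SEP = rep(sample(c("low", "high"), n_ind, replace = TRUE),
                    each = config$n_replicates),
    stringsAsFactors = FALSE
  )

  pb <- layout$probes
  np <- nrow(pb)
  prom_idx <- match(pb$promoter_id, layout$promoters$promoter_id)
  base_prom <- rnorm(nrow(layout$promoters), config$baseline_mean,
                     config$baseline_sd)
  m <- base_prom[prom_idx] + rnorm(np, 0, config$probe_jitter_sd)

  delta_probe <- numeric(np)
  hit <- match(pb$promoter_id, truth$dm$promoter_id)
  delta_probe[!is.na(hit)] <- truth$dm$delta[hit[!is.na(hit)]]

  ind_eff <- matrix(rnorm(np * n_ind, 0, config$individual_sd), np, n_ind)
  is_case <- group == "case"
  # true log2 level per (probe, individual)
  mu <- m + ind_eff + outer(delta_probe, as.numeric(is_case))

  arr_ind <- match(sheet$individual_id, ind_id)
  level <- mu[, arr_ind] + matrix(rnorm(np * n_arr, 0, config$replicate_sd),
                                  np, n_arr)
  input <- matrix(rlnorm(np * n_arr, config$input_meanlog, config$input_sdlog),
                  np, n_arr)
  if (config$dye_bias_amplitude != 0) {
    a <- 2 * log2(input) + level  # approximate A = log2(Cy5*Cy3)
    a_c <- sweep(a, 2, apply(a, 2, median))
    a_s <- sweep(a_c, 2, apply(a, 2, function(z) max(stats::IQR(z), 1e-8)), "/")
    level <- level + config$dye_bias_amplitude * a_s
  }
  bound <- input * 2^level
  dimnames(bound) <- dimnames(input) <- list(pb$probe_id, sheet$array_id)

  out <- list(bound = bound, input = input, sheet = sheet)
  class(out) <- "medip_arrays"
  out
}

#' Generate a miRNA-to-target-gene map with planted consistency
#'
#' Every miRNA promoter in the layout receives `n_targets_per_mirna` target
#' genes drawn from the layout's gene universe. For a subset of the planted
#' hypermethylated DM miRNAs (the "consistent" ones) targets are drawn with
#' sampling odds `consistency_odds` in favour of genes whose promoters are
#' planted hypomethylated, emulating a hypermethylated (silenced) miRNA whose
#' targets are coordinately de-repressed. All other miRNAs draw targets
#' uniformly.
#'
#' @param layout a `genome_layout`.
#' @param truth a `sim_truth`.
#' @param config a [sim_config()].
#' @return A data frame (mirna_id, gene_id) of class `target_map`, with the
#'   planted consistent miRNA ids in `attr(, "consistent_mirnas")`.
#' @export
generate_target_map <- function(layout, truth, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(truth, "sim_truth"))
  pr <- layout$promoters
  mirnas <- pr$gene_id[pr$class == "miRNA"]
  if (!length(mirnas)) .stopf("layout contains no miRNA promoters")
  genes <- pr$gene_id[pr$class == "gene"]
  if (config$n_targets_per_mirna > length(genes))
    .stopf("requested target-set size (%d) exceeds gene count (%d)",
           config$n_targets_per_mirna, length(genes))
  set.seed(config$seed + 3L)

  hyper_mirna_prom <- truth$dm$promoter_id[truth$dm$class == "miRNA" &
                                             truth$dm$direction == "hyper"]
  n_cons <- min(config$n_consistent_mirnas, length(hyper_mirna_prom))
  cons_prom <- head(hyper_mirna_prom, n_cons)
  cons_mirna <- pr$gene_id[match(cons_prom, pr$promoter_id)]

  hypo_genes <- truth$dm$gene_id[truth$dm$class == "gene" &
                                   truth$dm$direction == "hypo"]
  w <- ifelse(genes %in% hypo_genes, config$consistency_odds, 1)

  res <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    if (mirnas[i] %in% cons_mirna) {
      tg <- sample(genes, config$n_targets_per_mirna, prob = w)
    } else {
      tg <- sample(genes, config$n_targets_per_mirna)
    }
    res[[i]] <- data.frame(mirna_id = mirnas[i], gene_id = sort(tg),
                           stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, res)
  attr(map, "consistent_mirnas") <- cons_mirna
  class(map) <- c("target_map", "data.frame")
  map
}

#' Simulate a complete synthetic MeDIP-chip dataset
#'
#' Convenience wrapper running [generate_genome_layout()], [simulate_truth()],
#' [simulate_arrays()] and [generate_target_map()] under one configuration.
#' The entire dataset is a deterministic function of `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of class `medip_dataset` with elements `layout`, `truth`,
#'   `arrays`, `target_map` and `config`.
#' @export
simulate_medip_dataset <- function(config = sim_config()) {
  layout <- generate_genome_layout(config)
  truth <- simulate_truth(layout, config)
  arrays <- simulate_arrays(layout, truth, config)
  map <- if (any(layout$promoters$class == "miRNA"))
    generate_target_map(layout, truth, config) else NULL
  out <- list(layout = layout, truth = truth, arrays = arrays,
              target_map = map, config = config)
  class(out) <- "medip_dataset"
  out
}

#' Simulate gene sets with planted enrichment
#'
#' Builds a small gene-set collection over the layout's gene universe for
#' testing enrichment code: `n_enriched` sets oversample planted DM genes
#' with the given odds, the rest are uniform draws.
#'
#' @param layout a `genome_layout`.
#' @param truth a `sim_truth`.
#' @param n_sets,set_size number and size of sets.
#' @param n_enriched how many sets oversample DM genes.
#' @param odds sampling odds for DM genes in enriched sets.
#' @param seed integer seed.
#' @return A named list of character vectors.
#' @export
simulate_gene_sets <- function(layout, truth, n_sets = 20, set_size = 100,
                               n_enriched = 2, odds = 5, seed = 1L) {
  set.seed(seed)
  genes <- layout$promoters$gene_id[layout$promoters$class == "gene"]
  dm <- truth$dm$gene_id
  w <- ifelse(genes %in% dm, odds, 1)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    sets[[i]] <- if (i <= n_enriched) sample(genes, set_size, prob = w)
                 else sample(genes, set_size)
  }
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  sets
}

#' Simulate promoter sequences with class-specific CpG density
#'
#' Generates one sequence per promoter (covering the tiled -1000..+250
#' region) from a first-order Markov chain whose C-to-G transition is damped
#' so that the normalized CpG frequency (observed/expected) approximates a
#' per-promoter target: `ratio_hypo` for planted hypomethylated promoters,
#' `ratio_hyper` for hypermethylated ones and `ratio_default` elsewhere. The
#' defaults mirror the CpG-density contrast this pipeline is meant to detect
#' (high CpG density in hypomethylated promoters).
#'
#' @param layout a `genome_layout`.
#' @param truth optional `sim_truth`; without it all promoters use
#'   `ratio_default`.
#' @param length sequence length in bp.
#' @param gc GC content of the base composition.
#' @param ratio_default,ratio_hypo,ratio_hyper target observed/expected CpG
#'   frequencies by promoter class.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] named by promoter id.
#' @export
simulate_promoter_sequences <- function(layout, truth = NULL, length = 1250,
                                        gc = 0.5, ratio_default = 0.42,
                                        ratio_hypo = 0.86, ratio_hyper = 0.38,
                                        seed = 1L) {
  set.seed(seed)
  pr <- layout$promoters
  n <- nrow(pr)
  rho <- rep(ratio_default, n)
  if (!is.null(truth)) {
    i <- match(truth$dm$promoter_id, pr$promoter_id)
    rho[i] <- ifelse(truth$dm$direction == "hypo", ratio_hypo, ratio_hyper)
  }
  pG <- gc / 2
  pC <- gc / 2
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cum_base <- cumsum(base)
  # after-C G-transition g solving rho = g / ((1-pC) pG + pC g), so the
  # realized obs/expected CpG ratio matches the per-promoter target
  g_after_c <- rho * (1 - pC) * pG / pmax(1 - rho * pC, 1e-6)
  g_after_c <- pmin(g_after_c, 0.95)
  rest <- (1 - g_after_c) / (1 - pG)
  cum_c1 <- rest * base["A"]
  cum_c2 <- cum_c1 + rest * base["C"]
  cum_c3 <- cum_c2 + g_after_c

  letters4 <- c("A", "C", "G", "T")
  seqm <- matrix("", n, length)
  state <- findInterval(runif(n), cum_base) + 1L
  seqm[, 1] <- letters4[state]
  for (j in 2:length) {
    u <- runif(n)
    nxt <- findInterval(u, cum_base) + 1L
    isC <- state == 2L
    if (any(isC)) {
      uc <- u[isC]
      nxt[isC] <- 1L + (uc >= cum_c1[isC]) + (uc >= cum_c2[isC]) +
        (uc >= cum_c3[isC])
    }
    seqm[, j] <- letters4[nxt]
    state <- nxt
  }
  seqs <- apply(seqm, 1, paste0, collapse = "")
  Biostrings::DNAStringSet(setNames(seqs, pr$promoter_id))
}
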