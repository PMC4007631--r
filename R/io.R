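#' Write / read the probe annotation table
#'
#' The annotation is a BED-like TSV with 0-based half-open coordinates and
#' columns chrom, start, end, probe_id, promoter_id, gene_id, class, strand,
#' offset (the probe's offset from the promoter TSS, which makes the layout
#' reconstructible). `read_probe_annotation` validates coordinates
#' (start < end), rejects duplicate probe ids and malformed rows with the
#' offending line number, and groups probes by promoter.
#'
#' @param layout a `genome_layout`.
#' @param path TSV file path.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent the observed maximum coordinate is used.
#' @return `write_probe_annotation` the path, invisibly;
#'   `read_probe_annotation` a `genome_layout`.
#' @export
write_probe_annotation <- function(layout, path) {
  pb <- layout$probes
  pr <- layout$promoters
  i <- match(pb$promoter_id, pr$promoter_id)
  out <- data.frame(chrom = pb$chrom, start = pb$start, end = pb$end,
                    probe_id = pb$probe_id, promoter_id = pb$promoter_id,
                    gene_id = pr$gene_id[i], class = pr$class[i],
                    strand = pr$strand[i], offset = pb$offset)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_annotation
#' @export
read_probe_annotation <- function(path, chrom_lengths = NULL) {
  d <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                error = function(e) .stopf("cannot parse %s: %s", path,
                                           conditionMessage(e)))
  need <- c("chrom", "start", "end", "probe_id", "promoter_id", "gene_id",
            "class", "strand", "offset")
  if (!all(need %in% names(d)))
    .stopf("annotation lacks column(s): %s",
           paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(!is.finite(d$start) | !is.finite(d$end) | d$start >= d$end)
  if (length(bad))
    .stopf("malformed annotation row(s) (start >= end or non-numeric) at line(s): %s",
           paste(head(bad + 1L, 5), collapse = ", "))
  dup <- which(duplicated(d$probe_id))
  if (length(dup))
    .stopf("duplicate probe_id at line(s): %s",
           paste(head(dup + 1L, 5), collapse = ", "))

  # reconstruct TSS from the offset: plus strand probes start at tss+offset,
  # minus strand probes end at tss-offset
  tss <- ifelse(d$strand == "+", d$start - d$offset, d$end + d$offset)
  first <- !duplicated(d$promoter_id)
  promoters <- data.frame(promoter_id = d$promoter_id[first],
                          gene_id = d$gene_id[first],
                          chrom = d$chrom[first], tss = tss[first],
                          strand = d$strand[first], class = d$class[first],
                          stringsAsFactors = FALSE)
  promoters <- promoters[order(match(promoters$chrom, unique(d$chrom)),
                               promoters$tss), ]
  rownames(promoters) <- NULL
  chroms <- unique(d$chrom)
  lens <- if (!is.null(chrom_lengths)) unname(chrom_lengths[chroms])
          else vapply(chroms, function(ch) max(d$end[d$chrom == ch]), 0)
  layout <- list(
    chromosomes = data.frame(name = chroms, length = lens,
                             stringsAsFactors = FALSE),
    promoters = promoters,
    probes = data.frame(probe_id = d$probe_id, promoter_id = d$promoter_id,
                        chrom = d$chrom, start = as.numeric(d$start),
                        end = as.numeric(d$end), offset = d$offset,
                        stringsAsFactors = FALSE),
    blocks = NULL
  )
  class(layout) <- "genome_layout"
  layout
}

#' Write / read the sample sheet
#'
#' TSV with columns array_id, individual_id, replicate, group and optional
#' covariates. Reading validates unique array ids and a binary group label.
#'
#' @param sheet sample-sheet data frame.
#' @param path TSV path.
#' @return The path, invisibly / the validated data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "individual_id", "replicate", "group")
  if (!all(need %in% names(d)))
    .stopf("sample sheet lacks column(s): %s",
           paste(setdiff(need, names(d)), collapse = ", "))
  if (anyDuplicated(d$array_id)) .stopf("duplicate array_id in sample sheet")
  if (length(unique(d$group)) != 2)
    .stopf("group label must be binary (found: %s)",
           paste(unique(d$group), collapse = ", "))
  d
}

#' Write per-array intensity tables
#'
#' One TSV per array (named `<array_id>.tsv`) with columns probe_id,
#' bound, input.
#'
#' @param arrays a `medip_arrays` object.
#' @param dir output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_intensities <- function(arrays, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(colnames(arrays$bound), ".tsv"))
  for (j in seq_along(paths)) {
    write.table(
      data.frame(probe_id = rownames(arrays$bound),
                 bound = arrays$bound[, j], input = arrays$input[, j]),
      paths[j], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Load aligned two-channel intensities
#'
#' Reads one intensity TSV per array listed in the sample sheet, verifies
#' that every array has a file and that all arrays cover the same probe set
#' (offenders are listed), and aligns rows by probe id regardless of row
#' order. Non-positive intensities are kept as-is and flagged into missing
#' log-ratios by [compute_log_ratios()].
#'
#' @param dir directory containing `<array_id>.tsv` files, or a named
#'   character vector of paths (names = array ids).
#' @param sheet a sample-sheet data frame or path.
#' @return A `medip_arrays` object (bound, input, sheet).
#' @export
load_arrays <- function(dir, sheet) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  paths <- if (length(dir) == 1 && dir.exists(dir))
    setNames(file.path(dir, paste0(sheet$array_id, ".tsv")), sheet$array_id)
  else dir
  missing <- sheet$array_id[!file.exists(paths[sheet$array_id])]
  if (length(missing))
    .stopf("missing intensity file(s) for array(s): %s",
           paste(head(missing, 5), collapse = ", "))

  tabs <- lapply(sheet$array_id, function(a)
    read.delim(paths[[a]], stringsAsFactors = FALSE))
  ref <- sort(tabs[[1]]$probe_id)
  for (j in seq_along(tabs)) {
    ids <- sort(tabs[[j]]$probe_id)
    if (!identical(ids, ref)) {
      off <- union(setdiff(ids, ref), setdiff(ref, ids))
      .stopf("probe set mismatch in array %s (e.g. %s)", sheet$array_id[j],
             paste(head(off, 5), collapse = ", "))
    }
  }
  probe_ids <- tabs[[1]]$probe_id
  bound <- vapply(tabs, function(t) t$bound[match(probe_ids, t$probe_id)],
                  numeric(length(probe_ids)))
  input <- vapply(tabs, function(t) t$input[match(probe_ids, t$probe_id)],
                  numeric(length(probe_ids)))
  dimnames(bound) <- dimnames(input) <- list(probe_ids, sheet$array_id)
  out <- list(bound = bound, input = input, sheet = sheet)
  class(out) <- "medip_arrays"
  out
}

#' Load a gene-set collection (GMT)
#'
#' Parses a GMT file (set name, description, tab-separated gene ids per
#' line). Gene ids are normalized to upper case; when a universe is given,
#' sets are restricted to it and sets left empty are dropped with a warning.
#'
#' @param path GMT file.
#' @param universe optional gene-id universe for filtering.
#' @return Named list of gene-id vectors.
#' @export
load_gene_sets <- function(path, universe = NULL) {
  sets <- lapply(fgsea::gmtPathways(path), toupper)
  if (!is.null(universe)) {
    universe <- toupper(universe)
    sets <- lapply(sets, intersect, y = universe)
    empty <- lengths(sets) == 0
    if (any(empty)) {
      warning(sprintf("dropping %d gene set(s) with no profiled genes",
                      sum(empty)))
      sets <- sets[!empty]
    }
  }
  if (any(lengths(sets) == 0)) {
    warning("dropping empty gene set(s)")
    sets <- sets[lengths(sets) > 0]
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of gene-id vectors.
#' @param path output GMT file.
#' @return The path, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a miRNA target map
#'
#' TSV with columns mirna_id, gene_id, one row per (miRNA, target) pair.
#' Gene ids are upper-cased on reading; with a universe, pairs whose gene is
#' not profiled are dropped.
#'
#' @param map data frame with mirna_id, gene_id.
#' @param path TSV path.
#' @param universe optional gene universe.
#' @return The path, invisibly / the data frame.
#' @export
write_target_map <- function(map, path) {
  write.table(as.data.frame(map)[c("mirna_id", "gene_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_map
#' @export
load_mirna_targets <- function(path, universe = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(d)))
    .stopf("target map needs mirna_id and gene_id columns")
  d$gene_id <- toupper(d$gene_id)
  if (!is.null(universe)) d <- d[d$gene_id %in% toupper(universe), ]
  d
}

#' Write the planted-truth tables of a synthetic dataset
#'
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @return Paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "truth_dm_promoters.tsv")
  write.table(truth$dm, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "truth_cluster_blocks.tsv")
  if (!is.null(truth$cluster_blocks))
    write.table(truth$cluster_blocks, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the probe annotation, per-array intensity tables, sample sheet,
#' target map and truth tables of a [simulate_medip_dataset()] bundle in the
#' TSV dialect the loaders read back.
#'
#' @param dataset a `medip_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_medip_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_annotation(dataset$layout, file.path(dir, "annotation.tsv"))
  write_sample_sheet(dataset$arrays$sheet, file.path(dir, "samples.tsv"))
  write_intensities(dataset$arrays, file.path(dir, "intensities"))
  write_target_map(dataset$target_map, file.path(dir, "targets.tsv"))
  write_truth(dataset$truth, dir)
  invisible(dir)
}

#' Write fit result tables
#'
#' Probe statistics and promoter calls as TSV files.
#'
#' @param fit a `medip_fit`.
#' @param dir output directory.
#' @return Paths, invisibly.
#' @export
write_fit_tables <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "probe_stats.tsv")
  p2 <- file.path(dir, "promoters.tsv")
  write.table(fit$probes, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fit$promoters, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
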