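#' Sliding-window enrichment of differentially methylated promoters
#'
#' Scans each chromosome with windows of `width` bp every `step` bp (plus a
#' final window flush with the chromosome end) and tests each window's
#' called-promoter count against the genome-wide rate with an upper-tail
#' hypergeometric test; FDR is adjusted across all retained windows. With
#' `by_chromosome = TRUE` each chromosome is a single window, the
#' chromosome-level variant of the scan. Promoters are assigned to windows
#' by their TSS; windows containing no promoter are skipped.
#'
#' @param fit a `medip_fit`.
#' @param layout the `genome_layout`.
#' @param width,step window width and step in bp (defaults 750 kb / 250 kb).
#' @param direction count all called promoters or only one direction.
#' @param by_chromosome treat each chromosome as one window.
#' @param mode call tier.
#' @return Data frame with chrom, start, end, n, k, p, q.
#' @export
window_enrichment <- function(fit, layout, width = 750000, step = 250000,
                              direction = c("any", "hyper", "hypo"),
                              by_chromosome = FALSE,
                              mode = c("default", "strict")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  col <- if (mode == "default") "called_default" else "called_strict"
  pm <- fit$promoters
  pr <- layout$promoters
  tested <- pr[pr$promoter_id %in% pm$promoter_id, ]
  idx <- match(tested$promoter_id, pm$promoter_id)
  called <- pm[[col]][idx]
  if (direction != "any") called <- called & pm$direction[idx] == direction

  N <- nrow(tested); K <- sum(called)
  res <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    ch <- layout$chromosomes$name[i]
    len <- layout$chromosomes$length[i]
    sel <- tested$chrom == ch
    tss <- tested$tss[sel]
    cal <- called[sel]
    if (!length(tss)) return(NULL)
    if (by_chromosome) {
      starts <- 0
      ends <- len
    } else {
      starts <- seq(0, max(0, len - width), by = step)
      if (max(starts) + width < len) starts <- c(starts, len - width)
      ends <- starts + width
    }
    o <- order(tss)
    tss_s <- tss[o]; cal_s <- cal[o]
    ck <- cumsum(cal_s)
    lo <- findInterval(starts - 0.5, tss_s)       # promoters before window
    hi <- findInterval(ends - 0.5, tss_s)         # promoters before end
    n <- hi - lo
    k <- (c(0, ck)[hi + 1]) - (c(0, ck)[lo + 1])
    keep <- n > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               n = n[keep], k = k[keep],
               p = hypergeometric_tail(N, K, n[keep], k[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Distance-correlation profile of differential-methylation statistics
#'
#' Quantifies genomic clustering of differential methylation: for every
#' same-chromosome promoter pair whose TSS distance falls within
#' `max_dist`, the pair of representative-probe statistics enters the
#' Pearson correlation of its distance bin (both orientations included, so
#' the correlation is symmetric in the pair). 95% confidence intervals use
#' the Fisher z transform with the number of unordered pairs. Bins with
#' fewer than `min_pairs` pairs are omitted.
#'
#' @param fit a `medip_fit`.
#' @param layout the `genome_layout`.
#' @param bin_width,max_dist distance bin width and maximum distance in bp
#'   (defaults 500 kb / 2 Mb).
#' @param min_pairs minimum pairs per reported bin.
#' @return Data frame with bin_center, r, n_pairs, ci_low, ci_high.
#' @export
distance_correlation <- function(fit, layout, bin_width = 500000,
                                 max_dist = 2000000, min_pairs = 10) {
  pm <- fit$promoters
  pr <- layout$promoters
  stat <- setNames(
    fit$probes$t_mod[match(pm$representative_probe_id, fit$probes$probe_id)],
    pm$promoter_id)
  tested <- pr[pr$promoter_id %in% pm$promoter_id, ]

  xs <- numeric(0); ys <- numeric(0); ds <- numeric(0)
  for (ch in unique(tested$chrom)) {
    sel <- tested[tested$chrom == ch, ]
    if (nrow(sel) < 2) next
    o <- order(sel$tss)
    tss <- sel$tss[o]
    st <- stat[sel$promoter_id[o]]
    hi <- findInterval(tss + max_dist, tss)
    for (i in seq_len(length(tss) - 1)) {
      if (hi[i] <= i) next
      j <- (i + 1):hi[i]
      xs <- c(xs, rep(st[i], length(j)))
      ys <- c(ys, st[j])
      ds <- c(ds, tss[j] - tss[i])
    }
  }
  if (!length(ds)) return(NULL)
  bin <- pmin(floor(ds / bin_width), ceiling(max_dist / bin_width) - 1)
  res <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    np <- sum(sel)
    if (np < min_pairs) {
      .msgf("distance bin %d omitted (%d pairs < %d)", b, np, min_pairs)
      return(NULL)
    }
    r <- cor(c(xs[sel], ys[sel]), c(ys[sel], xs[sel]))
    z <- atanh(max(min(r, 1 - 1e-12), -1 + 1e-12))
    se <- 1 / sqrt(max(np - 3, 1))
    data.frame(bin_center = (b + 0.5) * bin_width, r = r, n_pairs = np,
               ci_low = min(tanh(z - 1.96 * se), r),
               ci_high = max(tanh(z + 1.96 * se), r))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Promoter CpG density (observed/expected)
#'
#' Computes the normalized CpG frequency of each promoter sequence,
#' `(#CpG x L) / (#C x #G)` — the observed CpG dinucleotide count relative
#' to what the sequence's own C and G composition predicts (values >= 0.6
#' conventionally mark CpG islands) — and compares the planted call groups:
#' group means for all, hypermethylated and hypomethylated promoters, with
#' two-sided Welch t-tests between groups. Promoters whose region has no C
#' or no G are excluded (count reported).
#'
#' @param seqs a [Biostrings::DNAStringSet] named by promoter id, or a path
#'   to a FASTA file of promoter sequences.
#' @param calls the `promoters` table of a `medip_fit` (promoter_id,
#'   direction, called column), or NULL for densities only.
#' @param mode call tier.
#' @return A list with `per_promoter` (promoter_id, cpg_ratio, group),
#'   `group_means`, and `tests` (Welch t-test p-values between groups).
#' @export
cpg_density <- function(seqs, calls = NULL, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  n_cg <- Biostrings::vcountPattern("CG", seqs)
  comp <- Biostrings::letterFrequency(seqs, c("C", "G"))
  L <- Biostrings::width(seqs)
  ok <- comp[, "C"] > 0 & comp[, "G"] > 0
  if (any(!ok))
    .msgf("excluding %d promoter(s) with no C or no G", sum(!ok))
  ratio <- rep(NA_real_, length(seqs))
  ratio[ok] <- n_cg[ok] * L[ok] / (comp[ok, "C"] * comp[ok, "G"])

  grp <- rep("all", length(seqs))
  if (!is.null(calls)) {
    col <- if (mode == "default") "called_default" else "called_strict"
    i <- match(names(seqs), calls$promoter_id)
    called <- !is.na(i) & calls[[col]][i]
    grp[called] <- calls$direction[i[called]]
  }
  per <- data.frame(promoter_id = names(seqs), cpg_ratio = ratio,
                    group = grp, stringsAsFactors = FALSE)
  per <- per[!is.na(per$cpg_ratio), ]

  means <- c(all = mean(per$cpg_ratio),
             hyper = mean(per$cpg_ratio[per$group == "hyper"]),
             hypo = mean(per$cpg_ratio[per$group == "hypo"]))
  tests <- NULL
  welch <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    stats::t.test(a, b)$p.value
  }
  if (!is.null(calls)) {
    hypo <- per$cpg_ratio[per$group == "hypo"]
    hyper <- per$cpg_ratio[per$group == "hyper"]
    tests <- data.frame(
      comparison = c("hypo_vs_all", "hyper_vs_all", "hypo_vs_hyper"),
      p = c(welch(hypo, per$cpg_ratio), welch(hyper, per$cpg_ratio),
            welch(hypo, hyper)))
  }
  list(per_promoter = per, group_means = means, tests = tests)
}

#' Write a UCSC variableStep wiggle track of group differences
#'
#' Emits the per-probe case-minus-control mean difference as a UCSC wiggle
#' track (variableStep, 1-based positions, span = probe length), one section
#' per chromosome, probes sorted by position.
#'
#' @param diff named numeric vector of per-probe differences (names = probe
#'   ids), e.g. `coef(fit)`.
#' @param layout the `genome_layout`.
#' @param path output file.
#' @param name track name.
#' @return The path, invisibly.
#' @export
write_wiggle <- function(diff, layout, path, name = "medip_diff") {
  pb <- layout$probes[layout$probes$probe_id %in% names(diff), ]
  pb$value <- diff[pb$probe_id]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s"', name), con)
  for (ch in unique(layout$chromosomes$name)) {
    sel <- pb[pb$chrom == ch, ]
    if (!nrow(sel)) next
    sel <- sel[order(sel$start), ]
    span <- unique(sel$end - sel$start)
    if (length(span) > 1) span <- min(span)
    writeLines(sprintf("variableStep chrom=%s span=%d", ch, as.integer(span)),
               con)
    writeLines(sprintf("%d\t%.10g", as.integer(sel$start + 1), sel$value),
               con)
  }
  invisible(path)
}

#' Read a variableStep wiggle track
#'
#' Minimal parser for the files produced by [write_wiggle()] (and any
#' variableStep track): returns the (chromosome, 1-based position, span,
#' value) records.
#'
#' @param path wiggle file.
#' @return Data frame with chrom, pos, span, value.
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  chrom <- NA_character_; span <- 1L
  pos <- numeric(0); val <- numeric(0)
  cur_ch <- character(0); cur_sp <- integer(0)
  for (ln in lines) {
    if (startsWith(ln, "track")) next
    if (startsWith(ln, "variableStep")) {
      chrom <- sub('.*chrom=(\\S+).*', "\\1", ln)
      span <- if (grepl("span=", ln))
        as.integer(sub(".*span=(\\d+).*", "\\1", ln)) else 1L
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    pos <- c(pos, as.numeric(f[1])); val <- c(val, as.numeric(f[2]))
    cur_ch <- c(cur_ch, chrom); cur_sp <- c(cur_sp, span)
  }
  data.frame(chrom = cur_ch, pos = pos, span = cur_sp, value = val,
             stringsAsFactors = FALSE)
}
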