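#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` "interesting" elements in a draw of
#' `n` from a universe of `N` containing `K` interesting elements:
#' `P = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)` (computed via the stable
#' log-space routine underlying [stats::phyper()]). `k = 0` gives `p = 1`.
#'
#' @param N universe size.
#' @param K interesting elements in the universe.
#' @param n draw size.
#' @param k observed overlap.
#' @return Upper-tail probability; vectorized over its arguments.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  bad <- k > pmin(n, K) | pmin(n, K) > N | k < 0 | K < 0 | n < 0 | n > N
  if (any(bad)) .stopf("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# one enrichment record per set
.enrich_records <- function(sets, interesting, universe) {
  N <- length(universe)
  K <- length(intersect(interesting, universe))
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (!length(s)) return(NULL)
    k <- length(intersect(s, interesting))
    data.frame(unit_id = nm, N = N, K = K, n = length(s), k = k,
               p = hypergeometric_tail(N, K, length(s), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(out)) out$q <- bh_fdr(out$p)
  out
}

#' Hypergeometric gene-set enrichment of differentially methylated genes
#'
#' For each gene set, tests the overlap with the differentially methylated
#' genes against the measured universe, separately for all DM genes, the
#' hypomethylated ones, and the hypermethylated ones (three analyses, as the
#' reference tables report them). FDR is adjusted across sets within each
#' analysis. Sets disjoint from the universe are skipped.
#'
#' @param called a list with `any`, `hypo`, `hyper` gene-id vectors (see
#'   [dm_genes()]).
#' @param universe gene ids of all genes with profiled promoters.
#' @param gene_sets named list of gene-id vectors (see [load_gene_sets()]).
#' @return Data frame with unit_id, context, N, K, n, k, p, q.
#' @export
gene_set_enrichment <- function(called, universe, gene_sets) {
  res <- lapply(c("any", "hypo", "hyper"), function(ctx) {
    r <- .enrich_records(gene_sets, called[[ctx]], universe)
    if (!is.null(r)) r$context <- ctx
    r
  })
  out <- do.call(rbind, res)
  out[c("unit_id", "context", "N", "K", "n", "k", "p", "q")]
}

#' miRNA-target consistency analysis
#'
#' For every differentially methylated miRNA, tests whether its target genes
#' are enriched for hypomethylated promoters: `n` targets within the
#' measured universe, `k` of them called hypomethylated, against `K` (all
#' hypomethylated genes) of `N` (universe), upper-tail hypergeometric; the
#' hypermethylated target count is reported alongside. FDR is adjusted
#' across the tested miRNAs. A miRNA is flagged `consistent` when it is
#' itself hypermethylated and the hypomethylated-target enrichment passes
#' `q < q_cut` — the epigenetically coherent configuration of a silenced
#' miRNA with de-repressed targets.
#'
#' @param fit a `medip_fit`.
#' @param layout the `genome_layout`.
#' @param target_map data frame with `mirna_id`, `gene_id` columns.
#' @param q_cut FDR threshold of the consistency flag (default 0.2, the
#'   pipeline's discovery FDR convention).
#' @param mode call tier used for both miRNA and gene calls.
#' @return Data frame with one row per tested miRNA: mirna_id, direction,
#'   n_targets, k_hypo, k_hyper, N, K, p, q, consistent.
#' @export
mirna_target_consistency <- function(fit, layout, target_map, q_cut = 0.2,
                                     mode = c("default", "strict")) {
  mode <- match.arg(mode)
  col <- if (mode == "default") "called_default" else "called_strict"
  pm <- fit$promoters
  pr <- layout$promoters

  mir <- pr[pr$class == "miRNA", ]
  mcall <- pm[match(mir$promoter_id, pm$promoter_id), ]
  dm_mir <- mir$gene_id[!is.na(mcall[[col]]) & mcall[[col]]]
  if (!length(dm_mir)) {
    .msgf("no differentially methylated miRNAs to test")
    return(NULL)
  }
  mdir <- setNames(mcall$direction[!is.na(mcall[[col]]) & mcall[[col]]], dm_mir)

  g <- dm_genes(fit, layout, mode = mode)
  universe <- setdiff(g$universe, mir$gene_id)
  hypo <- intersect(g$hypo, universe)
  hyper <- intersect(g$hyper, universe)
  N <- length(universe); K <- length(hypo)

  res <- lapply(dm_mir, function(mid) {
    tg <- intersect(unique(target_map$gene_id[target_map$mirna_id == mid]),
                    universe)
    if (!length(tg)) {
      .msgf("miRNA %s has no profiled targets; skipped", mid)
      return(NULL)
    }
    k <- length(intersect(tg, hypo))
    data.frame(mirna_id = mid, direction = unname(mdir[mid]),
               n_targets = length(tg), k_hypo = k,
               k_hyper = length(intersect(tg, hyper)),
               N = N, K = K,
               p = hypergeometric_tail(N, K, length(tg), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  out$q <- bh_fdr(out$p)
  out$consistent <- out$direction == "hyper" & out$q < q_cut
  out
}

#' Hypergeometric intersection test between two gene lists
#'
#' Upper-tail test of the overlap between a study's differential list and an
#' external (for instance cell-type-specific) list within a common universe.
#' The "no confound" criterion holds when the overlap is not
#' larger than expected, i.e. `p > threshold` (default 0.4).
#'
#' @param study_genes,other_genes gene-id vectors (subsets of `universe`).
#' @param universe the common universe.
#' @param threshold p-value above which the overlap is declared unremarkable.
#' @return A one-row data frame with N, K, n, k, p and `no_confound`.
#' @export
intersection_test <- function(study_genes, other_genes, universe,
                              threshold = 0.4) {
  study <- intersect(study_genes, universe)
  other <- intersect(other_genes, universe)
  if (!length(study) || !length(other)) {
    warning("empty list after universe filtering; p = 1")
    return(data.frame(N = length(universe), K = length(study),
                      n = length(other), k = 0L, p = 1,
                      no_confound = TRUE))
  }
  k <- length(intersect(study, other))
  p <- hypergeometric_tail(length(universe), length(study), length(other), k)
  data.frame(N = length(universe), K = length(study), n = length(other),
             k = k, p = p, no_confound = p > threshold)
}
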