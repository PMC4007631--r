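#' Wilcoxon rank-sum shift test of promoter statistics against the array
#'
#' Tests whether a promoter's probe statistics are shifted relative to the
#' distribution of all probes on the array (which, in the pipeline, includes
#' the promoter's own probes; at 13 of tens of thousands the overlap is
#' negligible and keeps the background identical for every promoter). When
#' both samples have at most 8 values the two-sided p-value is computed by
#' exhaustive enumeration of rank assignments; otherwise the normal
#' approximation with tie correction is used, with a continuity correction
#' when the background has more than 50 values.
#'
#' @param x the promoter's statistics (at least 2 values).
#' @param y the background statistics (all scored probes).
#' @return A list with `statistic` (the rank sum W of `x`), `p.value`
#'   (two-sided) and `direction` ("hyper" if `median(x) > median(y)`).
#' @export
promoter_shift_test <- function(x, y) {
  if (length(x) < 2) .stopf("promoter shift test needs >= 2 scored probes")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  if (m <= 8 && n <= 8) {
    p <- .exact_ranksum_p(c(x, y), m, w)
  } else {
    p <- .normal_ranksum_p(w, r, m, n, correct = n > 50)
  }
  list(statistic = w, p.value = p,
       direction = if (median(x) > median(y)) "hyper" else "hypo")
}

# exact two-sided p by enumeration of all C(m+n, m) assignments of the
# combined midranks; two-sided p doubles the smaller tail (capped at 1)
.exact_ranksum_p <- function(combined, m, w_obs) {
  r <- rank(combined)
  ws <- utils::combn(length(combined), m, FUN = function(i) sum(r[i]))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

.normal_ranksum_p <- function(w, r, m, n, correct = TRUE) {
  N <- m + n
  mu <- m * (N + 1) / 2
  # tie correction from the combined midranks
  tab <- tabulate(match(r, unique(r)))
  tiesum <- sum(tab^3 - tab)
  v <- m * n / 12 * ((N + 1) - tiesum / (N * (N - 1)))
  if (v <= 0) return(1)
  d <- w - mu
  cc <- if (correct) 0.5 else 0
  z <- (abs(d) - cc) / sqrt(v)
  if (z < 0) z <- 0
  min(1, 2 * pnorm(-z))
}

# Vectorized shift tests for all promoters against the full array, assuming
# (as in the pipeline) that each promoter's values are themselves members of
# the background vector. Midranks of the combined (background + promoter
# duplicate) sample are derived from the global background ranks in O(total
# probes), so a genome-wide scan costs one rank() of the background.
.shift_tests_bulk <- function(tmod, promoter) {
  N <- length(tmod)
  ry <- rank(tmod)

  # fast path: continuous statistics (no duplicated values) and a common
  # promoter size let everything collapse into rowsum/matrix operations
  cnt <- table(promoter)
  if (!anyDuplicated(tmod) && length(unique(cnt)) == 1L && all(cnt >= 2)) {
    m <- as.integer(cnt[1])
    o <- order(promoter)
    prom_ids <- names(cnt)
    wsum <- rowsum(ry, promoter)      # rows sorted like names(cnt)
    stopifnot(identical(rownames(wsum), prom_ids))
    wsum <- unname(wsum[, 1]) + m^2 / 2
    Ntot <- N + m
    mu <- m * (Ntot + 1) / 2
    vv <- m * N / 12 * ((Ntot + 1) - 6 * m / (Ntot * (Ntot - 1)))
    z <- pmax(0, (abs(wsum - mu) - 0.5) / sqrt(vv))
    pvals <- pmin(1, 2 * pnorm(-z))
    tm <- matrix(tmod[o], nrow = m)
    meds <- apply(tm, 2, median)
    dirs <- ifelse(meds > median(tmod), "hyper", "hypo")
    return(data.frame(promoter_id = prom_ids, n_probes = m,
                      shift_p = pvals, direction = dirs,
                      stringsAsFactors = FALSE))
  }
  o <- order(tmod)
  v <- tmod[o]
  runid <- cumsum(c(1L, as.integer(v[-1] != v[-N])))
  rl <- tabulate(runid)
  ey <- integer(N); ey[o] <- rl[runid]     # multiplicity of each value in y
  med_all <- median(tmod)

  idx_by_prom <- split(seq_len(N), promoter)
  prom_ids <- names(idx_by_prom)
  pvals <- numeric(length(prom_ids))
  dirs <- character(length(prom_ids))
  nps <- integer(length(prom_ids))

  for (g in seq_along(prom_ids)) {
    idx <- idx_by_prom[[g]]
    m <- length(idx)
    nps[g] <- m
    if (m < 2) { pvals[g] <- NA_real_; dirs[g] <- NA_character_; next }
    xv <- tmod[idx]
    eyx <- ey[idx]
    rx <- rank(xv)
    ex <- integer(m)
    ox <- order(xv); xs <- xv[ox]
    rid <- cumsum(c(1L, as.integer(xs[-1] != xs[-m])))
    rlx <- tabulate(rid)
    ex[ox] <- rlx[rid]
    # midrank of each x value in the combined sample (y plus x duplicated):
    # values below it in y, plus values below it in x, plus half the ties
    less_y <- ry[idx] - (eyx + 1) / 2
    less_x <- rx - (ex + 1) / 2
    mid <- less_y + less_x + (eyx + ex + 1) / 2
    w <- sum(mid)
    Ntot <- N + m
    mu <- m * (Ntot + 1) / 2
    # tie sum over the combined sample: background runs, with runs touched
    # by x enlarged from ey to ey + ex (counted once per distinct x value)
    first <- ox[match(unique(rid), rid)]
    e_y <- eyx[first]; e_x <- rlx
    S <- sum(rl^3 - rl) - sum(e_y^3 - e_y) + sum((e_y + e_x)^3 - (e_y + e_x))
    vv <- m * N / 12 * ((Ntot + 1) - S / (Ntot * (Ntot - 1)))
    if (vv <= 0) { pvals[g] <- 1 } else {
      z <- max(0, (abs(w - mu) - 0.5) / sqrt(vv))
      pvals[g] <- min(1, 2 * pnorm(-z))
    }
    dirs[g] <- if (median(xv) > med_all) "hyper" else "hypo"
  }
  data.frame(promoter_id = prom_ids, n_probes = nps, shift_p = pvals,
             direction = dirs, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment: `q_i = min over {j : p_j >= p_i}` of
#' `p_j * m / rank_j`, capped at 1. Input p-values must lie in (0, 1].
#'
#' @param p vector of p-values.
#' @return Vector of q-values, monotone non-decreasing in `p`.
#' @export
bh_fdr <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp <= 0 | pp > 1)) .stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Representative probe per promoter
#'
#' The probe "most associated" with the group contrast: smallest p-value,
#' ties broken by larger |log2 fold-difference|, then lexicographic probe id.
#'
#' @param stats probe statistics with probe_id, promoter_id, p, beta.
#' @return Data frame promoter_id, representative_probe_id.
#' @export
representative_probe <- function(stats) {
  o <- order(stats$promoter_id, stats$p, -abs(stats$beta), stats$probe_id)
  s <- stats[o, ]
  first <- !duplicated(s$promoter_id)
  data.frame(promoter_id = s$promoter_id[first],
             representative_probe_id = s$probe_id[first],
             stringsAsFactors = FALSE)
}

#' Two-tier promoter differential-methylation calls
#'
#' Combines the probe tier and the shift tier into the final promoter call.
#' Default mode: the promoter contains a called probe (p < `p_cut`,
#' |log2FC| >= `fc_cut`) and its shift-test FDR `q` is below `q_cut` (20%).
#' Strict mode: a member probe passes p < `strict_p` at the same fold-change
#' cut and `q` is below `strict_q` (5%). The two criteria are applied
#' independently; direction comes from the shift test.
#'
#' @param probe_stats probe table with promoter_id, p, beta, called columns
#'   (see [call_probes()]).
#' @param shift_tests data frame from the shift tier with promoter_id,
#'   shift_p, direction (see [promoter_shift_test()]).
#' @param p_cut,fc_cut,q_cut default-mode thresholds.
#' @param strict_p,strict_q strict-mode thresholds.
#' @return Data frame with one row per tested promoter: n_probes,
#'   has_dm_probe, shift_p, q, direction, called_default, called_strict,
#'   representative_probe_id.
#' @export
call_promoters <- function(probe_stats, shift_tests,
                           p_cut = 0.05, fc_cut = 0.25, q_cut = 0.20,
                           strict_p = 0.01, strict_q = 0.05) {
  st <- shift_tests[!is.na(shift_tests$shift_p), , drop = FALSE]
  st$q <- bh_fdr(st$shift_p)

  has_dm <- rowsum(as.numeric(probe_stats$called),
                   probe_stats$promoter_id)[, 1] > 0
  strict_probe <- rowsum(
    as.numeric(probe_stats$p < strict_p & abs(probe_stats$beta) >= fc_cut),
    probe_stats$promoter_id)[, 1] > 0
  st$has_dm_probe <- unname(has_dm[st$promoter_id])
  st$has_strict_probe <- unname(strict_probe[st$promoter_id])
  st$called_default <- st$has_dm_probe & st$q < q_cut
  st$called_strict <- st$has_strict_probe & st$q < strict_q

  rep <- representative_probe(probe_stats)
  st$representative_probe_id <-
    rep$representative_probe_id[match(st$promoter_id, rep$promoter_id)]
  attr(st, "thresholds") <- c(p_cut = p_cut, fc_cut = fc_cut, q_cut = q_cut,
                              strict_p = strict_p, strict_q = strict_q)
  st[c("promoter_id", "n_probes", "has_dm_probe", "shift_p", "q", "direction",
       "called_default", "called_strict", "representative_probe_id")]
}

#' Hierarchical clustering of individuals on called promoters
#'
#' Clusters the individual columns of a methylation matrix with Ward's
#' method on Pearson correlation distance (1 - r). Constant (zero-variance)
#' columns, whose correlation is undefined, are flagged and given distance 1
#' to every other column.
#'
#' @param x matrix restricted to the rows of interest (typically the
#'   representative probes of called promoters) x individuals.
#' @return A list with `hclust` (the tree), `order` (leaf order as column
#'   names) and `flagged` (constant columns).
#' @export
cluster_samples <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2, nrow(x) >= 2)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  flagged <- colnames(x)[!is.finite(sds) | sds == 0]
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  d <- 1 - r
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "ward.D2")
  list(hclust = hc, order = colnames(x)[hc$order], flagged = flagged)
}
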