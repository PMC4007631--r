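#' Fit the two-group differential-methylation model
#'
#' The central fitting function. Given a replicate-averaged, normalized
#' methylation matrix (probes x individuals), the two-group labels and the
#' promoter layout, it:
#'
#' 1. fits the per-probe two-group model ([fit_group_model()]);
#' 2. estimates the empirical-Bayes variance prior and computes moderated
#'    t-statistics and p-values ([estimate_eb_hyperparameters()],
#'    [moderated_t()]);
#' 3. calls probes at `p < p_cut` and `|log2FC| >= fc_cut`
#'    ([call_probes()]);
#' 4. runs the promoter shift tier (rank-sum of each promoter's moderated
#'    t-statistics against all scored probes), adjusts across promoters by
#'    Benjamini-Hochberg, and issues the two-tier promoter calls at FDR <
#'    `q_cut` (default) and at `strict_p`/`strict_q` (strict)
#'    ([call_promoters()]).
#'
#' Promoters with fewer than 2 scored probes are skipped (count reported).
#'
#' @param x probes x individuals matrix; rownames are probe ids present in
#'   `layout$probes`.
#' @param group vector of length `ncol(x)` with two levels; `case` names the
#'   case group.
#' @param layout a `genome_layout` (or any list with a `probes` data frame
#'   carrying probe_id and promoter_id).
#' @param p_cut,fc_cut probe-tier thresholds (p < 0.05, |log2FC| >= 0.25).
#' @param q_cut promoter FDR threshold of the default call (20%).
#' @param strict_p,strict_q strict-mode thresholds (probe p < 0.01,
#'   promoter FDR < 5%).
#' @param case label of the case group in `group`.
#' @return An object of class `medip_fit` with components `probes` (probe
#'   statistics and calls), `promoters` (two-tier promoter calls), `hyper`
#'   (EB hyperparameters d0 and s0_2), `thresholds`, `group`, and counts.
#' @seealso [summary.medip_fit()], [coef.medip_fit()], [plot.medip_fit()],
#'   [permutation_percentile()]
#' @export
medip_fit <- function(x, group, layout,
                      p_cut = 0.05, fc_cut = 0.25, q_cut = 0.20,
                      strict_p = 0.01, strict_q = 0.05, case = "case") {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x))) .stopf("'x' needs probe ids as rownames")
  probes <- layout$probes
  keep <- rownames(x) %in% probes$probe_id
  if (!all(keep)) {
    .msgf("dropping %d probe(s) absent from the layout", sum(!keep))
    x <- x[keep, , drop = FALSE]
  }

  fitp <- fit_group_model(x, group, case = case)
  dfs <- fitp$df
  df_main <- max(dfs)
  est_ok <- dfs == df_main & is.finite(fitp$s2) & fitp$s2 > 0
  hyper <- estimate_eb_hyperparameters(fitp$s2[est_ok], df_main)
  mod <- moderated_t(fitp$beta, fitp$s2, fitp$df, hyper, fitp$n1, fitp$n2)
  stats <- cbind(fitp, mod)
  stats$promoter_id <- probes$promoter_id[match(stats$probe_id,
                                                probes$probe_id)]
  stats <- call_probes(stats, p_cut = p_cut, fc_cut = fc_cut)

  shifts <- .shift_tests_bulk(stats$t_mod, stats$promoter_id)
  n_skip <- sum(is.na(shifts$shift_p))
  if (n_skip > 0)
    .msgf("skipping %d promoter(s) with < 2 scored probes", n_skip)
  proms <- call_promoters(stats, shifts, p_cut = p_cut, fc_cut = fc_cut,
                          q_cut = q_cut, strict_p = strict_p,
                          strict_q = strict_q)

  out <- list(
    probes = stats,
    promoters = proms,
    hyper = hyper,
    thresholds = c(p_cut = p_cut, fc_cut = fc_cut, q_cut = q_cut,
                   strict_p = strict_p, strict_q = strict_q),
    group = setNames(as.character(group), colnames(x)),
    case = case,
    n_case = sum(group == case),
    n_control = sum(group != case),
    skipped_promoters = n_skip
  )
  class(out) <- "medip_fit"
  out
}

#' @export
print.medip_fit <- function(x, ...) {
  pm <- x$promoters
  cat("Two-group MeDIP differential-methylation fit\n")
  cat(sprintf("  %d probes in %d promoters; %d case vs %d control\n",
              nrow(x$probes), nrow(pm), x$n_case, x$n_control))
  cat(sprintf("  EB prior: d0 = %s, s0^2 = %.4g\n",
              format(x$hyper$d0, digits = 4), x$hyper$s0_2))
  cat(sprintf("  called promoters (FDR < %d%%): %d (%d hyper / %d hypo)\n",
              round(100 * x$thresholds["q_cut"]), sum(pm$called_default),
              sum(pm$called_default & pm$direction == "hyper"),
              sum(pm$called_default & pm$direction == "hypo")))
  cat(sprintf("  called promoters (strict): %d\n", sum(pm$called_strict)))
  invisible(x)
}

#' Summarize a differential-methylation fit
#'
#' @param object a `medip_fit`.
#' @param ... unused.
#' @return A list with probe- and promoter-level call counts, the
#'   hyper/hypo split, and the EB hyperparameters.
#' @export
summary.medip_fit <- function(object, ...) {
  pm <- object$promoters
  out <- list(
    n_probes = nrow(object$probes),
    n_promoters = nrow(pm),
    n_probes_called = sum(object$probes$called),
    n_called_default = sum(pm$called_default),
    n_called_strict = sum(pm$called_strict),
    n_hyper = sum(pm$called_default & pm$direction == "hyper"),
    n_hypo = sum(pm$called_default & pm$direction == "hypo"),
    hyper = object$hyper,
    thresholds = object$thresholds
  )
  class(out) <- "summary.medip_fit"
  out
}

#' @export
print.summary.medip_fit <- function(x, ...) {
  cat(sprintf(
    "probes: %d (%d called)\npromoters: %d\ncalled default: %d (%d hyper, %d hypo)\ncalled strict: %d\nEB prior: d0 = %s, s0^2 = %.4g\n",
    x$n_probes, x$n_probes_called, x$n_promoters, x$n_called_default,
    x$n_hyper, x$n_hypo, x$n_called_strict,
    format(x$hyper$d0, digits = 4), x$hyper$s0_2))
  invisible(x)
}

#' Probe-level effect sizes
#'
#' @param object a `medip_fit`.
#' @param ... unused.
#' @return Named vector of per-probe case-minus-control log2 differences.
#' @export
coef.medip_fit <- function(object, ...) {
  setNames(object$probes$beta, object$probes$probe_id)
}

#' Volcano plot of probe statistics
#'
#' Plots -log10 moderated p against the log2 fold-difference, marking the
#' probe-call thresholds and called probes.
#'
#' @param x a `medip_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.medip_fit <- function(x, ...) {
  s <- x$probes
  graphics::plot(s$beta, -log10(s$p),
                 pch = 16, cex = 0.3,
                 col = ifelse(s$called, "firebrick", "grey60"),
                 xlab = "log2 fold-difference (case - control)",
                 ylab = "-log10 moderated p", ...)
  graphics::abline(v = c(-1, 1) * x$thresholds["fc_cut"], lty = 2)
  graphics::abline(h = -log10(x$thresholds["p_cut"]), lty = 2)
  invisible(x)
}

#' Called genes by direction, with the measured universe
#'
#' Maps promoter calls to gene ids. The universe is every gene with at least
#' one scored promoter. A gene is hypo-/hypermethylated if any of its called
#' promoters has that direction (a gene with conflicting promoters counts in
#' both direction lists).
#'
#' @param fit a `medip_fit`.
#' @param layout the `genome_layout` used for the fit.
#' @param mode which call tier to use.
#' @return A list with `universe`, `any`, `hypo`, `hyper` character vectors
#'   of gene ids.
#' @export
dm_genes <- function(fit, layout, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  col <- if (mode == "default") "called_default" else "called_strict"
  pm <- fit$promoters
  pr <- layout$promoters
  gene_of <- pr$gene_id[match(pm$promoter_id, pr$promoter_id)]
  called <- pm[[col]]
  list(
    universe = unique(pr$gene_id[pr$promoter_id %in% pm$promoter_id]),
    any = unique(gene_of[called]),
    hypo = unique(gene_of[called & pm$direction == "hypo"]),
    hyper = unique(gene_of[called & pm$direction == "hyper"])
  )
}
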