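#' Random group partitions of the individuals
#'
#' Draws `n_partitions` mutually distinct case/control partitions, each
#' assigning exactly `n_case` individuals to the pseudo-case group, sampled
#' uniformly without replacement. Partitions identical to `exclude` (the
#' true labelling) are rejected and resampled.
#'
#' @param ids individual identifiers.
#' @param n_case pseudo-case group size.
#' @param n_partitions number of partitions.
#' @param seed optional integer seed.
#' @param exclude optional character vector of the true case ids; the
#'   identical partition is never returned.
#' @return A list of character vectors, each the ids of one pseudo-case
#'   group.
#' @export
random_partitions <- function(ids, n_case, n_partitions = 500, seed = NULL,
                              exclude = NULL) {
  n <- length(ids)
  if (n_case >= n) .stopf("n_case must be smaller than the number of ids")
  avail <- choose(n, n_case) - as.numeric(!is.null(exclude))
  if (n_partitions > avail)
    .stopf("requested %d partitions but only %g distinct ones available",
           n_partitions, avail)
  if (!is.null(seed)) set.seed(seed)
  truth_key <- if (!is.null(exclude)) paste(sort(exclude), collapse = "|")
  seen <- character(0)
  out <- vector("list", n_partitions)
  k <- 0L
  while (k < n_partitions) {
    cand <- sample(ids, n_case)
    key <- paste(sort(cand), collapse = "|")
    if (identical(key, truth_key) || key %in% seen) next
    k <- k + 1L
    seen <- c(seen, key)
    out[[k]] <- cand
  }
  out
}

#' Permutation significance of the genome-wide call count
#'
#' Re-runs the label-dependent stages of the pipeline (probe model, EB
#' hyperparameter estimation, moderated t, probe and promoter calls) for
#' each random partition of the individuals and compares the observed number
#' of default-mode promoter calls with the permutation distribution.
#' Normalization and replicate averaging are label-free and are not re-run.
#'
#' The reported `percentile` is the fraction of null counts *strictly* below
#' the observed count (ties count as not below, which is conservative).
#' `percentile_rand` additionally randomizes over ties and over the observed
#' count's own position, `(#below + U * (#ties + 1)) / (n + 1)`; under an
#' exchangeable null it is exactly uniform on (0, 1) and is the quantity to
#' use for calibration checks of a discrete count statistic.
#'
#' @param x probes x individuals matrix (normalized, replicate-averaged).
#' @param group true group labels for the columns of `x`.
#' @param layout the `genome_layout`.
#' @param n_partitions number of random partitions (the reference analysis
#'   used 500).
#' @param seed optional integer seed.
#' @param case label of the case group.
#' @param ... thresholds passed on to [medip_fit()].
#' @return An object of class `permutation_result`: observed count,
#'   `null_counts`, `percentile`, `percentile_rand`, `n_partitions`, `seed`.
#' @export
permutation_percentile <- function(x, group, layout, n_partitions = 500,
                                   seed = NULL, case = "case", ...) {
  ids <- colnames(x)
  n_case <- sum(group == case)
  observed_fit <- suppressMessages(medip_fit(x, group, layout, case = case, ...))
  observed <- sum(observed_fit$promoters$called_default)

  parts <- random_partitions(ids, n_case, n_partitions, seed = seed,
                             exclude = ids[group == case])
  null_counts <- vapply(parts, function(cs) {
    g <- ifelse(ids %in% cs, case, "control.")
    f <- suppressMessages(medip_fit(x, g, layout, case = case, ...))
    sum(f$promoters$called_default)
  }, integer(1))

  n_below <- sum(null_counts < observed)
  n_tie <- sum(null_counts == observed)
  out <- list(
    observed = observed,
    null_counts = null_counts,
    percentile = n_below / n_partitions,
    percentile_rand = (n_below + runif(1) * (n_tie + 1)) / (n_partitions + 1),
    n_partitions = n_partitions,
    seed = seed
  )
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation check: observed %d called promoters\n  larger than %d of %d random partitions (percentile %.3f)\n",
    x$observed, sum(x$null_counts < x$observed), x$n_partitions,
    x$percentile))
  invisible(x)
}
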