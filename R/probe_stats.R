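#' Per-probe two-group linear model
#'
#' For every probe computes the case-minus-control mean difference (the
#' probe-level log2 fold-difference) and the pooled within-group variance
#' with `n1 + n2 - 2` residual degrees of freedom. Probes with fewer than two
#' non-missing values in either group are excluded with a message.
#'
#' @param x probes x individuals matrix of (replicate-averaged) methylation
#'   scores.
#' @param group character/factor of length `ncol(x)`; the level given by
#'   `case` defines the case group.
#' @param case label identifying the case group.
#' @return Data frame with probe_id, beta, s2, df, n1, n2.
#' @export
fit_group_model <- function(x, group, case = "case") {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  group <- as.character(group)
  is_case <- group == case
  if (length(unique(group)) != 2)
    .stopf("'group' must have exactly two levels")
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    .stopf("each group needs at least 2 individuals")

  xc <- x[, is_case, drop = FALSE]
  xk <- x[, !is_case, drop = FALSE]
  n1 <- rowSums(!is.na(xc)); n2 <- rowSums(!is.na(xk))
  m1 <- rowMeans(xc, na.rm = TRUE); m2 <- rowMeans(xk, na.rm = TRUE)
  ss1 <- rowSums((xc - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((xk - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  keep <- n1 >= 2 & n2 >= 2
  if (!all(keep))
    .msgf("excluding %d probe(s) with a group entirely (or nearly) missing",
          sum(!keep))
  out <- data.frame(
    probe_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    beta = m1 - m2,
    s2 = ifelse(df > 0, (ss1 + ss2) / df, NA_real_),
    df = as.numeric(df), n1 = n1, n2 = n2,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Solve trigamma(x) = y by Newton iteration on 1/x-scale (monotone,
# convex); accurate over y in (~1e-8, ~1e8).
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & !is.na(y) & y <= 0] <- Inf
  x <- 0.5 + 1 / y[ok]
  for (it in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x), na.rm = TRUE) < 1e-10) break
  }
  out[ok] <- x
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments estimation of the prior degrees of freedom `d0` and
#' prior variance `s0_2` of a scaled inverse-chi-square prior on the
#' per-probe residual variances, performed on log variances: with
#' `e = log(s2) - digamma(df/2) + log(df/2)`, solve
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` by monotone root-finding and
#' set `s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the empirical
#' dispersion of the log variances does not exceed what sampling alone
#' explains, `d0` is `+Inf` and `s0_2 = exp(mean(e))`.
#'
#' Probes with zero (or missing) variance are excluded from estimation but
#' can still be scored by [moderated_t()].
#'
#' @param s2 vector of residual variances.
#' @param df scalar residual degrees of freedom shared by the probes used
#'   for estimation.
#' @return A list with `d0` (prior df, possibly `Inf`) and `s0_2`.
#' @export
estimate_eb_hyperparameters <- function(s2, df) {
  stopifnot(length(df) == 1L, df > 0)
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (!length(s2)) .stopf("all residual variances are zero: degenerate data")
  if (length(s2) < 100)
    warning("fewer than 100 positive variances; hyperparameters unstable")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_tilde = (d0 * s0_2 + df * s2) / (d0 + df)`, and computes
#' `t_mod = beta / sqrt(s2_tilde * (1/n1 + 1/n2))` with two-sided p-values
#' from the t distribution on `d0 + df` degrees of freedom (standard normal
#' when `d0` is infinite). With `d0 = 0` this is the ordinary pooled-variance
#' t-test. Probes with `s2_tilde = 0` get the smallest representable p-value
#' and are flagged in the `degenerate` column.
#'
#' @param beta per-probe group mean differences.
#' @param s2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar or per-probe).
#' @param hyper hyperparameters from [estimate_eb_hyperparameters()].
#' @param n1,n2 group sizes (scalar or per-probe).
#' @return Data frame with s2_tilde, t_mod, p, degenerate.
#' @export
moderated_t <- function(beta, s2, df, hyper, n1, n2) {
  d0 <- hyper$d0; s0 <- hyper$s0_2
  stopifnot(d0 >= 0, s0 > 0)
  s2t <- if (is.infinite(d0)) rep(s0, length(beta))
         else (d0 * s0 + df * s2) / (d0 + df)
  se2 <- s2t * (1 / n1 + 1 / n2)
  t <- beta / sqrt(se2)
  dft <- d0 + df
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df = dft)
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- sign(beta[degen]) * Inf
    t[degen & beta == 0] <- 0
    p[degen] <- .Machine$double.xmin
    p[degen & beta == 0] <- 1
  }
  data.frame(s2_tilde = s2t, t_mod = t, p = p, degenerate = degen)
}

#' Probe-level differential-methylation call
#'
#' A probe is called differentially methylated when its moderated-t p-value
#' is below `p_cut` and the absolute log2 fold-difference of the group means
#' is at least `fc_cut`; the direction is hypermethylated when the case
#' group is more methylated.
#'
#' @param stats data frame with at least `p` and `beta` (the log2
#'   fold-difference) columns, as produced by [fit_group_model()] +
#'   [moderated_t()].
#' @param p_cut,fc_cut call thresholds.
#' @return `stats` with `called` and `direction` columns appended.
#' @export
call_probes <- function(stats, p_cut = 0.05, fc_cut = 0.25) {
  stopifnot(all(c("p", "beta") %in% names(stats)))
  stats$called <- stats$p < p_cut & abs(stats$beta) >= fc_cut
  stats$direction <- ifelse(stats$beta > 0, "hyper", "hypo")
  attr(stats, "thresholds") <- c(p_cut = p_cut, fc_cut = fc_cut)
  stats
}
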