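#' Per-CpG-site validation statistics
#'
#' Site-level statistics for targeted (e.g. bisulfite pyrosequencing)
#' validation of a discovery screen: one t-test per CpG site with the
#' alternative direction fixed a priori from the screen, Benjamini-Hochberg
#' FDR across the sites of the region, and the conventional significance
#' tiers (`**` q < 0.025, `*` q < 0.05, `++` q < 0.1, `+` q < 0.2). Group
#' means and standard errors are reported for plotting.
#'
#' Welch's unequal-variance t-test is the default (the safer choice with
#' unequal group sizes); `var_equal = TRUE` restores the pooled test. Sites
#' with zero variance in both groups and equal means get p = 1.
#'
#' @param values sites x samples matrix of percent methylation (0-100).
#' @param group character vector (length `ncol(values)`) with two levels.
#' @param direction alternative: `"greater"` = case more methylated.
#' @param case label of the case group.
#' @param var_equal use the pooled-variance t-test.
#' @return Data frame with one row per site: t, df, p (one-sided), q, tier,
#'   mean_case, sem_case, mean_control, sem_control.
#' @export
site_tests <- function(values, group, direction = c("greater", "less"),
                       case = "case", var_equal = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(values), length(group) == ncol(values))
  if (any(values < 0 | values > 100, na.rm = TRUE))
    .stopf("methylation values must lie in [0, 100]")
  is_case <- group == case
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    .stopf("each group needs at least 2 samples")

  xc <- values[, is_case, drop = FALSE]
  xk <- values[, !is_case, drop = FALSE]
  n1 <- rowSums(!is.na(xc)); n2 <- rowSums(!is.na(xk))
  m1 <- rowMeans(xc, na.rm = TRUE); m2 <- rowMeans(xk, na.rm = TRUE)
  v1 <- apply(xc, 1, var, na.rm = TRUE); v2 <- apply(xk, 1, var, na.rm = TRUE)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- if (direction == "greater") pt(t, df, lower.tail = FALSE)
       else pt(t, df)
  degen <- se == 0
  if (any(degen)) {
    t[degen] <- ifelse(m1[degen] == m2[degen], 0,
                       sign(m1[degen] - m2[degen]) * Inf)
    p[degen] <- ifelse(m1[degen] == m2[degen], 1,
                       ifelse((direction == "greater") ==
                                (m1[degen] > m2[degen]), 0, 1))
  }
  q <- bh_fdr(pmin(pmax(p, .Machine$double.xmin), 1))
  tier <- as.character(cut(q, c(0, 0.025, 0.05, 0.1, 0.2, 1),
                           labels = c("**", "*", "++", "+", ""),
                           include.lowest = TRUE))
  data.frame(
    site = rownames(values) %||% as.character(seq_len(nrow(values))),
    t = t, df = df, p = p, q = q, tier = tier,
    mean_case = m1, sem_case = sqrt(v1 / n1),
    mean_control = m2, sem_control = sqrt(v2 / n2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
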