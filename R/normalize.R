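#' Compute log2 bound/input ratios
#'
#' Converts aligned two-channel intensities to per-probe methylation scores
#' `log2(bound/input)`. A value is missing where either channel is missing or
#' non-positive. Probes missing in more than `max_missing` of the arrays are
#' dropped (with a message reporting the count); remaining missing values
#' propagate as `NA`.
#'
#' @param bound probes x arrays matrix of bound (Cy5) intensities, or a
#'   `medip_arrays` object from [simulate_arrays()] / [load_arrays()].
#' @param input probes x arrays matrix of input (Cy3) intensities; ignored
#'   when `bound` is a `medip_arrays` object.
#' @param max_missing drop probes missing in more than this fraction of
#'   arrays.
#' @return Probes x arrays matrix of raw log2 ratios.
#' @export
compute_log_ratios <- function(bound, input = NULL, max_missing = 0.2) {
  if (inherits(bound, "medip_arrays")) {
    input <- bound$input
    bound <- bound$bound
  }
  stopifnot(is.matrix(bound), is.matrix(input),
            all(dim(bound) == dim(input)))
  bad <- !is.finite(bound) | !is.finite(input) | bound <= 0 | input <= 0
  m <- matrix(NA_real_, nrow(bound), ncol(bound), dimnames = dimnames(bound))
  m[!bad] <- log2(bound[!bad] / input[!bad])
  miss <- rowMeans(is.na(m))
  drop <- miss > max_missing
  if (any(drop)) {
    .msgf("dropping %d probe(s) missing in > %.0f%% of arrays",
          sum(drop), 100 * max_missing)
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Quantile-normalize arrays
#'
#' Forces every array (column) onto a common empirical distribution: the
#' reference is the across-array mean of sorted values, each column's sorted
#' values are replaced by it, and tied values within a column receive the
#' mean of the reference values their ranks span. Missing values are left
#' missing and excluded from rank computation; columns with missing values
#' are mapped onto the reference by linear interpolation of quantiles.
#'
#' @param x probes x arrays matrix (at least 2 arrays).
#' @return Matrix of the same shape; afterwards all complete columns share
#'   identical sorted values.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) .stopf("quantile normalization needs at least 2 arrays")
  n <- nrow(x)
  nn <- colSums(!is.na(x))
  if (any(nn < 2)) .stopf("column(s) with fewer than 2 non-missing values")

  # reference distribution of length n: mean across columns of each column's
  # sorted values, interpolated onto a common probability grid when needed
  probs <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  ref <- rowMeans(vapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j], na.last = NA)
    if (length(v) == n) v
    else approx(x = (seq_along(v) - 1) / (length(v) - 1), y = v,
                xout = probs, rule = 2)$y
  }, numeric(n)))

  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    v <- x[ok, j]
    nj <- length(v)
    refj <- if (nj == n) ref
            else approx(x = probs, y = ref,
                        xout = (seq_len(nj) - 1) / (nj - 1), rule = 2)$y
    o <- order(v)
    r <- sort(refj)
    new <- numeric(nj)
    vs <- v[o]
    if (nj < 2 || !any(vs[-1] == vs[-nj])) {
      new[o] <- r
    } else {
      # tie groups take the mean of the reference values they span
      grp <- cumsum(c(1L, as.integer(vs[-1] != vs[-nj])))
      gm <- rowsum(r, grp) / tabulate(grp)
      new[o] <- gm[grp]
    }
    out[ok, j] <- new
  }
  out
}

#' Per-array MvA quality-control summary
#'
#' For every array computes M = log2(Cy5/Cy3) and A = log2(Cy5 x Cy3) over
#' probes with both channels positive, and summarizes the MvA cloud: median
#' and IQR of M, median A (signal level) and the M-vs-A correlation (a
#' monotone symptom of intensity-dependent dye bias). Arrays are flagged when
#' |median M| exceeds `m_thresh`, median A falls below `a_thresh`, or
#' |cor(M, A)| exceeds `bias_thresh`.
#'
#' @param arrays a `medip_arrays` object (raw channels).
#' @param m_thresh,a_thresh,bias_thresh flagging thresholds.
#' @return Data frame with one row per array: median_m, iqr_m, median_a,
#'   cor_ma, flagged and the reason.
#' @export
ma_qc <- function(arrays, m_thresh = 1, a_thresh = 0, bias_thresh = 0.5) {
  stopifnot(inherits(arrays, "medip_arrays"))
  b <- arrays$bound; i <- arrays$input
  res <- lapply(seq_len(ncol(b)), function(j) {
    ok <- is.finite(b[, j]) & is.finite(i[, j]) & b[, j] > 0 & i[, j] > 0
    m <- log2(b[ok, j] / i[ok, j])
    a <- log2(b[ok, j] * i[ok, j])
    data.frame(array_id = colnames(b)[j],
               n_probes = sum(ok),
               median_m = median(m), iqr_m = stats::IQR(m),
               median_a = median(a),
               cor_ma = if (sd(m) > 0 && sd(a) > 0) cor(m, a) else 0,
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, res)
  reasons <- mapply(function(mm, aa, cc) {
    r <- c(if (abs(mm) > m_thresh) "dye_ratio",
           if (aa < a_thresh) "low_signal",
           if (abs(cc) > bias_thresh) "dye_bias")
    paste(r, collapse = ";")
  }, qc$median_m, qc$median_a, qc$cor_ma)
  qc$flagged <- nzchar(reasons)
  qc$reason <- reasons
  qc
}

#' Average replicate arrays per individual
#'
#' Collapses the normalized probes x arrays matrix to one column per
#' individual by averaging each individual's replicate arrays, ignoring
#' missing values. A probe with no non-missing replicate for an individual
#' becomes missing.
#'
#' @param x probes x arrays matrix (normalized log ratios).
#' @param sheet sample sheet with `array_id` and `individual_id`.
#' @return Probes x individuals matrix; columns follow the order of first
#'   appearance in the sheet.
#' @export
average_replicates <- function(x, sheet) {
  stopifnot(is.matrix(x), all(colnames(x) %in% sheet$array_id))
  sheet <- sheet[match(colnames(x), sheet$array_id), ]
  inds <- unique(sheet$individual_id)
  out <- vapply(inds, function(id) {
    cols <- which(sheet$individual_id == id)
    if (length(cols) == 1) x[, cols]
    else rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(x), inds)
  out
}

#' Fraction of probe variance explained by individual
#'
#' Selects the `top_k` most variable probes across all arrays and, for each,
#' decomposes the total sum of squares into between-individual and
#' within-individual (replicate) components. Returns the mean
#' between-individual fraction, the replicate-quality statistic quoted for
#' this design (values above 0.7 indicate reproducible arrays).
#'
#' @param x probes x arrays matrix (normalized log ratios).
#' @param sheet sample sheet with `array_id` and `individual_id`; every
#'   individual needs at least 2 replicate arrays.
#' @param top_k number of most-variable probes to use (capped at the probe
#'   count, with a warning).
#' @return A list with `fraction` (mean between-individual fraction over the
#'   selected probes) and `per_probe` (the probe-level fractions).
#' @export
replicate_variance_explained <- function(x, sheet, top_k = 500) {
  stopifnot(is.matrix(x))
  sheet <- sheet[match(colnames(x), sheet$array_id), ]
  reps <- table(sheet$individual_id)
  if (any(reps < 2)) .stopf("every individual needs >= 2 replicate arrays")
  if (top_k > nrow(x)) {
    warning(sprintf("top_k capped at probe count (%d)", nrow(x)))
    top_k <- nrow(x)
  }
  v <- apply(x, 1, var, na.rm = TRUE)
  sel <- order(v, decreasing = TRUE)[seq_len(top_k)]
  xs <- x[sel, , drop = FALSE]
  f <- factor(sheet$individual_id)
  grand <- rowMeans(xs, na.rm = TRUE)
  # group means per probe
  gm <- vapply(levels(f), function(id)
    rowMeans(xs[, f == id, drop = FALSE], na.rm = TRUE), numeric(nrow(xs)))
  if (!is.matrix(gm)) gm <- matrix(gm, nrow = nrow(xs))
  ni <- as.vector(table(f)[levels(f)])
  ssb <- rowSums(sweep(sweep(gm, 1, grand), 2, sqrt(ni), "*")^2)
  sst <- rowSums((xs - grand)^2, na.rm = TRUE)
  frac <- ifelse(sst > 0, ssb / sst, 1)
  list(fraction = mean(frac), per_probe = frac)
}
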