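# independent brute-force oracles, written from the textbook definitions;
# they deliberately share no code with the package internals

# Benjamini-Hochberg step-up from the definition
# q_i = min over {j : p_j >= p_i} of p_j * m / rank_j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# upper-tail hypergeometric by explicit log-space summation
hyper_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# exact two-sided rank-sum p by enumeration of all subsets
ranksum_oracle <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(combn(length(v), m), 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# quantile normalization of a complete, tie-free matrix from the definition
qnorm_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(v) ref[rank(v)])
}

# two-sample t statistics from the textbook formulas
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

welch_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  se2 <- var(a) / n1 + var(b) / n2
  df <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
  t <- (mean(a) - mean(b)) / sqrt(se2)
  list(t = t, df = df, p_greater = pt(t, df, lower.tail = FALSE))
}

# Ward (ward.D2) agglomeration by direct Lance-Williams updating on the
# distance matrix; returns the merge heights in order
ward_d2_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    dm <- d[active, active]
    diag(dm) <- Inf
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    heights <- c(heights, d[a, b])
    # Lance-Williams update for ward.D2 (on squared distances)
    for (k in setdiff(active, c(a, b))) {
      na <- size[a]; nb <- size[b]; nk <- size[k]
      newd2 <- ((na + nk) * d[a, k]^2 + (nb + nk) * d[b, k]^2 -
                  nk * d[a, b]^2) / (na + nb + nk)
      d[a, k] <- d[k, a] <- sqrt(newd2)
    }
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  heights
}

# scaled inverse-chi-square draws for EB recovery checks
rinvchisq_scaled <- function(n, d0, s0_2) d0 * s0_2 / rchisq(n, d0)
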