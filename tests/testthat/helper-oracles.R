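# Independent brute-force oracles and fixture builders. The oracles are kept
# deliberately naive (explicit loops, textbook formulas) so they cannot share
# a defect with the implementation under test.

random_cq_matrix <- function(k = 4, n = 6, seed = 1, groups = 2) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(k * n, mean = 26, sd = 1.2), k, n,
                 dimnames = list(paste0("g", seq_len(k)),
                                 paste0("s", seq_len(n))))
  grp <- rep(c("control", "case"), length.out = n)
  if (groups == 1) grp <- rep("all", n)
  cq_matrix(vals, group = stats::setNames(grp, colnames(vals)))
}

fixture_cq_small <- function() {
  vals <- matrix(c(24.1, 24.9, 25.6, 24.4,
                   26.3, 27.2, 27.5, 26.1,
                   28.9, 29.4, 30.2, 29.1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("miR-a", "miR-b", "miR-c"),
                                 paste0("s", 1:4)))
  cq_matrix(vals, group = c(s1 = "control", s2 = "control",
                            s3 = "case", s4 = "case"))
}

# mean pairwise log2-ratio SD, one gene at a time
oracle_genorm_m <- function(q) {
  x <- log2(unclass(q))
  k <- nrow(x)
  m <- numeric(k)
  for (g in 1:k) {
    acc <- c()
    for (h in 1:k) if (h != g) acc <- c(acc, stats::sd(x[g, ] - x[h, ]))
    m[g] <- mean(acc)
  }
  stats::setNames(m, rownames(x))
}

oracle_delta_ct <- function(cq_vals) {
  k <- nrow(cq_vals)
  out <- numeric(k)
  for (g in 1:k) {
    acc <- c()
    for (h in 1:k) if (h != g)
      acc <- c(acc, stats::sd(cq_vals[g, ] - cq_vals[h, ]))
    out[g] <- mean(acc)
  }
  stats::setNames(out, rownames(cq_vals))
}

oracle_bestkeeper_sd <- function(cq_vals) {
  out <- numeric(nrow(cq_vals))
  for (g in seq_len(nrow(cq_vals))) {
    geo <- prod(cq_vals[g, ])^(1 / ncol(cq_vals))
    out[g] <- mean(abs(cq_vals[g, ] - geo))
  }
  stats::setNames(out, rownames(cq_vals))
}

# V_n from first principles: per-sample geometric-mean NFs over the first n
# genes of `ord`, then sd of log2 ratios
oracle_v_series <- function(q, ord) {
  x <- unclass(q)[ord, , drop = FALSE]
  k <- nrow(x)
  nf <- function(n) apply(x[1:n, , drop = FALSE], 2,
                          function(col) prod(col)^(1 / n))
  vapply(2:(k - 1), function(n) stats::sd(log2(nf(n) / nf(n + 1))),
         numeric(1))
}

oracle_geomean_ranks <- function(rank_mat) {
  apply(rank_mat, 1, function(r) prod(r)^(1 / length(r)))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(x, y)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

rq_e2 <- function(m) relative_quantities(m, eff = NULL)
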