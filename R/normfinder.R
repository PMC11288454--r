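#' Model-based stability estimation (NormFinder-style)
#'
#' Decomposes log2-scale expression into a shared per-sample loading effect,
#' a gene effect, an optional gene-by-group effect and gene-specific noise,
#' and scores each candidate by how little it deviates from the common signal.
#'
#' The model for gene i, group g, sample j is
#' `y_igj = mu_ig + u_gj + e_igj`, with `u_gj` the sample loading common to
#' all genes and `e_igj ~ N(0, sigma2_ig)` the gene-specific noise. Per group,
#' residuals after two-way centering (gene and sample means removed) estimate
#' the noise; the naive residual variance `s2_ig` is biased because every
#' residual contains a share of all genes' noise, so it is corrected by
#' `sigma2_ig = k/(k-2) * (s2_ig - sum_i' s2_i'g / (k (k-1)))` (truncated at
#' zero), k being the number of genes.
#'
#' In grouped mode the gene-by-group interaction `d_ig` (the candidate's
#' systematic expression difference between conditions, summing to zero over
#' genes and over groups) is estimated from the group means and shrunk toward
#' zero by the empirical-Bayes factor `gamma2 / (gamma2 + var(d_ig))`, where
#' `gamma2` is the between-gene variance of the true differences estimated
#' from the spread of the observed ones. The stability value of gene i is the
#' group average of `|d_ig_shrunk| + sqrt(sigma2_ig / n_g)`: a candidate is
#' penalised both for differing systematically between groups and for being
#' noisy. In ungrouped mode all samples form one group and the stability value
#' is simply `sqrt(sigma2_i)`. Lower is more stable in both modes; the two
#' modes agree in ranking when group effects are negligible, but their
#' absolute values are not comparable.
#'
#' @param m a [cq_matrix()] without missing values, at least 3 genes.
#' @param eff optional [efficiency_map()]; by default (`NULL`) expression is
#'   taken as `-Cq` on the log2 scale, i.e. 100% efficiency, which is the
#'   convention of Cq-based NormFinder usage. Supplying efficiencies uses
#'   `log2` of the efficiency-corrected relative quantities instead.
#' @param use_groups `TRUE` for the grouped decomposition (requires exactly
#'   2+ groups, each with >= 2 samples; only 2-group designs are exercised by
#'   this package's tests), `FALSE` to pool all samples.
#' @return list of class `normfinder_result`:
#'   \describe{
#'     \item{table}{data frame `gene, stability, rank`, plus in grouped mode
#'       one `var_<group>` (intragroup variance) and one `dif_<group>`
#'       (shrunken intergroup difference) column per group.}
#'     \item{mode}{"grouped" or "ungrouped".}
#'   }
#' @export
normfinder_stability <- function(m, eff = NULL, use_groups = TRUE) {
  stopifnot(is_cq_matrix(m))
  if (anyNA(m)) stop("missing values present; run detection_filter() first")
  if (nrow(m) < 3) stop("NormFinder needs at least 3 genes")
  y <- if (is.null(eff)) -unclass_cq(m) else log2_rq(relative_quantities(m, eff))
  grp <- cq_groups(m)
  if (use_groups) {
    lv <- unique(grp)
    if (length(lv) < 2) stop("grouped mode requires at least 2 groups")
    if (any(table(grp) < 2)) stop("each group needs at least 2 samples")
  } else {
    lv <- "all"
    grp <- stats::setNames(rep("all", ncol(m)), colnames(m))
  }
  k <- nrow(y)
  G <- length(lv)
  n_g <- stats::setNames(as.integer(table(grp)[lv]), lv)

  # per-group intragroup variances with the small-k bias correction
  s2 <- sigma2 <- matrix(0, k, G, dimnames = list(rownames(y), lv))
  a <- matrix(0, k, G, dimnames = list(rownames(y), lv))  # gene-group means
  for (g in lv) {
    yg <- y[, grp == g, drop = FALSE]
    a[, g] <- rowMeans(yg)
    r <- yg - rowMeans(yg) -
      matrix(colMeans(yg), k, ncol(yg), byrow = TRUE) + mean(yg)
    s2[, g] <- rowSums(r^2) / (ncol(yg) - 1)
    sigma2[, g] <- pmax(k / (k - 2) * (s2[, g] - sum(s2[, g]) / (k * (k - 1))),
                        0)
  }

  if (!use_groups) {
    stability <- sqrt(sigma2[, 1])
    tab <- data.frame(gene = rownames(y), stability = unname(stability),
                      stringsAsFactors = FALSE)
  } else {
    # gene-by-group interaction of the group means
    d <- a - rowMeans(a) - matrix(colMeans(a), k, G, byrow = TRUE) + mean(a)
    vard <- sweep(sigma2, 2, n_g, "/")
    gamma2 <- max(sum(d^2) / ((k - 1) * (G - 1)) - mean(vard), 0)
    d_shrunk <- d * gamma2 / (gamma2 + vard)
    d_shrunk[!is.finite(d_shrunk)] <- 0   # gamma2 = vard = 0
    rho <- abs(d_shrunk) + sqrt(vard)
    stability <- rowMeans(rho)
    tab <- data.frame(gene = rownames(y), stability = unname(stability),
                      stringsAsFactors = FALSE)
    for (g in lv) tab[[paste0("var_", g)]] <- unname(sigma2[, g])
    for (g in lv) tab[[paste0("dif_", g)]] <- unname(d_shrunk[, g])
  }
  tab$rank <- rank(tab$stability, ties.method = "average")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 mode = if (use_groups) "grouped" else "ungrouped"),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("<normfinder_result> mode: %s (lower stability = better)\n",
              x$mode))
  print(x$table, ...)
  invisible(x)
}
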