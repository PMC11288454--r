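# BestKeeper descriptive-statistics ranking and the comparative delta-Ct
# method, both computed on raw (replicate-averaged) Cq.

#' BestKeeper descriptive stability statistics
#'
#' Per gene: geometric and arithmetic mean Cq, range, the BestKeeper "SD"
#' (mean absolute deviation of Cq around the geometric mean — the original
#' BestKeeper convention), CV% (SD as a percent of the arithmetic mean), and
#' the Pearson correlation of the gene with the BestKeeper index (the
#' per-sample geometric mean of all candidate Cq values). Genes are ranked by
#' ascending SD; a gene with SD above 1 cycle is conventionally considered
#' inconsistent and flagged. The ordinary sample SD is reported alongside.
#'
#' @param m a [cq_matrix()] without missing values, >= 2 samples; Cq must be
#'   positive (geometric means are undefined otherwise).
#' @param sd_cutoff flag threshold in cycles, default 1.
#' @return list of class `bestkeeper_result` with `table` (data frame `gene,
#'   geo_mean, ar_mean, min, max, sd (MAD-based), sd_sample, cv_pct, r,
#'   r_p, unstable, rank`) and `index` (named per-sample index vector).
#' @export
bestkeeper <- function(m, sd_cutoff = 1) {
  stopifnot(is_cq_matrix(m))
  if (anyNA(m)) stop("missing values present; run detection_filter() first")
  if (ncol(m) < 2) stop("BestKeeper needs at least 2 samples")
  cq <- unclass_cq(m)
  if (any(cq <= 0)) stop("non-positive Cq: geometric mean undefined")
  geo <- exp(rowMeans(log(cq)))
  sd_mad <- rowMeans(abs(cq - geo))
  index <- exp(colMeans(log(cq)))
  # index correlation needs >= 3 pairs; degenerate (constant) genes give NA
  cors <- lapply(seq_len(nrow(cq)), function(i) {
    if (ncol(cq) < 3 || stats::sd(cq[i, ]) == 0 || stats::sd(index) == 0)
      return(list(estimate = c(cor = NA_real_), p.value = NA_real_))
    suppressWarnings(stats::cor.test(cq[i, ], index))
  })
  tab <- data.frame(
    gene = rownames(cq),
    geo_mean = unname(geo),
    ar_mean = rowMeans(cq),
    min = apply(cq, 1, min),
    max = apply(cq, 1, max),
    sd = unname(sd_mad),
    sd_sample = apply(cq, 1, stats::sd),
    cv_pct = unname(100 * sd_mad / rowMeans(cq)),
    r = vapply(cors, function(ct) unname(ct$estimate), numeric(1)),
    r_p = vapply(cors, function(ct) ct$p.value, numeric(1)),
    unstable = unname(sd_mad > sd_cutoff),
    stringsAsFactors = FALSE)
  tab$rank <- rank(tab$sd, ties.method = "average")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, index = index), class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("<bestkeeper_result> ranked by ascending SD (mean |Cq - geo mean|)\n")
  print(x$table, ...)
  invisible(x)
}

#' Comparative delta-Ct stability
#'
#' For every gene pair (g, h) the standard deviation over samples of the Cq
#' difference `Cq_g - Cq_h` is computed; a gene's stability value is the mean
#' of its pair SDs against all other candidates (so each pair contributes
#' symmetrically to both members). Run on raw mean Cq, no efficiency
#' correction. With 100% efficiency for every gene this is numerically
#' identical to the single-pass geNorm M, since log2 of a quantity ratio is a
#' Cq difference and SD ignores the constant offset.
#'
#' @param m a [cq_matrix()] without missing values, >= 2 samples.
#' @return list of class `delta_ct_result` with `table` (data frame `gene,
#'   mean_pair_sd, rank`, ascending) and `pair_sd` (k x k symmetric matrix).
#' @export
delta_ct <- function(m) {
  stopifnot(is_cq_matrix(m))
  if (anyNA(m)) stop("missing values present; run detection_filter() first")
  if (ncol(m) < 2) stop("delta-Ct needs at least 2 samples")
  cq <- unclass_cq(m)
  k <- nrow(cq)
  if (k < 2) stop("delta-Ct needs at least 2 genes")
  if (k == 2)
    warning("only 2 genes: both stabilities equal the single pair SD")
  pair_sd <- matrix(0, k, k, dimnames = list(rownames(cq), rownames(cq)))
  for (g in seq_len(k - 1)) {
    for (h in (g + 1):k) {
      s <- stats::sd(cq[g, ] - cq[h, ])
      pair_sd[g, h] <- pair_sd[h, g] <- s
    }
  }
  stab <- rowSums(pair_sd) / (k - 1)
  tab <- data.frame(gene = rownames(cq), mean_pair_sd = unname(stab),
                    stringsAsFactors = FALSE)
  tab$rank <- rank(tab$mean_pair_sd, ties.method = "average")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, pair_sd = pair_sd), class = "delta_ct_result")
}

#' @export
print.delta_ct_result <- function(x, ...) {
  cat("<delta_ct_result> ranked by ascending mean pairwise Cq-difference SD\n")
  print(x$table, ...)
  invisible(x)
}
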