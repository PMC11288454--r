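# geNorm: stability value M, iterative ranking, normalization factors and the
# pairwise variation V used to pick the minimal number of reference genes.

#' Efficiency-corrected relative quantities
#'
#' Converts Cq to relative quantities `Q = E^(Cq_min - Cq)` per gene, where
#' `E` is the per-cycle amplification base (2 for a 100% efficient assay).
#' The most abundant sample of each gene gets Q = 1 and everything else falls
#' in (0, 1].
#'
#' @param m a [cq_matrix()] without missing values.
#' @param eff an [efficiency_map()], a named numeric vector of E% values, or
#'   `NULL` to assume 100% efficiency (`E = 2`) for every gene.
#' @return numeric matrix of relative quantities (class `relative_quantities`)
#'   with the group attribute carried over and the per-gene `e_base` attached.
#' @export
relative_quantities <- function(m, eff = NULL) {
  stopifnot(is_cq_matrix(m))
  if (anyNA(m))
    stop("missing values present; run detection_filter() first")
  base <- efficiency_bases(rownames(m), eff)
  if (any(base <= 1)) stop("amplification base must exceed 1")
  cq <- unclass_cq(m)
  q <- base^(apply(cq, 1, min) - cq)   # rows recycled: base and row min per gene
  structure(q, group = cq_groups(m), e_base = base,
            class = c("relative_quantities", "matrix", "array"))
}

# log2 expression from relative quantities
log2_rq <- function(q) log2(unclass(q))

#' Single-pass geNorm stability value M
#'
#' For each pair of genes (g, h), the pairwise variation `V_gh` is the
#' standard deviation over samples of `log2(Q_g / Q_h)` (sample SD, n-1
#' denominator). A gene's M is the mean of its pairwise variations against
#' every other candidate; lower M means the gene moves in concert with the
#' rest of the panel, i.e. is more stably expressed.
#'
#' @param q a [relative_quantities()] matrix (>= 2 genes, >= 2 samples).
#' @return named numeric vector of M values, one per gene.
#' @export
genorm_m <- function(q) {
  x <- log2_rq(q)
  k <- nrow(x)
  if (k < 2) stop("geNorm needs at least 2 genes")
  if (ncol(x) < 2) stop("geNorm needs at least 2 samples")
  if (k == 2)
    warning("only 2 genes: M degenerates to the single pairwise variation")
  m <- vapply(seq_len(k), function(g) {
    v <- vapply(seq_len(k)[-g],
                function(h) stats::sd(x[g, ] - x[h, ]), numeric(1))
    mean(v)
  }, numeric(1))
  names(m) <- rownames(x)
  m
}

#' Iterative geNorm ranking
#'
#' Repeatedly computes M on the current gene set and removes the least stable
#' gene (highest M) until two genes remain; those two cannot be distinguished
#' by the pairwise scheme and are reported as a tied pair at ranks 1-2
#' (average rank 1.5 each). The reported per-gene `m_iterative` is the M at
#' the iteration of the gene's removal; the final pair keeps the last
#' computed (two-gene) value. Equal M values during removal are broken by
#' dropping the lexicographically last gene name, deterministically.
#'
#' @param q a [relative_quantities()] matrix with at least 3 genes.
#' @return list of class `genorm_result`:
#'   \describe{
#'     \item{table}{data frame `gene, m_single_pass, m_iterative, rank`
#'       (rank 1.5/1.5 for the final pair), ordered most-stable first.}
#'     \item{order}{character vector of genes from most to least stable (the
#'       reverse removal order; the first two form the tied top pair).}
#'     \item{trace}{list of per-iteration M vectors.}
#'   }
#' @export
genorm_rank <- function(q) {
  x <- unclass(q)
  if (nrow(x) < 3) stop("iterative geNorm needs at least 3 genes")
  m_single <- genorm_m(q)
  remaining <- rownames(x)
  removal <- character(0)
  m_final <- stats::setNames(numeric(length(remaining)), remaining)
  trace <- list()
  while (length(remaining) > 2) {
    m_cur <- genorm_m(subset_rq(q, remaining))
    trace[[length(trace) + 1L]] <- m_cur
    worst_m <- max(m_cur)
    cand <- names(m_cur)[m_cur == worst_m]
    if (length(cand) > 1)
      warning("tied M values; removing lexicographically last gene: ",
              sort(cand)[length(cand)])
    worst <- sort(cand)[length(cand)]
    m_final[worst] <- m_cur[worst]
    removal <- c(removal, worst)
    remaining <- setdiff(remaining, worst)
  }
  m_pair <- suppressWarnings(genorm_m(subset_rq(q, remaining)))
  trace[[length(trace) + 1L]] <- m_pair
  m_final[remaining] <- m_pair
  order_genes <- c(sort(remaining), rev(removal))
  rank <- stats::setNames(seq_along(order_genes), order_genes)
  rank[remaining] <- 1.5
  tab <- data.frame(gene = order_genes,
                    m_single_pass = unname(m_single[order_genes]),
                    m_iterative = unname(m_final[order_genes]),
                    rank = unname(rank[order_genes]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, order = order_genes, trace = trace),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result> most stable first (final pair tied)\n")
  print(x$table, ...)
  invisible(x)
}

subset_rq <- function(q, genes) {
  x <- unclass(q)[genes, , drop = FALSE]
  structure(x, group = attr(q, "group"),
            e_base = attr(q, "e_base")[genes],
            class = c("relative_quantities", "matrix", "array"))
}

#' geNorm pairwise variation V and the optimal number of reference genes
#'
#' The normalization factor `NF_n` of a sample is the geometric mean of the
#' relative quantities of the n most stable genes. `V_n` is the standard
#' deviation over samples of `log2(NF_n / NF_(n+1))`: how much the
#' normalization would change if an (n+1)-th gene were added. The smallest n
#' with `V_n` below the cutoff (conventionally 0.15) is taken as the number
#' of reference genes needed for reliable normalization.
#'
#' @param q a [relative_quantities()] matrix.
#' @param ranking a [genorm_rank()] result computed on the same gene set (or a
#'   character vector ordering genes most-stable first).
#' @param cutoff V threshold, default 0.15.
#' @return list of class `pairwise_variation`:
#'   `table` (data frame `n, v, below_cutoff` for n = 2..k-1), `cutoff`,
#'   `optimal_n` (smallest n with V_n < cutoff, `NA` when never reached).
#' @export
pairwise_variation <- function(q, ranking, cutoff = 0.15) {
  ord <- if (inherits(ranking, "genorm_result")) ranking$order else ranking
  x <- unclass(q)
  if (!setequal(ord, rownames(x)))
    stop("ranking and quantity matrix cover different gene sets")
  k <- length(ord)
  if (k < 3) stop("pairwise variation needs at least 3 genes")
  lx <- log2(x[ord, , drop = FALSE])
  log_nf <- function(n) colMeans(lx[seq_len(n), , drop = FALSE])
  v <- vapply(2:(k - 1),
              function(n) stats::sd(log_nf(n) - log_nf(n + 1)), numeric(1))
  tab <- data.frame(n = 2:(k - 1), v = v, below_cutoff = v < cutoff)
  hit <- which(tab$below_cutoff)
  structure(list(table = tab, cutoff = cutoff,
                 optimal_n = if (length(hit)) tab$n[hit[1]] else NA_integer_),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat(sprintf("<pairwise_variation> cutoff %.2f, optimal n = %s\n", x$cutoff,
              if (is.na(x$optimal_n)) "not reached" else x$optimal_n))
  print(x$table, ...)
  invisible(x)
}
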