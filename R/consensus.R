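# Consensus (comprehensive) ranking across stability algorithms by the
# geometric mean of per-algorithm ranks, as popularised by RefFinder.

#' Consensus stability ranking by geometric mean of ranks
#'
#' Each algorithm contributes its gene ranking (ties as average ranks, e.g.
#' 1.5/1.5 for geNorm's tied top pair); a gene's comprehensive score is the
#' geometric mean of its ranks and the final ordering is by ascending score.
#' Tied scores are broken by the mean of the individual ranks, then by gene
#' name, so the output is deterministic.
#'
#' @param rankings named list (>= 2 entries) of named numeric vectors, one per
#'   algorithm, each mapping every gene to its rank. All vectors must cover
#'   the same gene set.
#' @return list of class `consensus_ranking` with `table`: data frame of one
#'   `rank_<algorithm>` column per input, `geomean_score` and `final_rank`,
#'   ordered most-stable first.
#' @examples
#' consensus(list(a = c(g1 = 1, g2 = 2, g3 = 3),
#'                b = c(g1 = 2, g2 = 1, g3 = 3)))
#' @export
consensus <- function(rankings) {
  if (!is.list(rankings) || length(rankings) < 2)
    stop("need at least 2 algorithm rankings")
  if (is.null(names(rankings)) || any(!nzchar(names(rankings))))
    stop("`rankings` must be a named list")
  genes <- names(rankings[[1]])
  for (nm in names(rankings)) {
    gi <- names(rankings[[nm]])
    if (!setequal(gi, genes)) {
      diff <- c(setdiff(genes, gi), setdiff(gi, genes))
      stop("gene set mismatch in '", nm, "': ", paste(diff, collapse = ", "))
    }
  }
  rank_mat <- vapply(rankings, function(r) unname(r[genes]),
                     numeric(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes),
                     dimnames = list(genes, names(rankings)))
  score <- exp(rowMeans(log(rank_mat)))
  mean_rank <- rowMeans(rank_mat)
  ord <- order(score, mean_rank, genes)
  tab <- data.frame(gene = genes[ord], rank_mat[ord, , drop = FALSE],
                    geomean_score = unname(score[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(tab)[2:(1 + ncol(rank_mat))] <- paste0("rank_", colnames(rank_mat))
  tab$final_rank <- seq_len(nrow(tab))
  structure(list(table = tab), class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("<consensus_ranking> geometric mean of algorithm ranks, best first\n")
  print(x$table, ...)
  invisible(x)
}

#' Overlap of the top-k gene sets across algorithms
#'
#' @param rankings as in [consensus()].
#' @param depth how many top genes per algorithm, default 4.
#' @return list with `sets` (per-algorithm character vectors of the `depth`
#'   most stable genes), `intersection` (genes in every set), and
#'   `pairwise` (data frame of pairwise intersection sizes).
#' @export
top_overlap <- function(rankings, depth = 4) {
  if (depth > length(rankings[[1]])) stop("depth exceeds the gene count")
  sets <- lapply(rankings, function(r) names(sort(r))[seq_len(depth)])
  algs <- names(sets)
  pairs <- utils::combn(algs, 2)
  pairwise <- data.frame(
    alg_a = pairs[1, ], alg_b = pairs[2, ],
    n_shared = apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE)
  list(sets = sets, intersection = Reduce(intersect, sets),
       pairwise = pairwise)
}

#' Extract gene -> rank maps from the stability result objects
#'
#' Convenience for feeding [consensus()]: accepts results from
#' [genorm_rank()], [normfinder_stability()], [bestkeeper()] and [delta_ct()].
#'
#' @param ... named stability result objects.
#' @return named list of named rank vectors.
#' @export
stability_ranks <- function(...) {
  objs <- list(...)
  if (is.null(names(objs)) || any(!nzchar(names(objs))))
    stop("arguments must be named, e.g. genorm = ...")
  lapply(objs, function(o) {
    tab <- if (is.data.frame(o)) o else o$table
    stats::setNames(tab$rank, tab$gene)
  })
}
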