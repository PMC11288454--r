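#' Collapse technical replicates to mean Cq with quality control
#'
#' Averages the technical replicates of each (gene, sample) reaction and flags
#' entries whose replicate spread (max - min) exceeds the tolerance. The
#' conventional bench rule keeps replicates that differ by at most 0.3 cycles;
#' flagged entries are retained in the output but reported in the QC table so
#' the analyst can decide what to do with them.
#'
#' @param reps a `cq_replicates` object (see [read_cq_table()]) or a long
#'   data frame with columns `sample, group, mirna, replicate, cq`.
#' @param tolerance maximum allowed replicate spread in cycles (> 0),
#'   default 0.3.
#' @return A list with components
#'   \describe{
#'     \item{cq}{[cq_matrix()] of per-reaction mean Cq; a reaction whose
#'       replicates are all undetermined is `NA`.}
#'     \item{qc}{data frame `gene, sample, n_replicates, spread, flag` with
#'       `flag = "spread_exceeds_tolerance"` or `"pass"`; spread is computed
#'       over the detected replicates only.}
#'   }
#' @export
collapse_replicates <- function(reps, tolerance = 0.3) {
  if (!is.data.frame(reps))
    stop("`reps` must be a cq_replicates object or long data frame")
  if (!isTRUE(tolerance > 0)) stop("`tolerance` must be > 0")
  reps <- new_cq_replicates(as.data.frame(reps))
  key <- interaction(reps$mirna, reps$sample, drop = TRUE)
  if (!nrow(reps)) stop("empty replicate set")
  per <- split(reps, key)
  rows <- lapply(per, function(d) {
    v <- d$cq[!is.na(d$cq)]
    if (!length(v)) {
      data.frame(gene = d$mirna[1], sample = d$sample[1],
                 group = d$group[1], n_replicates = nrow(d),
                 mean_cq = NA_real_, spread = NA_real_, flag = "all_missing",
                 stringsAsFactors = FALSE)
    } else {
      spread <- max(v) - min(v)
      data.frame(gene = d$mirna[1], sample = d$sample[1],
                 group = d$group[1], n_replicates = nrow(d),
                 mean_cq = mean(v), spread = spread,
                 flag = if (spread > tolerance) "spread_exceeds_tolerance"
                        else "pass",
                 stringsAsFactors = FALSE)
    }
  })
  qc <- do.call(rbind, rows)
  rownames(qc) <- NULL
  # preserve input ordering of genes and samples
  genes <- unique(reps$mirna)
  samples <- unique(reps$sample)
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  vals[cbind(match(qc$gene, genes), match(qc$sample, samples))] <- qc$mean_cq
  gm <- stats::setNames(reps$group, reps$sample)
  gm <- gm[!duplicated(names(gm))]
  qc <- qc[order(match(qc$gene, genes), match(qc$sample, samples)),
           c("gene", "sample", "n_replicates", "mean_cq", "spread", "flag")]
  rownames(qc) <- NULL
  list(cq = cq_matrix(vals, group = gm[samples]), qc = qc)
}
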