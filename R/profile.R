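#' Descriptive Cq profile of candidate reference miRNAs
#'
#' Summarises each gene's Cq distribution over the available (detected)
#' measurements and reports which fraction of the panel has a mean Cq inside
#' the working range for a reference assay. Reference transcripts should be
#' neither scarce (Cq above ~32 cannot be quantified reliably) nor so abundant
#' that Cq drops under ~15; a mean between 24 and 30 cycles is the usual
#' comfort zone.
#'
#' @param m a [cq_matrix()]; genes with some undetermined wells are profiled
#'   on their detected values.
#' @param low,high working-range bounds (cycles) used for the percentage,
#'   default 24 and 30.
#' @return list with
#'   \describe{
#'     \item{profile}{data frame `gene, n, mean, sd, min, max, median, iqr,
#'       flag` where `flag` is one of `too_low` (mean < 15), `in_range`,
#'       `high` (mean > 30), `too_high` (mean > 32).}
#'     \item{pct_in_range}{percentage of genes whose mean Cq lies in
#'       `[low, high]`.}
#'   }
#' @export
cq_profile <- function(m, low = 24, high = 30) {
  stopifnot(is_cq_matrix(m))
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty Cq matrix")
  if (any(rowSums(!is.na(m)) == 0))
    stop("gene(s) with no detected value: ",
         paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", "))
  stats_one <- function(v) {
    v <- v[!is.na(v)]
    c(n = length(v), mean = mean(v), sd = stats::sd(v), min = min(v),
      max = max(v), median = stats::median(v), iqr = stats::IQR(v))
  }
  s <- t(apply(unclass_cq(m), 1, stats_one))
  flag <- ifelse(s[, "mean"] < 15, "too_low",
          ifelse(s[, "mean"] > 32, "too_high",
          ifelse(s[, "mean"] > 30, "high", "in_range")))
  profile <- data.frame(gene = rownames(m), s, flag = unname(flag),
                        row.names = NULL, stringsAsFactors = FALSE)
  in_range <- profile$mean >= low & profile$mean <= high
  list(profile = profile,
       pct_in_range = 100 * mean(in_range))
}
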