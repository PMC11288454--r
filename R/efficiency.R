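#' Amplification efficiency from a serial-dilution standard curve
#'
#' Fits Cq against the log of the dilution factor by least squares and
#' converts the slope to a percent amplification efficiency,
#' \code{E\% = 100 * (base^(-1/slope) - 1)}. A perfect assay doubles the
#' template every cycle: on a log2 scale a 1:2 dilution series then has slope
#' exactly -1 and E% = 100 (equivalently, slope -3.32 on the familiar log10
#' scale). Efficiencies between 90 and 110% are conventionally accepted.
#'
#' @param dilution numeric vector of dilution factors (e.g. `1, 1/2, 1/4, ...`),
#'   strictly decreasing, at least 3 points.
#' @param cq numeric vector of measured Cq, same length as `dilution`.
#' @param log_base base for the dilution log-scale used in the regression:
#'   2 (natural for 1:2 series, the default) or 10.
#' @param accept_range numeric length-2, E% acceptance window
#'   (default `c(90, 110)`).
#' @return list with `e_percent`, `e_base` (`1 + e_percent/100`), `slope`
#'   (on the chosen log scale), `r_squared` and logical `accepted`.
#' @examples
#' # perfect doubling: Cq climbs 1 cycle per 1:2 dilution
#' efficiency_from_curve(1 / 2^(0:6), 20 + 0:6)$e_percent  # 100
#' @export
efficiency_from_curve <- function(dilution, cq, log_base = 2,
                                  accept_range = c(90, 110)) {
  if (length(dilution) != length(cq)) stop("dilution/cq length mismatch")
  if (length(dilution) < 3) stop("a standard curve needs at least 3 points")
  if (any(diff(dilution) >= 0)) stop("dilutions must be strictly decreasing")
  if (!log_base %in% c(2, 10)) stop("log_base must be 2 or 10")
  x <- log(dilution, base = log_base)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid curve: non-negative slope")
  e_percent <- 100 * (log_base^(-1 / slope) - 1)
  tss <- sum((cq - mean(cq))^2)
  list(e_percent = e_percent,
       e_base = 1 + e_percent / 100,
       slope = slope,
       r_squared = 1 - sum(stats::residuals(fit)^2) / tss,
       accepted = e_percent >= accept_range[1] & e_percent <= accept_range[2])
}

#' Build an efficiency map from percent efficiencies
#'
#' @param e_percent named numeric vector of per-miRNA percent efficiencies
#'   (100 = perfect doubling).
#' @param accept_range E% acceptance window, default `c(90, 110)`.
#' @return data frame of class `efficiency_map` with columns `mirna`,
#'   `e_percent`, `e_base`, `accepted`.
#' @export
efficiency_map <- function(e_percent, accept_range = c(90, 110)) {
  if (is.null(names(e_percent)) || any(!nzchar(names(e_percent))))
    stop("`e_percent` must be named by miRNA")
  if (any(!is.finite(e_percent) | e_percent <= 0))
    stop("E% must be finite and positive")
  out <- data.frame(
    mirna = names(e_percent),
    e_percent = unname(e_percent),
    e_base = 1 + unname(e_percent) / 100,
    accepted = unname(e_percent) >= accept_range[1] &
      unname(e_percent) <= accept_range[2],
    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_map", "data.frame")
  out
}

#' Efficiency map from a table of standard curves
#'
#' @param curves data frame with columns `mirna`, `dilution`, `cq`.
#' @param log_base passed to [efficiency_from_curve()].
#' @return An [efficiency_map()] with one row per miRNA.
#' @export
efficiency_map_from_curves <- function(curves, log_base = 2) {
  stopifnot(all(c("mirna", "dilution", "cq") %in% names(curves)))
  per <- split(curves, curves$mirna)
  e <- vapply(per, function(d) {
    d <- d[order(-d$dilution), ]
    efficiency_from_curve(d$dilution, d$cq, log_base = log_base)$e_percent
  }, numeric(1))
  efficiency_map(e)
}

# E_base lookup for a set of genes; e = NULL means assume perfect doubling.
efficiency_bases <- function(genes, eff = NULL) {
  if (is.null(eff)) return(stats::setNames(rep(2, length(genes)), genes))
  if (is.numeric(eff) && !is.null(names(eff)))
    eff <- efficiency_map(eff)
  stopifnot(inherits(eff, "efficiency_map"))
  miss <- setdiff(genes, eff$mirna)
  if (length(miss))
    stop("no efficiency for gene(s): ", paste(miss, collapse = ", "))
  stats::setNames(eff$e_base[match(genes, eff$mirna)], genes)
}
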