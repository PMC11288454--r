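#' Construct a Cq matrix
#'
#' A `cq_matrix` holds quantification-cycle (Cq) values for a panel of
#' candidate reference miRNAs measured across samples, together with the
#' per-sample biological group labels. Undetermined reactions (no
#' amplification) are stored as `NA`, which is distinct from any numeric Cq.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Entries
#'   must be finite and positive where present; `NA` marks an undetermined
#'   (missing) measurement.
#' @param group character or factor of group labels, one per sample (column).
#'   Named vectors are matched to column names.
#' @param genes,samples optional identifiers; default to the dimnames of
#'   `values`.
#' @return An object of class `cq_matrix`: the numeric matrix with a
#'   `group` attribute (named character vector, sample -> group).
#' @examples
#' m <- cq_matrix(matrix(c(24, 25, 26, 27), 2, 2,
#'                       dimnames = list(c("miR-a", "miR-b"), c("s1", "s2"))),
#'                group = c(s1 = "control", s2 = "case"))
#' cq_groups(m)
#' @export
cq_matrix <- function(values, group, genes = rownames(values),
                      samples = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  storage.mode(values) <- "double"
  rownames(values) <- genes
  colnames(values) <- samples
  if (!is.null(names(group))) {
    if (!all(samples %in% names(group)))
      stop("group labels missing for sample(s): ",
           paste(setdiff(samples, names(group)), collapse = ", "))
    group <- group[samples]
  } else {
    if (length(group) != length(samples))
      stop("`group` must have one label per sample")
    names(group) <- samples
  }
  group <- as.character(group)
  names(group) <- samples
  if (anyNA(group)) stop("every sample needs a group label")
  bad <- which(!is.na(values) & (!is.finite(values) | values <= 0))
  if (length(bad))
    stop("Cq values must be finite and positive where present")
  structure(values, group = group, class = c("cq_matrix", "matrix", "array"))
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d miRNAs x %d samples (%d missing)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  gr <- table(cq_groups(x))
  cat("groups:", paste(sprintf("%s (n=%d)", names(gr), gr), collapse = ", "),
      "\n")
  print(unclass_cq(x), ...)
  invisible(x)
}

unclass_cq <- function(x) {
  attr(x, "group") <- NULL
  class(x) <- NULL
  x
}

#' Sample group labels of a Cq matrix
#'
#' @param m a [cq_matrix()].
#' @return Named character vector mapping sample identifier to group label.
#' @export
cq_groups <- function(m) {
  stopifnot(inherits(m, "cq_matrix"))
  attr(m, "group")
}

#' Subset a Cq matrix by gene
#'
#' Keeps `cq_matrix` semantics (group labels travel with the samples).
#'
#' @param m a [cq_matrix()].
#' @param genes character vector of gene identifiers to keep.
#' @return A [cq_matrix()] restricted to `genes`.
#' @export
cq_subset <- function(m, genes) {
  stopifnot(inherits(m, "cq_matrix"))
  missing_g <- setdiff(genes, rownames(m))
  if (length(missing_g))
    stop("unknown gene(s): ", paste(missing_g, collapse = ", "))
  cq_matrix(unclass_cq(m)[genes, , drop = FALSE], group = cq_groups(m))
}

is_cq_matrix <- function(x) inherits(x, "cq_matrix")
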