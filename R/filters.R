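# Candidate exclusion rules applied before the stability algorithms:
# detection in all samples, between-group differential expression, and
# gene-family co-regulation.

#' Exclude genes not detected in every sample
#'
#' A reference candidate must amplify in all samples; any gene with at least
#' one undetermined Cq is removed.
#'
#' @param m a [cq_matrix()].
#' @return list with `cq` (the filtered matrix, free of missing values) and
#'   `decisions` (data frame `gene, rule, excluded, detail`).
#' @export
detection_filter <- function(m) {
  stopifnot(is_cq_matrix(m))
  n_missing <- rowSums(is.na(m))
  excluded <- n_missing > 0
  detail <- vapply(seq_len(nrow(m)), function(i) {
    if (!excluded[i]) return("detected in all samples")
    paste0("undetermined in: ",
           paste(colnames(m)[is.na(m[i, ])], collapse = ", "))
  }, "")
  decisions <- data.frame(gene = rownames(m), rule = "detection",
                          excluded = unname(excluded), detail = detail,
                          stringsAsFactors = FALSE)
  if (all(excluded)) stop("no candidates survive detection filter")
  list(cq = cq_subset(m, rownames(m)[!excluded]), decisions = decisions)
}

#' Mann-Whitney U test between two independent groups
#'
#' Thin wrapper around [stats::wilcox.test()] that reports the U statistic of
#' the first group and a two-sided p-value. Small untied samples
#' (n_A + n_B <= 24) are tested exactly; otherwise the normal approximation
#' with continuity and tie correction is used. Because the test is rank-based,
#' the p-value is invariant under any strictly monotone transform of the
#' pooled values (Cq, 2^-Cq, ... all give the same result).
#'
#' @param x,y numeric vectors, the two groups (both non-empty).
#' @param mode `"auto"` (default), `"exact"` (falls back to the approximation
#'   when ties are present) or `"approximate"`.
#' @return list with `u` (U statistic of `x`), `p` (two-sided p-value) and
#'   `mode_used`.
#' @export
mann_whitney_two_group <- function(x, y, mode = c("auto", "exact",
                                                  "approximate")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = !ties && length(x) + length(y) <= 24,
                  exact = !ties,
                  approximate = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(u = unname(ht$statistic), p = ht$p.value,
       mode_used = if (exact) "exact" else "approximate")
}

#' Exclude differentially expressed candidates between the two groups
#'
#' A reference gene must have similar average expression in both biological
#' conditions; candidates whose expression differs between groups at `alpha`
#' are excluded. By default each gene is tested with the Mann-Whitney U test
#' on the linear-scale relative quantities `2^-Cq` (the rank-based p-value is
#' identical for any monotone transform of Cq). Precomputed per-gene
#' p-values — e.g. the values printed in a study report — can be supplied
#' instead of re-testing.
#'
#' @param m a [cq_matrix()] without missing values and with exactly two groups,
#'   each with at least 2 samples.
#' @param alpha per-gene significance level, default 0.05 (no multiplicity
#'   correction: each candidate is judged on its own).
#' @param p optional named numeric vector of per-gene p-values to which the
#'   `alpha` rule is applied directly.
#' @return list with `cq` (matrix of retained genes) and `decisions`
#'   (data frame `gene, rule, excluded, p, detail`).
#' @export
de_filter <- function(m, alpha = 0.05, p = NULL) {
  stopifnot(is_cq_matrix(m))
  if (anyNA(m))
    stop("missing values present; run detection_filter() first")
  grp <- cq_groups(m)
  lv <- unique(grp)
  if (length(lv) != 2) stop("de_filter requires exactly two groups")
  if (any(table(grp) < 2)) stop("each group needs at least 2 samples")
  if (is.null(p)) {
    p <- vapply(rownames(m), function(g) {
      v <- 2^(-m[g, ])   # linear-scale relative quantities
      mann_whitney_two_group(v[grp == lv[1]], v[grp == lv[2]])$p
    }, numeric(1))
  } else {
    miss <- setdiff(rownames(m), names(p))
    if (length(miss))
      stop("p-values missing for gene(s): ", paste(miss, collapse = ", "))
    p <- p[rownames(m)]
  }
  excluded <- p < alpha
  decisions <- data.frame(
    gene = rownames(m), rule = "differential_expression",
    excluded = unname(excluded), p = unname(p),
    detail = sprintf("Mann-Whitney two-sided p = %.4g (alpha = %g)", p, alpha),
    stringsAsFactors = FALSE)
  if (all(excluded)) stop("no candidates survive differential-expression filter")
  list(cq = cq_subset(m, rownames(m)[!excluded]), decisions = decisions)
}

#' Flag candidates that share a miRNA gene family
#'
#' Pairwise-comparison stability methods assume candidates are not
#' co-regulated; members of one miRBase family are likely co-regulated, so if
#' two or more candidates share a family identifier all but one are flagged.
#' Flagged genes are reported, not dropped — exclusion is the caller's choice.
#'
#' @param genes character vector of candidate identifiers.
#' @param families named character vector, gene -> family identifier. Genes
#'   without annotation are warned about and treated as their own family.
#' @return data frame `gene, rule, excluded (always FALSE), flagged, detail`.
#' @export
family_filter <- function(genes, families) {
  fam <- families[genes]
  names(fam) <- genes
  unannotated <- is.na(fam)
  if (any(unannotated)) {
    warning("no family annotation for: ",
            paste(genes[unannotated], collapse = ", "),
            " (each treated as its own family)")
    fam[unannotated] <- paste0("unannotated:", genes[unannotated])
  }
  flagged <- logical(length(genes))
  detail <- rep("family unique among candidates", length(genes))
  detail[unannotated] <- "unannotated; treated as its own family"
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) > 1) {
      flagged[idx[-1]] <- TRUE
      detail[idx] <- sprintf("family %s shared by: %s", f,
                             paste(genes[idx], collapse = ", "))
    }
  }
  data.frame(gene = genes, rule = "family", excluded = FALSE,
             flagged = flagged, detail = detail, stringsAsFactors = FALSE)
}
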