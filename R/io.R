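# Tabular input for Cq data, amplification efficiencies and family annotation.
#
# Two layouts are supported:
#  * long: columns sample, group, mirna, [replicate,] cq  (one row per well)
#  * wide: first column mirna, remaining columns one per sample or per
#    sample_replicate ("S01_1", "S01_2", ...); groups supplied separately.
# "Undetermined", "undetectable", "NA" and empty cells all mean: no
# amplification (stored as NA).

MISSING_MARKERS <- c("undetermined", "undetectable", "na", "")

parse_cq_field <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  is_missing <- tolower(x) %in% MISSING_MARKERS | is.na(x)
  if (any(!is_missing & is.na(out)))
    stop("non-numeric Cq value(s) that are not a recognised missing marker: ",
         paste(unique(x[!is_missing & is.na(out)]), collapse = ", "))
  out[is_missing] <- NA_real_
  out
}

#' Read a table of Cq values
#'
#' Reads RT-qPCR Cq data from a delimited text file in either long or wide
#' layout. Cells equal to `"Undetermined"`, `"undetectable"`, `"NA"` or empty
#' are treated as undetermined reactions and become `NA`.
#'
#' If the file carries a single measurement per (gene, sample) the result is a
#' [cq_matrix()]; if technical replicates are present (a `replicate` column in
#' long layout, or `sample_replicate` column headers in wide layout) the result
#' is a `cq_replicates` object to be passed to [collapse_replicates()].
#'
#' @param path file path (CSV by default; `sep` is passed to
#'   [utils::read.table()]).
#' @param layout `"long"` (columns `sample, group, mirna, [replicate,] cq`) or
#'   `"wide"` (first column `mirna`, one column per sample or
#'   `sample_replicate`).
#' @param group_map for the wide layout: named character vector or two-column
#'   data frame (`sample`, `group`) giving each sample's biological group.
#' @param sep field separator, default `","`.
#' @return A [cq_matrix()], or a `cq_replicates` object when technical
#'   replicates are present.
#' @export
read_cq_table <- function(path, layout = c("long", "wide"), group_map = NULL,
                          sep = ",") {
  layout <- match.arg(layout)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (layout == "long") parse_long_cq(df) else parse_wide_cq(df, group_map)
}

parse_long_cq <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("sample", "group", "mirna", "cq")
  if (!all(need %in% names(df)))
    stop("long layout requires columns: ", paste(need, collapse = ", "))
  has_rep <- "replicate" %in% names(df)
  rep <- if (has_rep) df$replicate else rep("1", nrow(df))
  key <- paste(df$mirna, df$sample, rep, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicate (gene, sample, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  grp <- tapply(df$group, df$sample, unique)
  multi <- names(grp)[lengths(grp) > 1]
  if (length(multi))
    stop("sample(s) listed under more than one group: ",
         paste(multi, collapse = ", "))
  long <- data.frame(sample = df$sample, group = df$group, mirna = df$mirna,
                     replicate = rep, cq = parse_cq_field(df$cq),
                     stringsAsFactors = FALSE)
  if (has_rep && any(table(df$mirna, df$sample) > 1))
    return(new_cq_replicates(long))
  long_to_cq_matrix(long)
}

parse_wide_cq <- function(df, group_map) {
  if (is.null(group_map))
    stop("wide layout requires `group_map` (sample -> group)")
  if (is.data.frame(group_map)) {
    gm <- stats::setNames(as.character(group_map$group),
                          as.character(group_map$sample))
  } else gm <- group_map
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in wide table")
  cols <- names(df)[-1]
  # sample_replicate headers: strip a trailing _<number> shared by a sample
  rep_match <- regmatches(cols, regexec("^(.*)_([0-9]+)$", cols))
  has_rep_suffix <- lengths(rep_match) == 3
  base <- ifelse(has_rep_suffix, vapply(rep_match, function(x)
    if (length(x) == 3) x[2] else NA_character_, ""), cols)
  replicated <- all(has_rep_suffix) && anyDuplicated(base) > 0
  vals <- vapply(seq_along(cols),
                 function(j) parse_cq_field(df[[j + 1]]), numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, cols))
  if (!replicated) {
    if (!all(cols %in% names(gm)))
      stop("group_map misses sample(s): ",
           paste(setdiff(cols, names(gm)), collapse = ", "))
    return(cq_matrix(vals, group = gm[cols]))
  }
  repl <- vapply(rep_match, function(x) x[3], "")
  long <- data.frame(
    sample = rep(base, each = nrow(vals)),
    group = rep(gm[base], each = nrow(vals)),
    mirna = rep(genes, times = length(cols)),
    replicate = rep(repl, each = nrow(vals)),
    cq = as.vector(vals), stringsAsFactors = FALSE)
  if (anyNA(long$group))
    stop("group_map misses sample(s): ",
         paste(unique(long$sample[is.na(long$group)]), collapse = ", "))
  new_cq_replicates(long)
}

new_cq_replicates <- function(long) {
  stopifnot(all(c("sample", "group", "mirna", "replicate", "cq") %in%
                  names(long)))
  grp <- tapply(long$group, long$sample, unique)
  if (any(lengths(grp) > 1))
    stop("sample(s) listed under more than one group: ",
         paste(names(grp)[lengths(grp) > 1], collapse = ", "))
  structure(long, class = c("cq_replicates", "data.frame"))
}

long_to_cq_matrix <- function(long) {
  genes <- unique(long$mirna)
  samples <- unique(long$sample)
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  vals[cbind(match(long$mirna, genes), match(long$sample, samples))] <- long$cq
  gm <- stats::setNames(long$group, long$sample)
  gm <- gm[!duplicated(names(gm))]
  cq_matrix(vals, group = gm[samples])
}

#' Read per-miRNA amplification efficiencies
#'
#' @param path CSV with columns `mirna`, `e_percent`.
#' @return An efficiency map (see [efficiency_map()]).
#' @export
read_efficiencies <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("mirna", "e_percent") %in% names(df)))
    stop("efficiency file requires columns mirna, e_percent")
  efficiency_map(stats::setNames(as.numeric(df$e_percent),
                                 as.character(df$mirna)))
}

#' Read family annotations
#'
#' @param path CSV with columns `mirna`, `family_id`.
#' @return Named character vector, gene -> miRBase family identifier.
#' @export
read_families <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("mirna", "family_id") %in% names(df)))
    stop("family file requires columns mirna, family_id")
  stats::setNames(as.character(df$family_id), as.character(df$mirna))
}
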