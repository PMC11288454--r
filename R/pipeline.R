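# End-to-end orchestration: replicate QC -> candidate filters -> four
# stability algorithms (under both efficiency and grouping settings) ->
# consensus -> pairwise variation and the recommended reference set.

#' Run the full reference-miRNA selection pipeline
#'
#' Stages, in order: technical-replicate collapse (QC), detection filter,
#' differential-expression filter, family check, stability analysis with
#' geNorm (at 100% efficiency and, when efficiencies are supplied, at the
#' calculated E%), the model-based grouped/ungrouped decomposition
#' ([normfinder_stability()]), [bestkeeper()] and [delta_ct()], consensus
#' ranking, and the geNorm pairwise-variation series that fixes the optimal
#' number of reference genes. The consensus consumes the simple-flavoured
#' rankings (geNorm at E = 2, ungrouped decomposition, BestKeeper, delta-Ct),
#' matching the common web-tool behaviour; the efficiency-corrected and
#' grouped variants are reported alongside.
#'
#' @param cq a [cq_matrix()], a `cq_replicates` object, or a path to a long
#'   layout CSV (see [read_cq_table()]).
#' @param efficiencies optional [efficiency_map()], named E% vector, or path
#'   to an efficiency CSV.
#' @param families optional named gene -> family vector or path to a family
#'   CSV.
#' @param alpha differential-expression significance level, default 0.05.
#' @param de_p optional named per-gene p-values forwarded to [de_filter()].
#' @param v_cutoff pairwise-variation cutoff, default 0.15.
#' @param replicate_tolerance replicate-spread tolerance in cycles,
#'   default 0.3.
#' @param profile_range working Cq range for [cq_profile()], default
#'   `c(24, 30)`.
#' @param depth top-set depth for [top_overlap()], default 4.
#' @return list of class `pipeline_report` with elements `qc`, `profile`,
#'   `decisions`, `family_check`, `stability` (named list of result tables),
#'   `consensus`, `overlap`, `v_series` (per efficiency setting),
#'   `optimal_n`, `recommended` (character vector, or all candidates with a
#'   warning flag when the cutoff is never reached), `cutoff_reached`,
#'   `genes_analysed` and `parameters`.
#' @export
run_pipeline <- function(cq, efficiencies = NULL, families = NULL,
                         alpha = 0.05, de_p = NULL, v_cutoff = 0.15,
                         replicate_tolerance = 0.3, profile_range = c(24, 30),
                         depth = 4) {
  if (is.character(cq)) cq <- read_cq_table(cq, layout = "long")
  qc <- NULL
  if (inherits(cq, "cq_replicates")) {
    collapsed <- collapse_replicates(cq, tolerance = replicate_tolerance)
    qc <- collapsed$qc
    cq <- collapsed$cq
  }
  stopifnot(is_cq_matrix(cq))
  if (is.character(efficiencies) && is.null(names(efficiencies)))
    efficiencies <- read_efficiencies(efficiencies)
  if (is.numeric(efficiencies)) efficiencies <- efficiency_map(efficiencies)
  if (is.character(families) && is.null(names(families)))
    families <- read_families(families)

  profile <- cq_profile(cq, low = profile_range[1], high = profile_range[2])

  det <- detection_filter(cq)
  de <- de_filter(det$cq, alpha = alpha, p = de_p)
  decisions <- rbind(det$decisions,
                     cbind(de$decisions[, c("gene", "rule", "excluded")],
                           detail = de$decisions$detail)[, names(det$decisions)])
  m <- de$cq
  if (nrow(m) < 3)
    stop("insufficient candidates for geNorm/V analysis (",
         nrow(m), " survive the filters)")
  fam_check <- if (!is.null(families)) family_filter(rownames(m), families)
               else NULL

  q_e2 <- relative_quantities(m, eff = NULL)
  gn_e2 <- genorm_rank(q_e2)
  nf_un <- normfinder_stability(m, use_groups = FALSE)
  nf_gr <- normfinder_stability(m, use_groups = TRUE)
  bk <- bestkeeper(m)
  dc <- delta_ct(m)

  stab <- list(genorm_e100 = gn_e2$table, normfinder_ungrouped = nf_un$table,
               normfinder_grouped = nf_gr$table, bestkeeper = bk$table,
               delta_ct = dc$table)
  v_series <- list(e100 = pairwise_variation(q_e2, gn_e2, cutoff = v_cutoff))
  if (!is.null(efficiencies)) {
    q_eff <- relative_quantities(m, eff = efficiencies)
    gn_eff <- genorm_rank(q_eff)
    stab$genorm_calc_e <- gn_eff$table
    v_series$calc_e <- pairwise_variation(q_eff, gn_eff, cutoff = v_cutoff)
  }

  ranks <- stability_ranks(genorm = gn_e2, normfinder = nf_un,
                           bestkeeper = bk, delta_ct = dc)
  cons <- consensus(ranks)
  overlap <- top_overlap(ranks, depth = min(depth, nrow(m)))

  vn <- if (!is.null(efficiencies)) v_series$calc_e else v_series$e100
  cutoff_reached <- !is.na(vn$optimal_n)
  n_rec <- if (cutoff_reached) vn$optimal_n else nrow(m)
  recommended <- cons$table$gene[seq_len(n_rec)]

  structure(list(
    qc = qc, profile = profile, decisions = decisions,
    family_check = fam_check, stability = stab, consensus = cons$table,
    overlap = overlap,
    v_series = lapply(v_series, function(v)
      c(list(table = v$table), v[c("cutoff", "optimal_n")])),
    optimal_n = vn$optimal_n, cutoff_reached = cutoff_reached,
    recommended = recommended, genes_analysed = rownames(m),
    parameters = list(alpha = alpha, v_cutoff = v_cutoff,
                      replicate_tolerance = replicate_tolerance,
                      profile_range = profile_range, depth = depth,
                      efficiency_corrected = !is.null(efficiencies))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(" genes analysed:", paste(x$genes_analysed, collapse = ", "), "\n")
  cat(" excluded:",
      paste(unique(x$decisions$gene[x$decisions$excluded]), collapse = ", "),
      "\n")
  cat(" optimal n:", if (x$cutoff_reached) x$optimal_n else
    "not reached (using all candidates)", "\n")
  cat(" recommended set:", paste(x$recommended, collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits one TSV per table, a JSON summary that [read_report()] can reload
#' losslessly, and a plain-text narrative of the decisions taken (which genes
#' were excluded and why, how many reference genes are needed, and which).
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$qc)) wtsv(report$qc, "replicate_qc")
  wtsv(report$profile$profile, "cq_profile")
  wtsv(report$decisions, "filter_decisions")
  if (!is.null(report$family_check)) wtsv(report$family_check, "family_check")
  for (nm in names(report$stability)) wtsv(report$stability[[nm]],
                                           paste0("stability_", nm))
  wtsv(report$consensus, "consensus")
  for (nm in names(report$v_series))
    wtsv(report$v_series[[nm]]$table, paste0("pairwise_variation_", nm))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(serialize_report(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  paths <- c(paths, json_path)
  txt_path <- file.path(out_dir, "narrative.txt")
  writeLines(report_narrative(report), txt_path)
  invisible(c(paths, txt_path))
}

serialize_report <- function(report) {
  r <- unclass(report)
  r$profile <- list(profile = report$profile$profile,
                    pct_in_range = report$profile$pct_in_range)
  r$overlap <- list(sets = report$overlap$sets,
                    intersection = as.list(report$overlap$intersection),
                    pairwise = report$overlap$pairwise)
  r
}

#' Reload a pipeline report written by [write_report()]
#'
#' @param path either the output directory or the `report.json` inside it.
#' @return A `pipeline_report` equal (up to JSON number round-trip) to the
#'   one written.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$overlap$intersection <- as.character(unlist(r$overlap$intersection))
  r$overlap$sets <- lapply(r$overlap$sets, as.character)
  r$optimal_n <- if (is.null(r$optimal_n)) NA_integer_ else r$optimal_n
  structure(r, class = "pipeline_report")
}

report_narrative <- function(report) {
  dec <- report$decisions
  lines <- c("Reference miRNA selection - decision narrative", "")
  det <- dec[dec$rule == "detection" & dec$excluded, ]
  lines <- c(lines, if (nrow(det))
    sprintf("%s was excluded from the stability analyses because it was not detected in all samples (%s).",
            det$gene, det$detail)
    else "All candidates were detected in all samples.")
  de <- dec[dec$rule == "differential_expression" & dec$excluded, ]
  lines <- c(lines, if (nrow(de))
    sprintf("%s was excluded because its average expression differs between the groups (%s); a reference gene requires similar expression across conditions.",
            de$gene, de$detail)
    else "No candidate showed a significant between-group expression difference.")
  if (!is.null(report$family_check) && any(report$family_check$flagged))
    lines <- c(lines, sprintf(
      "Family co-regulation flags: %s.",
      paste(report$family_check$gene[report$family_check$flagged],
            collapse = ", ")))
  v <- report$v_series[[length(report$v_series)]]
  vn_desc <- paste(sprintf("V%d/%d = %.3f", v$table$n, v$table$n + 1,
                           v$table$v), collapse = "; ")
  lines <- c(lines, "", sprintf("Pairwise variation (cutoff %.2f): %s.",
                                v$cutoff, vn_desc))
  if (report$cutoff_reached) {
    lines <- c(lines, sprintf(
      "The first V below the cutoff fixes the optimal number of reference genes at %d.",
      report$optimal_n),
      sprintf("Recommended reference set: %s.",
              paste(report$recommended, collapse = ", ")))
  } else {
    lines <- c(lines,
      "WARNING: no pairwise variation fell below the cutoff; the optimal number of reference genes was not reached.",
      sprintf("Using all %d analysed candidates is advised: %s.",
              length(report$recommended),
              paste(report$recommended, collapse = ", ")))
  }
  lines
}
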