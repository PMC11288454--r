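# Synthetic Cq generator. Emulates the structure of a two-group RT-qPCR
# reference-candidate experiment: per-gene baseline Cq, a disease-group shift,
# a shared per-sample loading effect (pipetting / input amount) that induces
# inter-gene correlation, gene-specific biological noise, technical-replicate
# jitter, and optional dropout (undetermined wells).

#' Build a simulation configuration
#'
#' The generative model for gene g, sample j (replicate r) is
#' `Cq_gjr = mu_g + delta_g * [j in case group] + u_j + e_gj + eta_gjr`
#' with `u_j ~ N(0, tau^2)` shared by all genes of a sample,
#' `e_gj ~ N(0, sigma_g^2)` gene-specific noise, and `eta` replicate jitter.
#' Dropout (undetermined wells) is applied last to designated genes.
#'
#' @param genes data frame with columns `name`, `mean_cq` (control-group mean,
#'   cycles), `sigma` (gene noise SD, cycles) and optionally `sigma_case`
#'   (case-group noise SD; defaults to `sigma`), `delta` (case-minus-control
#'   shift, cycles; default 0), `family` (annotation id), `e_percent`
#'   (default 100), `n_dropout` (number of samples forced undetermined,
#'   default 0).
#' @param n_per_group samples per group (>= 2), default 10.
#' @param n_replicates technical replicates per well, default 3.
#' @param replicate_sd replicate jitter SD in cycles, default 0.05 (the
#'   expected spread of a triplicate is then well inside the 0.3-cycle rule).
#' @param tau shared per-sample loading SD in cycles, default 0.5.
#' @param group_labels length-2 character, default
#'   `c("control", "endometriosis")`; the shift `delta` applies to the second.
#' @param seed default RNG seed used by [simulate_cq()].
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(genes, n_per_group = 10, n_replicates = 3,
                              replicate_sd = 0.05, tau = 0.5,
                              group_labels = c("control", "endometriosis"),
                              seed = 1L) {
  stopifnot(is.data.frame(genes), all(c("name", "mean_cq", "sigma") %in%
                                        names(genes)))
  if (!"sigma_case" %in% names(genes)) genes$sigma_case <- genes$sigma
  if (!"delta" %in% names(genes)) genes$delta <- 0
  if (!"family" %in% names(genes)) genes$family <- NA_character_
  if (!"e_percent" %in% names(genes)) genes$e_percent <- 100
  if (!"n_dropout" %in% names(genes)) genes$n_dropout <- 0L
  if (any(genes$sigma < 0) || any(genes$sigma_case < 0) ||
      replicate_sd < 0 || tau < 0)
    stop("standard deviations must be >= 0")
  if (n_per_group < 2) stop("need at least 2 samples per group")
  if (length(group_labels) != 2) stop("exactly 2 group labels")
  structure(list(genes = genes, n_per_group = n_per_group,
                 n_replicates = n_replicates, replicate_sd = replicate_sd,
                 tau = tau, group_labels = group_labels, seed = seed),
            class = "sim_config")
}

#' Simulate a Cq dataset from a configuration
#'
#' Identical `(config, seed)` always yields the identical dataset.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list of class `sim_dataset`:
#'   \describe{
#'     \item{replicates}{`cq_replicates` long data frame
#'       (`sample, group, mirna, replicate, cq`) for [collapse_replicates()].}
#'     \item{cq}{[cq_matrix()] of true per-well means (replicates collapsed,
#'       no jitter), for convenience.}
#'     \item{truth}{data frame `gene, sigma, delta, shifted, truth_rank`
#'       (ascending true noise SD; genes with a group shift are flagged
#'       unstable).}
#'     \item{config, seed}{the generating parameters.}
#'   }
#' @export
simulate_cq <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- config$genes
  n <- config$n_per_group
  samples <- c(sprintf("%s_%02d", config$group_labels[1], seq_len(n)),
               sprintf("%s_%02d", config$group_labels[2], seq_len(n)))
  group <- stats::setNames(rep(config$group_labels, each = n), samples)
  is_case <- group == config$group_labels[2]
  k <- nrow(g)
  u <- stats::rnorm(2 * n, 0, config$tau)
  sd_mat <- outer(g$sigma, !is_case) + outer(g$sigma_case, is_case)
  mu <- matrix(g$mean_cq, k, 2 * n) +
    outer(g$delta, as.numeric(is_case)) +
    matrix(u, k, 2 * n, byrow = TRUE) +
    matrix(stats::rnorm(k * 2 * n, 0, sd_mat), k, 2 * n)
  dimnames(mu) <- list(g$name, samples)
  # dropout: undetermined wells for designated genes, random samples
  for (i in seq_len(k)) {
    nd <- g$n_dropout[i]
    if (nd > 0) mu[i, sample.int(2 * n, min(nd, 2 * n))] <- NA_real_
  }
  reps <- expand.grid(replicate = seq_len(config$n_replicates),
                      sample = samples, mirna = g$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_cq <- mu[cbind(match(reps$mirna, g$name), match(reps$sample, samples))]
  reps$cq <- base_cq + stats::rnorm(nrow(reps), 0, config$replicate_sd)
  reps$cq[is.na(base_cq)] <- NA_real_
  long <- data.frame(sample = reps$sample, group = unname(group[reps$sample]),
                     mirna = reps$mirna, replicate = as.character(reps$replicate),
                     cq = reps$cq, stringsAsFactors = FALSE)
  sigma_pooled <- sqrt((g$sigma^2 + g$sigma_case^2) / 2)
  truth <- data.frame(gene = g$name, sigma = sigma_pooled, delta = g$delta,
                      shifted = g$delta != 0,
                      truth_rank = rank(sigma_pooled, ties.method = "average"),
                      stringsAsFactors = FALSE)
  structure(list(replicates = new_cq_replicates(long),
                 cq = cq_matrix(mu, group = group),
                 truth = truth, config = config, seed = seed),
            class = "sim_dataset")
}

#' Reference panel description (printed study values)
#'
#' The published per-group Cq moments, assay efficiencies, miRBase family
#' identifiers and between-group Mann-Whitney p-values for the 9 detected
#' candidate miRNAs of the motivating endometriosis MenSC study. miR-101-3p,
#' the tenth candidate, has no printed moments because it was undetected in
#' some samples (its printed minimum Cq is 30.3).
#'
#' @return data frame `mirna, family, e_percent, mean_control, sd_control,
#'   mean_case, sd_case, p_value`.
#' @export
table1_reference <- function() {
  data.frame(
    mirna = c("miR-23a-3p", "miR-24-3p", "miR-16-5p", "miR-25-3p",
              "miR-191-5p", "miR-17-5p", "miR-30e-5p", "miR-103a-3p",
              "miR-22-5p"),
    family = c("MIPF0000027", "MIPF0000041", "MIPF0000006", "MIPF0000013",
               "MIPF0000194", "MIPF0000001", "MIPF0000005", "MIPF0000024",
               "MIPF0000053"),
    e_percent = c(104.4, 100.3, 103.6, 96.2, 101.9, 97.8, 100.9, 108.7, 101.6),
    mean_control = c(23.82, 24.00, 25.89, 27.49, 28.14, 28.50, 28.58, 29.00,
                     29.13),
    sd_control = c(0.97, 0.85, 1.28, 1.24, 0.99, 1.55, 1.28, 1.10, 1.20),
    mean_case = c(22.97, 23.28, 24.52, 26.28, 27.25, 27.41, 27.21, 27.95,
                  28.22),
    sd_case = c(0.93, 1.32, 1.42, 0.96, 1.35, 1.11, 1.73, 1.40, 1.48),
    p_value = c(0.0821, 0.2265, 0.0413, 0.0588, 0.2265, 0.0696, 0.0696,
                0.0963, 0.1306),
    stringsAsFactors = FALSE)
}

#' Simulation preset emulating the study panel
#'
#' Ten candidate miRNAs, 10 samples per group in triplicate. The nine
#' detected genes take their per-group means, marginal SDs and efficiencies
#' from [table1_reference()]; the undetected candidate (miR-101-3p, family
#' MIPF0000046) is given a control mean of 31.2 (so its minimum Cq lands near
#' the published 30.3), a modest case shift, and dropout in 3 wells.
#'
#' Printed SDs are marginal (per gene and group); each is split into the
#' shared per-sample loading variance `tau^2` and gene noise so that the
#' simulated marginal SD matches the printed value in expectation. The shared
#' fraction is configurable (default 0.5 of the smallest printed gene
#' variance, so every gene keeps positive own-noise) because the study does
#' not report inter-gene correlation. The case-group shift is the printed
#' mean difference (negative: expression up, Cq down, in the disease group).
#'
#' @param shared_fraction fraction of the smallest printed per-gene variance
#'   assigned to the shared loading effect, default 0.5.
#' @param seed default seed stored in the config.
#' @return a [simulation_config()].
#' @export
table1_preset <- function(shared_fraction = 0.5, seed = 1L) {
  t1 <- table1_reference()
  tau2 <- shared_fraction * min(c(t1$sd_control, t1$sd_case))^2
  genes <- data.frame(
    name = t1$mirna,
    mean_cq = t1$mean_control,
    sigma = sqrt(t1$sd_control^2 - tau2),
    sigma_case = sqrt(t1$sd_case^2 - tau2),
    delta = t1$mean_case - t1$mean_control,
    family = t1$family,
    e_percent = t1$e_percent,
    n_dropout = 0L,
    stringsAsFactors = FALSE)
  genes <- rbind(genes, data.frame(
    name = "miR-101-3p", mean_cq = 31.2,
    sigma = sqrt(max(0.8^2 - tau2, 0.04)),
    sigma_case = sqrt(max(0.8^2 - tau2, 0.04)), delta = -0.6,
    family = "MIPF0000046", e_percent = 100, n_dropout = 3L,
    stringsAsFactors = FALSE))
  simulation_config(genes, n_per_group = 10, n_replicates = 3,
                    replicate_sd = 0.05, tau = sqrt(tau2), seed = seed)
}

#' Designed-truth presets for recovery experiments
#'
#' `preset_one_noisy()` builds a panel of `k` genes with homogeneous noise
#' except one gene whose SD is `factor` times larger — the ground truth is
#' that this gene ranks last. `preset_designed_trio()` builds 3 designed
#' stable genes (sigma 0.45, comparable to a well-behaved reference panel)
#' and 5 noisier genes with graded SDs 0.6..1.0 — the ground truth is that
#' the trio occupies the top three ranks.
#'
#' @param k panel size, default 8.
#' @param sigma baseline gene noise SD (cycles), default 0.45.
#' @param factor noise multiplier of the designated unstable gene, default 3.
#' @param seed default seed stored in the config.
#' @return a [simulation_config()] (10 samples per group, triplicates,
#'   shared loading tau = 0.5).
#' @export
preset_one_noisy <- function(k = 8, sigma = 0.45, factor = 3, seed = 1L) {
  genes <- data.frame(
    name = sprintf("miR-sim-%02d", seq_len(k)),
    mean_cq = seq(24, 29, length.out = k),
    sigma = c(rep(sigma, k - 1), factor * sigma),
    stringsAsFactors = FALSE)
  simulation_config(genes, seed = seed)
}

#' @rdname preset_one_noisy
#' @export
preset_designed_trio <- function(seed = 1L) {
  genes <- data.frame(
    name = c(sprintf("miR-stable-%d", 1:3), sprintf("miR-noisy-%d", 1:5)),
    mean_cq = seq(24, 29, length.out = 8),
    sigma = c(rep(0.45, 3), c(0.6, 0.7, 0.8, 0.9, 1.0)),
    stringsAsFactors = FALSE)
  simulation_config(genes, seed = seed)
}
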