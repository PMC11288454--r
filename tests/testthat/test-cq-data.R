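# Cq input, replicate collapse, efficiency curves and Cq profiling.

test_that("wide files parse, with Undetermined mapping to missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mirna,s1,s2",
               "miR-a,24.1,Undetermined",
               "miR-b,25.0,26.2"), path)
  m <- read_cq_table(path, layout = "wide",
                     group_map = c(s1 = "control", s2 = "case"))
  expect_s3_class(m, "cq_matrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["miR-a", "s2"]))
  expect_equal(cq_groups(m), c(s1 = "control", s2 = "case"))
})

test_that("long files parse and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,mirna,replicate,cq",
               "s1,control,miR-a,1,24.0",
               "s1,control,miR-a,2,24.2",
               "s2,case,miR-a,1,undetectable",
               "s2,case,miR-a,2,25.1"), path)
  reps <- read_cq_table(path, layout = "long")
  expect_s3_class(reps, "cq_replicates")
  expect_equal(sum(is.na(reps$cq)), 1L)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,mirna,replicate,cq",
               "s1,control,miR-a,1,24.0",
               "s1,control,miR-a,1,24.2"), dup)
  expect_error(read_cq_table(dup, layout = "long"),
               "miR-a / s1 / 1")

  twogrp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,mirna,replicate,cq",
               "s1,control,miR-a,1,24.0",
               "s1,case,miR-b,1,25.0"), twogrp)
  expect_error(read_cq_table(twogrp, layout = "long"),
               "more than one group")
})

test_that("replicate collapse averages, flags spread, is order-invariant", {
  mk <- function(cqs) {
    data.frame(sample = "s1", group = "control", mirna = "miR-a",
               replicate = as.character(seq_along(cqs)), cq = cqs)
  }
  res <- collapse_replicates(mk(c(25.0, 25.0, 25.0)))
  expect_equal(unname(res$cq["miR-a", "s1"]), 25.0)
  expect_equal(res$qc$flag, "pass")

  # spread 0.4 exceeds the 0.3-cycle rule: flagged but retained
  res <- collapse_replicates(mk(c(25.0, 25.2, 25.4)), tolerance = 0.3)
  expect_equal(unname(res$cq["miR-a", "s1"]), 25.2)
  expect_equal(res$qc$flag, "spread_exceeds_tolerance")
  expect_equal(res$qc$spread, 0.4)

  res <- collapse_replicates(mk(c(24.9, 25.1)))
  expect_equal(unname(res$cq["miR-a", "s1"]), 25.0)
  expect_equal(res$qc$flag, "pass")

  # permutation invariance of replicate order; mean within [min, max]
  set.seed(42)
  for (i in 1:10) {
    v <- stats::rnorm(3, 25, 0.3)
    a <- collapse_replicates(mk(v))
    b <- collapse_replicates(mk(sample(v)))
    expect_equal(a$cq["miR-a", "s1"], b$cq["miR-a", "s1"])
    expect_gte(a$cq["miR-a", "s1"], min(v))
    expect_lte(a$cq["miR-a", "s1"], max(v))
  }

  # all replicates undetermined -> missing output, flagged
  allna <- mk(c(NA, NA, NA))
  res <- collapse_replicates(allna)
  expect_true(is.na(res$cq["miR-a", "s1"]))
  expect_equal(res$qc$flag, "all_missing")
})

test_that("efficiency from standard curves matches the closed form", {
  # perfect doubling: E% exactly 100 for any depth >= 3
  for (pts in c(3, 5, 7)) {
    e <- efficiency_from_curve(1 / 2^(0:(pts - 1)), 20 + 0:(pts - 1))
    expect_equal(e$e_percent, 100, tolerance = 1e-12)
    expect_true(e$accepted)
    expect_equal(e$e_base, 2)
  }
  # slope -3.32 on log10: closed-form oracle 100*(10^(1/3.32)-1)
  dil <- 10^-(0:4)
  cq <- 20 + 3.32 * (0:4)
  e <- efficiency_from_curve(dil, cq, log_base = 10)
  expect_equal(e$e_percent, 100 * (10^(1 / 3.32) - 1), tolerance = 1e-9)
  expect_true(e$accepted)
  # slope -4 on log10 -> ~77.8%, rejected
  e <- efficiency_from_curve(dil, 20 + 4 * (0:4), log_base = 10)
  expect_equal(e$e_percent, 100 * (10^0.25 - 1), tolerance = 1e-9)
  expect_false(e$accepted)
  # rising curve is invalid
  expect_error(efficiency_from_curve(dil, 20 - (0:4), log_base = 10),
               "invalid curve")
})

test_that("efficiency map encodes E_base = 1 + E%/100", {
  em <- efficiency_map(c("miR-a" = 104.4, "miR-b" = 100, "miR-c" = 89))
  expect_equal(em$e_base, c(2.044, 2, 1.89))
  expect_equal(em$accepted, c(TRUE, TRUE, FALSE))
})

test_that("cq profile statistics, flags and in-range percentage", {
  m1 <- cq_matrix(matrix(27, 1, 3, dimnames = list("miR-a", paste0("s", 1:3))),
                  group = rep("all", 3))
  pr <- cq_profile(m1)
  expect_equal(pr$profile$mean, 27)
  expect_equal(pr$profile$sd, 0)
  expect_equal(pr$profile$flag, "in_range")
  expect_equal(pr$pct_in_range, 100)

  m2 <- cq_matrix(matrix(c(33, 33, 31, 31, 14, 14, 25, 25), 4, 2,
                         byrow = TRUE,
                         dimnames = list(paste0("g", 1:4), c("s1", "s2"))),
                  group = c(s1 = "a", s2 = "b"))
  pr <- cq_profile(m2)
  expect_equal(pr$profile$flag, c("too_high", "high", "too_low", "in_range"))
  expect_equal(pr$pct_in_range, 25)

  # invariant to gene ordering and to wide vs long input layout
  m <- random_cq_matrix(5, 6, seed = 3)
  shuffled <- cq_subset(m, rev(rownames(m)))
  expect_equal(cq_profile(m)$pct_in_range, cq_profile(shuffled)$pct_in_range)

  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  vals <- unclass(m)
  writeLines(c(paste0("mirna,", paste(colnames(vals), collapse = ",")),
               vapply(rownames(vals), function(g)
                 paste(c(g, format(vals[g, ], digits = 15)), collapse = ","),
                 "")), wide)
  df <- expand.grid(sample = colnames(vals), mirna = rownames(vals),
                    stringsAsFactors = FALSE)
  df$group <- cq_groups(m)[df$sample]
  df$cq <- vals[cbind(df$mirna, df$sample)]
  utils::write.csv(df[, c("sample", "group", "mirna", "cq")], long,
                   row.names = FALSE)
  mw <- read_cq_table(wide, layout = "wide", group_map = cq_groups(m))
  ml <- read_cq_table(long, layout = "long")
  expect_equal(cq_profile(mw)$pct_in_range, cq_profile(m)$pct_in_range)
  expect_equal(cq_profile(ml)$pct_in_range, cq_profile(m)$pct_in_range)

  # degenerate inputs: empty matrices cannot even be constructed, and a gene
  # with no detected value cannot be profiled
  expect_error(cq_matrix(matrix(numeric(0), 0, 0), group = character(0)))
  v <- unclass(m)
  v[1, ] <- NA
  expect_error(cq_profile(cq_matrix(v, group = cq_groups(m))),
               "no detected value")
})
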