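test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_subjects = 10, cluster_sizes = c(6, 5)),
               "sum to n_subjects")
  expect_error(generator_config(n_subjects = 10, cluster_sizes = c(5, 5),
                                n_proteins = 5, up_in_c2 = 4, up_in_c1 = 2),
               "exceed the panel")
  expect_error(generator_config(covariate_prevalences = list(a = c(0.5, 1.2))),
               "prevalence")
  expect_error(generator_config(n_subjects = 10, cluster_sizes = c(5, 5),
                                transition_counts = c(4, 3, 2, 2)),
               "transition_counts")
  expect_error(generate_healthy(
    generator_config(n_subjects = 10, cluster_sizes = c(5, 5),
                     up_in_c2 = 2)), "no planted sets")
})

test_that("noise-free construction plants exact group differences", {
  coh <- generate_cohort(clean_config())
  X <- log2_transform(coh$matrix)
  lab <- coh$truth$labels
  pid <- coh$truth$up_c2
  d <- mean(X$values[lab == 2, pid]) - mean(X$values[lab == 1, pid])
  expect_equal(d, 1.0, tolerance = 1e-12)
  # non-planted proteins show no difference
  other <- setdiff(sprintf("P%04d", 1:20), pid)
  d0 <- colMeans(X$values[lab == 2, other]) - colMeans(X$values[lab == 1, other])
  expect_equal(max(abs(d0)), 0, tolerance = 1e-12)
})

test_that("the learning-cohort scenario has the planted dimensions", {
  coh <- generate_cohort(scenario_config("cobra_v1"))
  expect_equal(dim(coh$matrix), c(241L, 1305L + 6L))
  expect_equal(as.vector(table(coh$truth$labels)), c(126L, 115L))
  expect_length(coh$truth$up_c2, 90L)
  expect_length(coh$truth$up_c1, 6L)
  expect_true(all(c(coh$truth$up_c2, coh$truth$up_c1) %in%
                    colnames(coh$matrix$values)))
  # control probes flagged and disjoint from biology
  expect_gte(sum(coh$meta$is_hyb_control), 3L)
  expect_gte(sum(coh$meta$is_calibrator), 3L)
})

test_that("generation is reproducible and seeds only move the noise", {
  cfg <- medium_config(seed = 5L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(medium_config(seed = 6L))
  expect_equal(as.vector(table(a$truth$labels)),
               as.vector(table(c2$truth$labels)))
  expect_false(identical(a$matrix$values, c2$matrix$values))
})

test_that("empirical fold changes concentrate around the planted effects", {
  # SE of a mean difference at ~120/group with sd 0.5 is ~0.065, so planted
  # log2 fold changes are recovered to a few hundredths on average.
  coh <- generate_cohort(scenario_config("cobra_v1"))
  X <- log2_transform(coh$matrix)
  lab <- coh$truth$labels
  emp <- colMeans(X$values[lab == 2, coh$truth$up_c2]) -
    colMeans(X$values[lab == 1, coh$truth$up_c2])
  dev <- emp - coh$truth$effects_c2
  expect_lt(mean(abs(dev)), 0.08)
  expect_lt(max(abs(dev)), 0.25)
})

test_that("paired-visit truth follows the planted transition structure", {
  # single subject staying in Cluster 1
  cfg1 <- generator_config(n_subjects = 1L, cluster_sizes = c(1L, 0L),
                           n_proteins = 20L, up_in_c2 = 2L, up_in_c1 = 0L,
                           noise_sd = 0, plate_shift_sd = 0,
                           hyb_drift_sd = 0, control_noise_sd = 0,
                           n_plates = 1L,
                           transition_counts = c(1L, 0L, 0L, 0L), seed = 3L)
  pv1 <- generate_paired_visits(cfg1)
  expect_equal(unname(pv1$truth$labels_v1), 1L)
  expect_equal(unname(pv1$truth$labels_v2), "1")
  expect_equal(pv1$visit1$values[, pv1$truth$up_c2],
               pv1$visit2$values[, pv1$truth$up_c2])

  pv <- generate_paired_visits(scenario_config("paired_visits"))
  tr <- pv$truth$transition
  expect_equal(sum(tr), 163)
  # origin row sums: 68+29 = 97 in Cluster 1, 26+40 = 66 in Cluster 2
  expect_equal(as.vector(rowSums(tr)), c(97, 66))
  expect_equal(as.vector(tr["1", c("1", "mixed")]), c(68, 29))
  expect_equal(as.vector(tr["2", c("1", "2")]), c(26, 40))
})

test_that("noise-free stayers have identical group means at both visits", {
  cfg <- generator_config(n_subjects = 12L, cluster_sizes = c(7L, 5L),
                          n_proteins = 30L, up_in_c2 = 4L, up_in_c1 = 1L,
                          noise_sd = 0, plate_shift_sd = 0, hyb_drift_sd = 0,
                          control_noise_sd = 0, n_plates = 1L,
                          transition_counts = c(7L, 5L, 0L, 0L), seed = 8L)
  pv <- generate_paired_visits(cfg)
  expect_equal(pv$visit1$values, pv$visit2$values, tolerance = 1e-12)
})

test_that("mixed-profile subjects carry half of the Cluster-2 effects", {
  cfg <- generator_config(n_subjects = 4L, cluster_sizes = c(3L, 1L),
                          n_proteins = 10L, up_in_c2 = 2L, up_in_c1 = 0L,
                          effect_log2fc_range = c(1, 1), noise_sd = 0,
                          plate_shift_sd = 0, hyb_drift_sd = 0,
                          control_noise_sd = 0, n_plates = 1L,
                          transition_counts = c(2L, 1L, 1L, 0L), seed = 4L)
  pv <- generate_paired_visits(cfg)
  X2 <- log2_transform(pv$visit2)
  mixed <- names(pv$truth$labels_v2)[pv$truth$labels_v2 == "mixed"]
  stay1 <- names(pv$truth$labels_v2)[pv$truth$destination == "stay1"]
  gap <- mean(X2$values[mixed, pv$truth$up_c2]) -
    mean(colMeans(X2$values[stay1, pv$truth$up_c2, drop = FALSE]))
  expect_equal(gap, 0.5, tolerance = 1e-12)
})

test_that("cluster-conditional covariates follow their prevalences", {
  lab <- stats::setNames(rep(1:2, c(126, 115)), sprintf("S%03d", 1:241))
  # prevalence (1, 0) reproduces the cluster-1 indicator exactly
  cov <- generate_covariates(lab, list(flag = c(1, 0)), seed = 2L)
  expect_equal(cov$flag, as.integer(lab == 1L))
  # emphysema-style prevalences stay inside binomial 99% bounds
  cov <- generate_covariates(lab, list(emph = c(0.52, 0.31)), seed = 7L)
  k1 <- sum(cov$emph[lab == 1L]); k2 <- sum(cov$emph[lab == 2L])
  expect_true(k1 >= qbinom(0.005, 126, 0.52) &&
                k1 <= qbinom(0.995, 126, 0.52))
  expect_true(k2 >= qbinom(0.005, 115, 0.31) &&
                k2 <= qbinom(0.995, 115, 0.31))
  expect_error(generate_covariates(lab, list(bad = c(-0.1, 0.5))),
               "\\[0, 1\\]")
})

test_that("a healthy cohort has no structure and feeds the pipeline", {
  h <- generate_healthy(scenario_config("healthy"))
  expect_equal(dim(h$matrix), c(50L, 1311L))
  expect_null(h$truth$labels)
  X <- preprocess(h$matrix, h$meta)
  res <- discover_endotypes(X, h$meta)
  expect_length(res$clusters$labels, 50L)
})

test_that("scenario files round-trip through the writer", {
  coh <- generate_cohort(clean_config())
  outdir <- withr::local_tempdir()
  write_scenario(coh, outdir)
  back <- read_matrix(file.path(outdir, "matrix.csv"),
                      file.path(outdir, "panel_meta.csv"))
  expect_equal(back$matrix$values, coh$matrix$values, tolerance = 1e-9)
  expect_equal(back$meta$is_hyb_control, coh$meta$is_hyb_control)
  expect_true(file.exists(file.path(outdir, "truth.json")))
})
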