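test_that("transfer validation is self-consistent on the learning cohort", {
  coh <- generate_cohort(medium_config(seed = 81L))
  X <- log2_transform(coh$matrix)
  learn <- discover_endotypes(X, coh$meta)
  learned_up <- up_set(learn$de, "up_in_2")
  tv <- transfer_validate(X, learned_up, coh$meta)
  expect_identical(tv$clusters$labels, learn$clusters$labels)
  expect_equal(tv$overlap$percentage, 100)
  expect_equal(tv$overlap$k, length(learned_up))
  expect_lt(tv$score_comparison$p, 0.001)
  expect_error(transfer_validate(X, c(learned_up, "MISSING"), coh$meta),
               "MISSING")
})

test_that("a second cohort with re-planted signal validates the endotypes", {
  coh <- generate_cohort(medium_config(seed = 82L))
  X <- log2_transform(coh$matrix)
  learned_up <- up_set(discover_endotypes(X, coh$meta)$de, "up_in_2")
  # second cohort, smaller and imbalanced, shares 60% of the planted set
  cfg2 <- generator_config(n_subjects = 47L, n_proteins = 600L,
                           cluster_sizes = c(34L, 13L),
                           up_in_c2 = 40L, up_in_c1 = 3L,
                           up_c2_ids = c(1:24, 101:116), up_c1_ids = 117:119,
                           seed = 83L)
  new <- generate_cohort(cfg2)
  Xn <- log2_transform(new$matrix)
  tv <- transfer_validate(Xn, learned_up, new$meta)
  sizes <- sort(as.vector(table(tv$clusters$labels)))
  expect_equal(sizes, c(13L, 34L))
  # learned score separates the new clusters in the planted direction
  expect_gt(tv$score_comparison$median_by_cluster[["cluster2"]],
            tv$score_comparison$median_by_cluster[["cluster1"]])
  expect_lt(tv$score_comparison$p, 0.01)
  expect_gt(tv$overlap$k, 10)
})

test_that("switching analysis counts concordance and the mixed zone", {
  # identical labels, no mixed zone
  lab <- stats::setNames(rep(1:2, c(6, 4)), sprintf("S%02d", 1:10))
  sc <- structure(data.frame(subject_id = names(lab),
                             score = c(rep(0, 6), rep(1, 4))),
                  class = c("ScoreVector", "data.frame"))
  sw <- switching_analysis(lab, lab, sc, band = c(0.5, 0.5))
  expect_equal(sw$concordant, 10L)
  expect_equal(sw$total, 10L)
  expect_equal(as.vector(sw$counts[, "mixed"]), c(0L, 0L))

  # planted transition structure: 68 stay-1, 40 stay-2, 29 mixed, 26 switch
  n <- 163
  ids <- sprintf("S%03d", 1:n)
  origin <- rep(c(1L, 1L, 2L, 2L), c(68, 29, 26, 40))
  v2lab <- rep(c(1L, 1L, 1L, 2L), c(68, 29, 26, 40))
  score <- rep(c(0, 0.5, 0, 1), c(68, 29, 26, 40)) +
    seq(-0.01, 0.01, length.out = n)
  sc2 <- structure(data.frame(subject_id = ids, score = score),
                   class = c("ScoreVector", "data.frame"))
  sw2 <- switching_analysis(stats::setNames(origin, ids),
                            stats::setNames(v2lab, ids), sc2)
  expect_equal(sw2$concordant, 108L)
  expect_equal(sw2$total, 163L)
  expect_equal(as.vector(sw2$counts["1", ]), c(68L, 0L, 29L))
  expect_equal(as.vector(sw2$counts["2", ]), c(26L, 40L, 0L))
  expect_lt(sw2$fisher_p, 0.001)

  # with the zone closed the same data give a plain 2x2 table
  sw3 <- switching_analysis(stats::setNames(origin, ids),
                            stats::setNames(v2lab, ids), sc2,
                            band = c(0.5, 0.5))
  expect_equal(sum(sw3$counts[, "mixed"]), 0L)
  expect_equal(sw3$concordant, 108L + 29L)

  expect_error(switching_analysis(stats::setNames(origin, ids),
                                  stats::setNames(v2lab[-1], ids[-1]), sc2),
               "unmatched")
})

test_that("concordance is symmetric in visit order", {
  set.seed(84)
  ids <- sprintf("S%02d", 1:40)
  l1 <- stats::setNames(sample(1:2, 40, replace = TRUE), ids)
  l2 <- stats::setNames(sample(1:2, 40, replace = TRUE), ids)
  sc <- structure(data.frame(subject_id = ids,
                             score = ifelse(l2 == 2, 1, 0) + rnorm(40, 0, 0.01)),
                  class = c("ScoreVector", "data.frame"))
  scr <- structure(data.frame(subject_id = ids,
                              score = ifelse(l1 == 2, 1, 0) + rnorm(40, 0, 0.01)),
                   class = c("ScoreVector", "data.frame"))
  a <- switching_analysis(l1, l2, sc, band = c(0.5, 0.5))
  b <- switching_analysis(l2, l1, scr, band = c(0.5, 0.5))
  expect_equal(a$concordant, b$concordant)
})

test_that("the paired scenario recovers the planted transition counts", {
  pv <- generate_paired_visits(scenario_config("paired_visits"))
  X1 <- preprocess(pv$visit1, pv$meta)
  X2 <- preprocess(pv$visit2, pv$meta)
  d1 <- discover_endotypes(X1, pv$meta)
  d2 <- discover_endotypes(X2, pv$meta)
  sc2 <- protein_score(X2, pv$truth$up_c2)
  sw <- switching_analysis(d1$clusters$labels, d2$clusters$labels, sc2)
  # planted concordance is 108/163; allow a few boundary subjects
  expect_gt(sw$concordant, 0.9 * 108)
  expect_lt(sw$concordant, 1.1 * 108)
  expect_equal(sum(sw$counts), 163)
  # the mixed zone captures roughly the 29 planted mixed profiles
  expect_gt(sum(sw$counts[, "mixed"]), 0.7 * 29)
  expect_lt(sum(sw$counts[, "mixed"]), 1.3 * 29)
})

test_that("visit-to-visit up-set overlap is summarized correctly", {
  mk_de <- function(ids_up2, ids_up1, universe) {
    structure(data.frame(
      protein_id = universe,
      log2fc = ifelse(universe %in% ids_up2, 1,
                      ifelse(universe %in% ids_up1, -1, 0)),
      fold_change = ifelse(universe %in% c(ids_up2, ids_up1), 2, 1),
      t_mod = 0, p = 0.5, degenerate = FALSE, q = 0.5,
      significant = universe %in% c(ids_up2, ids_up1),
      direction = ifelse(universe %in% ids_up2, "up_in_2",
                         ifelse(universe %in% ids_up1, "up_in_1", "none"))),
      class = c("DETable", "data.frame"))
  }
  universe <- sprintf("P%03d", 1:500)
  de1 <- mk_de(universe[1:90], universe[91:96], universe)
  self <- visit_consistency_report(de1, de1, universe)
  expect_equal(self$up_in_2$pct_of_v2, 100)
  # printed worked example: 75 of 83 visit-2 proteins shared -> 90%
  de2 <- mk_de(c(universe[1:75], universe[200:207]), universe[300:302],
               universe)
  rep2 <- visit_consistency_report(de1, de2, universe)
  expect_equal(rep2$up_in_2$n_v2, 83L)
  expect_equal(rep2$up_in_2$shared, 75L)
  expect_equal(rep2$up_in_2$pct_of_v2, 90)
  expect_lt(rep2$up_in_2$p, 1e-10)
  # disjoint sets
  de3 <- mk_de(universe[400:420], universe[430], universe)
  rep3 <- visit_consistency_report(de1, de3, universe)
  expect_equal(rep3$up_in_2$shared, 0L)
  expect_gt(rep3$up_in_2$p, 0.5)
})
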