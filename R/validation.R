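#' Agnostic transfer validation in a new cohort
#'
#' Re-runs the full discovery stage on a new cohort *alone* — variance
#' filter, hierarchical clustering, moderated differential expression,
#' canonicalization — so the validation is agnostic to the learning
#' cohort's results. Only afterwards are the learned results brought in:
#' the learned up-set defines a protein score compared across the new
#' clusters, and the new Cluster-2 up-set is tested for overlap enrichment
#' against the learned one.
#'
#' @param X_new log2 `ExpressionMatrix` of the new cohort (same panel).
#' @param learned_up_set the learning cohort's Cluster-2 up-regulated
#'   protein ids.
#' @param meta [panel_meta()] for the shared panel.
#' @param fraction variance-filter fraction (default 0.10).
#' @param fc_threshold,q_threshold significance rule for the new cohort DE.
#' @return A list: `clusters` (canonical `ClusterResult`), `de`
#'   (significance-called `DETable`), `score_comparison`
#'   (from [compare_scores()] with the learned set), `overlap`
#'   (from [overlap_enrichment()] of new vs learned Cluster-2 up-sets).
#' @export
transfer_validate <- function(X_new, learned_up_set, meta, fraction = 0.10,
                              fc_threshold = 1.5, q_threshold = 0.05) {
  stopifnot(inherits(X_new, "ExpressionMatrix"))
  universe <- intersect(protein_ids(X_new), assay_proteins(meta))
  miss <- setdiff(learned_up_set, protein_ids(X_new))
  if (length(miss))
    stop("new cohort lacks learned protein(s): ",
         paste(miss, collapse = ", "))
  panel <- select_variable_proteins(X_new, fraction = fraction, meta = meta)
  cl <- hierarchical_cluster(X_new, panel = panel, k = 2L)
  de <- call_significant(
    moderated_ttest(X_new, cl$labels, proteins = universe),
    fc_threshold = fc_threshold, q_threshold = q_threshold)
  cl <- canonicalize_labels(cl, de, X_new)
  # recompute DE under the canonical orientation
  de <- call_significant(
    moderated_ttest(X_new, cl$labels, proteins = universe),
    fc_threshold = fc_threshold, q_threshold = q_threshold)
  sc <- protein_score(X_new, learned_up_set, set_id = "learned_up_set")
  cmp <- compare_scores(sc, cl$labels)
  ov <- overlap_enrichment(up_set(de, "up_in_2"), learned_up_set, universe)
  list(clusters = cl, de = de, score_comparison = cmp, overlap = ov)
}

#' Paired-visit cluster switching analysis
#'
#' Cross-tabulates independently derived visit-1 and visit-2 cluster
#' identities, with a third visit-2 destination, "mixed", for subjects
#' whose visit-2 protein score falls in the gap between the two visit-2
#' cluster score levels. Operationally, with `m1` and `m2` the visit-2
#' cluster score medians (low/high), a subject is mixed when their score
#' lies strictly inside the central band
#' `(m1 + band[1] * (m2 - m1), m1 + band[2] * (m2 - m1))`; the default
#' band (0.25, 0.75) is the middle half of the gap, and a zero-width band
#' (`c(0.5, 0.5)`) disables the mixed category, reducing the analysis to a
#' plain 2x2 transition table.
#'
#' Concordance counts subjects with the same non-mixed identity at both
#' visits; a Fisher exact test is run on the 2x2 collapse in which mixed
#' destinations are folded into Cluster 1 (the origin of mixed profiles).
#'
#' @param labels_v1,labels_v2 named canonical cluster labels (1/2) per
#'   subject id, one per visit, from independent clustering runs.
#' @param scores_v2 a [protein_score()] result on the visit-2 matrix with
#'   the learned up-set.
#' @param band numeric pair of gap fractions defining the mixed zone.
#' @return A `TransitionTable`: list with `counts` (origin 1/2 x
#'   destination 1/2/mixed), `concordant`, `total`, `fisher_p`,
#'   `mixed_rule`.
#' @export
switching_analysis <- function(labels_v1, labels_v2, scores_v2,
                               band = c(0.25, 0.75)) {
  ids <- names(labels_v1)
  if (is.null(ids) || is.null(names(labels_v2)))
    stop("labels must be named by subject id")
  unmatched <- c(setdiff(ids, names(labels_v2)),
                 setdiff(names(labels_v2), ids))
  if (length(unmatched))
    stop("unmatched subject id(s): ", paste(unique(unmatched), collapse = ", "))
  if (length(band) != 2L || band[1] > band[2] ||
      any(band < 0) || any(band > 1))
    stop("band must be an ordered pair of fractions in [0, 1]")
  l1 <- as.integer(labels_v1[ids])
  l2 <- as.integer(labels_v2[ids])
  sc <- scores_v2$score[match(ids, scores_v2$subject_id)]
  if (anyNA(sc)) stop("visit-2 scores must cover every paired subject")
  med <- tapply(sc, l2, stats::median)
  lohi <- sort(med)
  lo <- lohi[1]; hi <- lohi[2]
  zone <- c(lo + band[1] * (hi - lo), lo + band[2] * (hi - lo))
  dest <- ifelse(sc > zone[1] & sc < zone[2] & zone[1] < zone[2],
                 "mixed", as.character(l2))
  counts <- table(origin = factor(l1, levels = 1:2),
                  destination = factor(dest, levels = c("1", "2", "mixed")))
  concordant <- sum(dest == as.character(l1))
  collapse <- ifelse(dest == "mixed", "1", dest)
  fisher_p <- stats::fisher.test(
    table(factor(l1, levels = 1:2),
          factor(collapse, levels = c("1", "2"))))$p.value
  structure(
    list(counts = counts, concordant = concordant, total = length(ids),
         destination = stats::setNames(dest, ids), fisher_p = fisher_p,
         mixed_rule = sprintf(
           "score strictly inside (%.3f, %.3f); band fractions (%.2f, %.2f) of the cluster-median gap",
           zone[1], zone[2], band[1], band[2])),
    class = "TransitionTable")
}

#' @export
print.TransitionTable <- function(x, ...) {
  cat(sprintf("TransitionTable: %d/%d concordant (Fisher p = %.3g)\n",
              x$concordant, x$total, x$fisher_p))
  print(x$counts)
  invisible(x)
}

#' Consistency of up-regulated sets between two visits
#'
#' Summarizes how much of each visit's Cluster-2 (and Cluster-1) up-set is
#' shared with the other visit, with an upper-tail hypergeometric p for
#' the Cluster-2 overlap.
#'
#' @param de_v1,de_v2 significance-called `DETable`s from the two visits.
#' @param universe all assayed proteins.
#' @return A list per side (`up_in_2`, `up_in_1`): `n_v1`, `n_v2`,
#'   `shared`, `pct_of_v2` (integer percentage), `p` (hypergeometric,
#'   Cluster-2 side).
#' @export
visit_consistency_report <- function(de_v1, de_v2, universe) {
  one <- function(side) {
    s1 <- up_set(de_v1, side)
    s2 <- up_set(de_v2, side)
    shared <- length(intersect(s1, s2))
    p <- if (length(s2) && length(s1))
      overlap_enrichment(s1, s2, universe)$p else NA_real_
    list(n_v1 = length(s1), n_v2 = length(s2), shared = shared,
         pct_of_v2 = if (length(s2)) round(100 * shared / length(s2))
                     else NA_integer_,
         p = p)
  }
  list(up_in_2 = one("up_in_2"), up_in_1 = one("up_in_1"))
}
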