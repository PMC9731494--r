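#' Standardize and log2-transform a raw cohort
#'
#' Convenience composition of [standardize()] and [log2_transform()].
#'
#' @inheritParams standardize
#' @return A normalized log2 `ExpressionMatrix`.
#' @export
preprocess <- function(raw, meta, reference = NULL) {
  log2_transform(standardize(raw, meta, reference = reference))
}

#' Discover endotypes in a log2 cohort
#'
#' The learning stage in one call: variance filter, Ward clustering into
#' two groups, moderated differential expression over all assay proteins,
#' DE-based canonicalization of the cluster identities, and a final DE run
#' under the canonical orientation.
#'
#' @param X log2 `ExpressionMatrix`.
#' @param meta [panel_meta()] (controls are excluded from the variance
#'   filter and from testing).
#' @param fraction variance-filter fraction.
#' @param fc_threshold,q_threshold significance rule.
#' @return A list: `clusters` (canonical `ClusterResult`), `de`
#'   (significance-called `DETable`), `panel` (selected protein ids).
#' @export
discover_endotypes <- function(X, meta, fraction = 0.10,
                               fc_threshold = 1.5, q_threshold = 0.05) {
  universe <- intersect(protein_ids(X), assay_proteins(meta))
  panel <- select_variable_proteins(X, fraction = fraction, meta = meta)
  cl <- hierarchical_cluster(X, panel = panel, k = 2L)
  de <- call_significant(
    moderated_ttest(X, cl$labels, proteins = universe),
    fc_threshold = fc_threshold, q_threshold = q_threshold)
  cl <- canonicalize_labels(cl, de, X)
  de <- call_significant(
    moderated_ttest(X, cl$labels, proteins = universe),
    fc_threshold = fc_threshold, q_threshold = q_threshold)
  list(clusters = cl, de = de, panel = panel)
}
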