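#' Select the most variable proteins
#'
#' Ranks assay proteins by their standard deviation across subjects on the
#' log2 scale and returns the top fraction (floor of fraction x panel
#' size). Control probes are excluded before ranking; ties are broken by
#' protein id order so the selection is deterministic.
#'
#' @param X a log2 `ExpressionMatrix`.
#' @param fraction proportion of the panel to keep (default 0.10).
#' @param meta optional [panel_meta()]; when supplied, control probes are
#'   dropped before ranking.
#' @return Character vector of selected protein ids, most variable first.
#' @export
select_variable_proteins <- function(X, fraction = 0.10, meta = NULL) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$scale != "log2") stop("variance selection expects log2 values")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ids <- protein_ids(X)
  if (!is.null(meta)) ids <- intersect(ids, assay_proteins(meta))
  v <- X$values[, ids, drop = FALSE]
  sds <- apply(v, 2, stats::sd)
  n_keep <- floor(fraction * length(ids))
  if (n_keep < 2L) stop("fewer than 2 proteins selected; increase fraction")
  ord <- order(-sds, ids)
  ids[ord][seq_len(n_keep)]
}

#' Hierarchically cluster subjects on a protein panel
#'
#' Proteins are z-scored across subjects (zero mean, unit sd), subjects are
#' clustered by Euclidean distance with Ward linkage, and the tree is cut
#' into `k` groups. Group numbers at this stage are arbitrary; use
#' [canonicalize_labels()] to assign Cluster 1/2 identities.
#'
#' @param X a log2 `ExpressionMatrix`.
#' @param panel protein ids to cluster on (e.g. from
#'   [select_variable_proteins()]); defaults to all columns.
#' @param k number of groups (default 2).
#' @return A `ClusterResult`: list with `labels` (named integer vector),
#'   `selected_proteins`, `merge_tree` (the `hclust` object),
#'   `canonicalized` flag and `label_rule`.
#' @export
hierarchical_cluster <- function(X, panel = NULL, k = 2L) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.null(panel)) panel <- protein_ids(X)
  miss <- setdiff(panel, protein_ids(X))
  if (length(miss))
    stop("panel protein(s) absent from matrix: ", paste(miss, collapse = ", "))
  v <- X$values[, panel, drop = FALSE]
  if (nrow(v) < k) stop("k exceeds the number of subjects")
  sds <- apply(v, 2, stats::sd)
  if (all(sds == 0))
    stop("zero-variance panel: no protein varies across subjects")
  keep <- sds > 0
  z <- scale(v[, keep, drop = FALSE])
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(
    list(labels = labels, selected_proteins = panel, merge_tree = hc,
         canonicalized = FALSE, label_rule = "arbitrary (tree order)"),
    class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %s; sizes %s; panel of %d proteins\n",
              if (x$canonicalized) "canonical Cluster 1/2"
              else "uncanonicalized",
              paste(table(x$labels), collapse = "/"),
              length(x$selected_proteins)))
  invisible(x)
}

#' Assign canonical Cluster 1/2 identities
#'
#' The group with the larger number of significantly up-regulated proteins
#' (from a differential-expression table computed between the two raw
#' groups) becomes Cluster 2 — the identity of the cluster marked by a
#' broad up-regulation signature. On a tie, the group with the higher mean
#' log2 expression over the significant (or, failing that, all panel)
#' proteins becomes Cluster 2.
#'
#' @param result an uncanonicalized two-group `ClusterResult`.
#' @param de a [moderated_ttest()] + [call_significant()] `DETable`
#'   computed with `result$labels` as groups (group 2 minus group 1).
#' @param X the log2 `ExpressionMatrix` (used only for the tie rule).
#' @return The `ClusterResult` with labels possibly flipped so that label 2
#'   is canonical Cluster 2, `canonicalized = TRUE` and the rule recorded.
#' @export
canonicalize_labels <- function(result, de, X) {
  stopifnot(inherits(result, "ClusterResult"))
  if (length(unique(result$labels)) != 2L)
    stop("canonicalization requires exactly two clusters")
  n_up2 <- sum(de$significant & de$direction == "up_in_2")
  n_up1 <- sum(de$significant & de$direction == "up_in_1")
  if (n_up2 != n_up1) {
    flip <- n_up1 > n_up2
    rule <- sprintf("more significant up-regulated proteins (%d vs %d)",
                    max(n_up1, n_up2), min(n_up1, n_up2))
  } else {
    set <- de$protein_id[de$significant]
    if (!length(set)) set <- intersect(result$selected_proteins,
                                       protein_ids(X))
    sc <- protein_score(X, set)
    m2 <- mean(sc$score[result$labels == 2L])
    m1 <- mean(sc$score[result$labels == 1L])
    flip <- m1 > m2
    rule <- "tie on up-regulated counts; higher mean protein score"
  }
  if (flip) result$labels <- 3L - result$labels
  result$canonicalized <- TRUE
  result$label_rule <- rule
  result
}
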