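#' Per-patient protein score
#'
#' The protein score of a subject is the median of their log2 expression
#' over a designated up-regulated protein set (canonically the proteins up
#' in Cluster 2 of the learning cohort). It summarizes a broad
#' up-regulation signature in a single, outlier-robust number per patient.
#'
#' @param X a log2 `ExpressionMatrix`.
#' @param up_set nonempty character vector of protein ids present in `X`.
#' @param set_id provenance label stored with the scores.
#' @return A `ScoreVector` data.frame: `subject_id`, `score`; attribute
#'   `set_id` records the set used.
#' @export
protein_score <- function(X, up_set, set_id = "up_set") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!length(up_set)) stop("up_set must be nonempty")
  miss <- setdiff(up_set, protein_ids(X))
  if (length(miss))
    stop("up_set protein(s) missing from matrix: ",
         paste(miss, collapse = ", "))
  sc <- apply(X$values[, up_set, drop = FALSE], 1, stats::median)
  out <- data.frame(subject_id = subject_ids(X), score = unname(sc),
                    stringsAsFactors = FALSE)
  attr(out, "set_id") <- set_id
  class(out) <- c("ScoreVector", "data.frame")
  out
}

#' Compare protein scores between two clusters
#'
#' Two-sided Wilcoxon rank-sum comparison of the per-subject scores across
#' cluster labels: exact for small tie-free groups, normal approximation
#' with tie correction otherwise.
#'
#' @param scores a [protein_score()] result.
#' @param labels named cluster labels (1/2) per subject id.
#' @return A list: `median_by_cluster` (named length-2), `statistic`
#'   (rank-sum W of cluster 2 vs cluster 1), `p` (two-sided).
#' @export
compare_scores <- function(scores, labels) {
  stopifnot(inherits(scores, "ScoreVector"))
  lab <- labels[scores$subject_id]
  if (anyNA(lab)) stop("labels must cover every scored subject")
  s1 <- scores$score[lab == 1L | lab == "1"]
  s2 <- scores$score[lab == 2L | lab == "2"]
  if (!length(s1) || !length(s2)) stop("both clusters must be nonempty")
  wt <- stats::wilcox.test(s2, s1, alternative = "two.sided",
                           exact = (length(s1) <= 25 && length(s2) <= 25 &&
                                      !anyDuplicated(c(s1, s2))))
  list(median_by_cluster = c(cluster1 = stats::median(s1),
                             cluster2 = stats::median(s2)),
       statistic = unname(wt$statistic), p = wt$p.value)
}

#' Select the short biomarker signature
#'
#' Deterministic operationalization of a "rational ranking" of biomarkers
#' into a short signature of (by default) 11 Cluster-2 plus 4 Cluster-1
#' proteins:
#'
#' * **Cluster-2 side** — candidates are the top 10% of the significant
#'   `up_in_2` proteins by absolute log2 fold change. Each candidate is
#'   assigned to its most-enriched annotated pathway family (lowest
#'   enrichment q among the terms that contain it); within a family,
#'   candidates are ranked by their strongest clinical association
#'   (largest absolute log odds ratio over the configured outcomes).
#'   Families are visited in enrichment order (best q first) taking one
#'   representative per family per round, cycling until `n_cluster2`
#'   members are collected.
#' * **Cluster-1 side** — the significant `up_in_1` proteins minus an
#'   exclusion list (markers that failed external replication), ranked by
#'   absolute log2 fold change; the top `n_cluster1` are kept.
#'
#' Every ranking decision is appended to a selection log, making the
#' procedure auditable; the whole function is a pure function of its input
#' tables (ties broken by protein id).
#'
#' @param de a significance-called `DETable`.
#' @param enr an `EnrichmentTable` from [enrich()] whose `members` cover
#'   the candidate proteins.
#' @param or_table an `AssociationTable` from [protein_outcome_or()] (any
#'   number of outcomes; the strongest |log OR| per protein is used).
#' @param n_cluster2,n_cluster1 signature sizes per side (defaults 11 / 4).
#' @param top_fraction fraction of the `up_in_2` set considered (0.10).
#' @param exclude protein ids barred from the Cluster-1 side.
#' @return A `SignatureSpec`: data.frame `members` (protein_id, side,
#'   family), plus attribute `selection_log` (character).
#' @export
select_signature <- function(de, enr, or_table,
                             n_cluster2 = 11L, n_cluster1 = 4L,
                             top_fraction = 0.10, exclude = character(0)) {
  stopifnot(inherits(de, "DETable"))
  if (is.null(de$direction)) stop("run call_significant() first")
  if (!nrow(enr)) stop("empty enrichment table")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  ## Cluster-2 side
  up2 <- de[de$direction == "up_in_2", , drop = FALSE]
  up2 <- up2[order(-abs(up2$log2fc), up2$protein_id), , drop = FALSE]
  n_top <- max(1L, floor(top_fraction * nrow(up2)))
  cand <- up2$protein_id[seq_len(min(n_top, nrow(up2)))]
  note("cluster2: %d of %d up-regulated proteins retained (top %.0f%% by |log2FC|)",
       length(cand), nrow(up2), 100 * top_fraction)
  enr <- enr[order(enr$q, enr$term_id), , drop = FALSE]
  # most-enriched family per candidate
  fam_of <- vapply(cand, function(p) {
    hit <- which(vapply(enr$members, function(m) p %in% m, logical(1)))
    if (!length(hit)) NA_character_ else enr$family[hit[1]]
  }, character(1))
  or_best <- best_abs_log_or(or_table)
  fam_order <- unique(enr$family)
  picked <- character(0)
  families <- split(cand, factor(fam_of, levels = fam_order))
  # rank within family by strongest clinical OR, ties by protein id
  families <- lapply(families, function(ps) {
    ps[order(-or_best[ps], ps)]
  })
  unannotated <- cand[is.na(fam_of)]
  if (length(unannotated))
    note("cluster2: %d candidate(s) without pathway annotation set aside: %s",
         length(unannotated), paste(unannotated, collapse = ", "))
  round <- 0L
  while (length(picked) < n_cluster2) {
    round <- round + 1L
    added <- FALSE
    for (f in fam_order) {
      pool <- setdiff(families[[f]], picked)
      if (length(pool) && length(picked) < n_cluster2) {
        picked <- c(picked, pool[1])
        note("cluster2: round %d, family '%s' -> %s (|logOR| = %.3f)",
             round, f, pool[1],
             ifelse(is.finite(or_best[pool[1]]), or_best[pool[1]], NA))
        added <- TRUE
      }
    }
    if (!added) break
  }
  if (length(picked) < n_cluster2) {
    pool <- setdiff(unannotated, picked)
    take <- utils::head(pool, n_cluster2 - length(picked))
    if (length(take)) {
      picked <- c(picked, take)
      note("cluster2: filled %d slot(s) with unannotated candidates: %s",
           length(take), paste(take, collapse = ", "))
    }
  }
  if (length(picked) < n_cluster2)
    note("warning: only %d of %d requested cluster2 members available",
         length(picked), n_cluster2)

  ## Cluster-1 side
  up1 <- de[de$direction == "up_in_1", , drop = FALSE]
  dropped <- intersect(up1$protein_id, exclude)
  if (length(dropped))
    note("cluster1: excluded %s (failed external replication)",
         paste(dropped, collapse = ", "))
  up1 <- up1[!up1$protein_id %in% exclude, , drop = FALSE]
  up1 <- up1[order(-abs(up1$log2fc), up1$protein_id), , drop = FALSE]
  keep1 <- utils::head(up1$protein_id, n_cluster1)
  note("cluster1: kept top %d of %d by |log2FC|: %s",
       length(keep1), nrow(up1), paste(keep1, collapse = ", "))
  if (length(keep1) < n_cluster1)
    note("warning: only %d of %d requested cluster1 members available",
         length(keep1), n_cluster1)

  members <- data.frame(
    protein_id = c(picked, keep1),
    side = rep(c("cluster2", "cluster1"),
               c(length(picked), length(keep1))),
    family = c(ifelse(is.na(fam_of[picked]), "unannotated", fam_of[picked]),
               rep(NA_character_, length(keep1))),
    stringsAsFactors = FALSE)
  rownames(members) <- NULL
  attr(members, "selection_log") <- log
  class(members) <- c("SignatureSpec", "data.frame")
  members
}

# strongest |log OR| per protein across outcomes; missing proteins get -Inf
best_abs_log_or <- function(or_table) {
  if (is.null(or_table) || !nrow(or_table))
    return(structure(numeric(0), names = character(0)))
  v <- abs(log(or_table$OR))
  v[!is.finite(v)] <- max(v[is.finite(v)], 0) + 1  # separation beats all
  tapply(v, or_table$protein_id, max)
}

#' Write / read a signature specification as JSON
#' @param sig a `SignatureSpec`.
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(
    list(members = as.data.frame(sig),
         selection_log = attr(sig, "selection_log")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
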