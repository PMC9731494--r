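#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the protein set contains more
#' term members than expected when drawing `|set|` proteins without
#' replacement from the universe: the upper-tail hypergeometric probability
#' \eqn{P[X \ge k]} with population `|universe|`, `|term|` successes and
#' `|set|` draws. Terms are intersected with the universe first; q-values
#' are BH-adjusted across terms.
#'
#' @param protein_set character vector, a subset of `universe`.
#' @param annotation a data.frame with columns `term_id`, `protein_id` and
#'   optionally `family` (a coarser grouping used by signature selection;
#'   defaults to the term itself).
#' @param universe character vector of all assayed proteins.
#' @param q_report report-filter threshold stored as attribute
#'   `significant_terms` (the full table is always returned).
#' @return An `EnrichmentTable` data.frame: `term_id`, `family`,
#'   `term_size`, `overlap`, `p`, `q`, `members` (list column of the
#'   overlapping ids), ordered by `q` then `term_id`.
#' @export
enrich <- function(protein_set, annotation, universe, q_report = 1e-4) {
  if (!length(universe)) stop("empty universe")
  if (!length(protein_set)) stop("empty protein set")
  protein_set <- unique(protein_set)
  out_of <- setdiff(protein_set, universe)
  if (length(out_of))
    stop("set protein(s) outside the universe: ",
         paste(out_of, collapse = ", "))
  if (is.null(annotation$family)) annotation$family <- annotation$term_id
  annotation <- annotation[annotation$protein_id %in% universe, ,
                           drop = FALSE]
  terms <- split(annotation, annotation$term_id)
  N <- length(universe)
  n <- length(protein_set)
  rows <- lapply(terms, function(tt) {
    memb <- unique(tt$protein_id)
    K <- length(memb)
    hits <- intersect(protein_set, memb)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tt$term_id[1], family = tt$family[1],
               term_size = K, overlap = k, p = p,
               members = I(list(sort(hits))), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p)
  tab <- tab[order(tab$q, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "significant_terms") <- tab$term_id[tab$q < q_report]
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Overlap of two protein sets with hypergeometric enrichment
#'
#' Counts the intersection of two protein sets, expresses it as an integer
#' percentage of `setB`, and computes the upper-tail hypergeometric
#' probability of an overlap at least that large in a universe of the
#' given size.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe all assayed proteins.
#' @return A list: `k` (overlap), `percentage` (of `setB`, rounded to
#'   integer), `p` (upper-tail hypergeometric).
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  if (!length(setB)) stop("setB must be nonempty")
  setA <- unique(setA); setB <- unique(setB)
  bad <- setdiff(c(setA, setB), universe)
  if (length(bad))
    stop("protein(s) outside the universe: ", paste(bad, collapse = ", "))
  k <- length(intersect(setA, setB))
  p <- stats::phyper(k - 1, length(setA), length(universe) - length(setA),
                     length(setB), lower.tail = FALSE)
  list(k = k, percentage = round(100 * k / length(setB)), p = p)
}

#' Build a synthetic pathway annotation for a protein universe
#'
#' Partitions consecutive blocks of the universe into pathway terms of
#' sizes drawn from `size_range` and groups terms into `n_families`
#' families. A stand-in for a real GO mapping of aptamer targets, used so
#' that enrichment and signature selection are exercisable on generated
#' cohorts.
#'
#' @param universe character vector of protein ids.
#' @param n_terms number of terms.
#' @param size_range term size interval.
#' @param n_families number of families the terms cycle through.
#' @param seed RNG seed.
#' @return Annotation data.frame (`term_id`, `protein_id`, `family`).
#' @export
synthetic_annotation <- function(universe, n_terms = 40L,
                                 size_range = c(5L, 40L),
                                 n_families = 3L, seed = 1L) {
  set.seed(seed)
  fams <- sprintf("family%02d", seq_len(n_families))
  rows <- lapply(seq_len(n_terms), function(i) {
    size <- sample(size_range[1]:size_range[2], 1L)
    data.frame(term_id = sprintf("T%03d", i),
               protein_id = sample(universe, min(size, length(universe))),
               family = fams[(i - 1L) %% n_families + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
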