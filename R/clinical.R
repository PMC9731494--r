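#' Cluster-versus-clinical comparison table
#'
#' Compares each clinical variable between the two clusters the way
#' clinical baseline tables do: continuous variables with a two-sided
#' equal-variance Student t-test (summarized mean +/- sd), binary or
#' categorical variables with a two-tailed Fisher exact test (summarized
#' n (%)). Missing values are dropped per variable and the per-group n
#' reported.
#'
#' @param covariates data.frame with `subject_id` and clinical columns;
#'   numeric columns with more than two distinct values are treated as
#'   continuous, everything else as categorical.
#' @param labels named cluster labels (1/2) per subject id.
#' @return A `ClinicalComparison` data.frame: `variable`, `type`, `n1`,
#'   `n2`, `summary1`, `summary2`, `statistic`, `p`.
#' @export
compare_clinical <- function(covariates, labels) {
  lab <- labels[covariates$subject_id]
  if (anyNA(lab)) stop("labels must cover every subject in the table")
  lab <- as.integer(lab)
  vars <- setdiff(names(covariates), "subject_id")
  rows <- lapply(vars, function(v) {
    x <- covariates[[v]]
    ok <- !is.na(x)
    if (!any(ok & lab == 1L) || !any(ok & lab == 2L))
      stop("variable '", v, "' entirely missing in one cluster")
    xo <- x[ok]; lo <- lab[ok]
    continuous <- is.numeric(xo) && length(unique(xo)) > 2L
    if (continuous) {
      tt <- stats::t.test(xo[lo == 1L], xo[lo == 2L], var.equal = TRUE)
      summ <- function(z) sprintf("%.2f ± %.2f", mean(z), stats::sd(z))
      data.frame(variable = v, type = "continuous",
                 n1 = sum(lo == 1L), n2 = sum(lo == 2L),
                 summary1 = summ(xo[lo == 1L]), summary2 = summ(xo[lo == 2L]),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(xo), factor(lo, levels = 1:2))
      ft <- stats::fisher.test(tab)
      pos <- if (nrow(tab) == 2L) rownames(tab)[nrow(tab)] else NA
      summ <- function(g) {
        n <- sum(lo == g)
        if (!is.na(pos)) {
          k <- sum(xo[lo == g] == pos)
          sprintf("%d (%.0f%%)", k, 100 * k / n)
        } else sprintf("%d levels", nrow(tab))
      }
      data.frame(variable = v, type = "categorical",
                 n1 = sum(lo == 1L), n2 = sum(lo == 2L),
                 summary1 = summ(1L), summary2 = summ(2L),
                 statistic = NA_real_, p = ft$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ClinicalComparison", "data.frame")
  out
}

#' Two-tailed Fisher exact test with the sample odds ratio
#'
#' Exact conditional test on a 2x2 count table using the probability-mass
#' two-sided rule (sum of the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table).
#' Unlike the conditional-ML estimate, the reported odds ratio is the plain
#' sample cross-product ratio ad/bc; a zero off-diagonal cell makes it
#' infinite, which is flagged.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A list: `OR` (ad/bc, possibly `Inf`), `p` (two-sided),
#'   `or_infinite` flag.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != round(table)))
    stop("fisher_exact expects a 2x2 table of nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  list(OR = or, p = p, or_infinite = is.infinite(or) || is.nan(or))
}

#' Per-protein clinical-outcome odds ratios
#'
#' Fits, for each protein, a univariable logistic regression of a binary
#' clinical outcome on the protein's standardized log2 expression (zero
#' mean, unit sd), so odds ratios are per standard deviation of
#' expression. Wald 95% confidence bounds accompany each OR and q-values
#' are BH-adjusted across proteins within the outcome. Complete separation
#' (diverging coefficient) is detected and flagged, the OR then being a
#' finite bound rather than an estimate.
#'
#' @param X a log2 `ExpressionMatrix`.
#' @param outcome named binary (0/1) vector per subject id; both classes
#'   must occur.
#' @param proteins protein ids to fit (all assay columns by default).
#' @param outcome_name label stored in the table.
#' @param unit `"sd"` (default) standardizes expression so ORs are per
#'   standard deviation; `"log2"` leaves expression unscaled (OR per log2
#'   unit).
#' @return An `AssociationTable` data.frame: `protein_id`, `outcome`, `OR`,
#'   `ci_low`, `ci_high`, `p`, `q`, `separation`.
#' @export
protein_outcome_or <- function(X, outcome, proteins = NULL,
                               outcome_name = "outcome",
                               unit = c("sd", "log2")) {
  unit <- match.arg(unit)
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$scale != "log2") stop("logistic fits expect log2 values")
  y <- outcome[subject_ids(X)]
  if (anyNA(y)) stop("outcome must cover every subject id")
  y <- as.integer(y)
  if (length(unique(y)) != 2L || !all(y %in% 0:1))
    stop("degenerate outcome: need both classes coded 0/1")
  if (is.null(proteins)) proteins <- protein_ids(X)
  rows <- lapply(proteins, function(pid) {
    z <- X$values[, pid]
    if (stats::sd(z) == 0)
      return(data.frame(protein_id = pid, outcome = outcome_name,
                        OR = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        separation = FALSE, stringsAsFactors = FALSE))
    if (unit == "sd") z <- (z - mean(z)) / stats::sd(z)
    fit <- suppressWarnings(
      stats::glm(y ~ z, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8,
                                              maxit = 100L)))
    beta <- stats::coef(fit)[["z"]]
    se <- sqrt(stats::vcov(fit)["z", "z"])
    separation <- !fit$converged || abs(beta) > 15
    data.frame(protein_id = pid, outcome = outcome_name,
               OR = exp(beta), ci_low = exp(beta - 1.96 * se),
               ci_high = exp(beta + 1.96 * se),
               p = 2 * stats::pnorm(-abs(beta / se)),
               separation = separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  class(out) <- c("AssociationTable", "data.frame")
  out
}

#' Correlation between a protein (or score) and a clinical quantity
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `rho`, `p` (two-sided, t approximation).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
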