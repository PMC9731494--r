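#' Empirical-Bayes moderated two-group t-test
#'
#' Per-protein two-group comparison on log2 values with variance
#' moderation. For each protein the pooled within-group residual variance
#' \eqn{s_g^2} (with \eqn{d_g = n_1 + n_2 - 2} degrees of freedom) is
#' shrunk towards a prior variance \eqn{s_0^2} with prior degrees of
#' freedom \eqn{d_0}, both estimated from all proteins by matching the
#' first two moments of \eqn{\log s_g^2} to its scaled-F sampling
#' distribution (the trigamma equation for \eqn{d_0} is solved by Newton
#' iteration). The posterior variance is
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and the moderated statistic
#' \eqn{t_g = \Delta_g / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})} is referred to
#' a t distribution on \eqn{d_0 + d_g} degrees of freedom, where
#' \eqn{\Delta_g} is mean(group 2) - mean(group 1). With `prior_df = 0` the
#' result is the ordinary equal-variance t-test.
#'
#' @param X a log2 `ExpressionMatrix`.
#' @param labels named vector of group labels (values 1 and 2) covering the
#'   subjects; each group needs at least 2 members.
#' @param proteins optional subset of protein ids to test (all by default).
#' @param prior_df `NULL` to estimate the prior degrees of freedom from the
#'   data (the default); a number (possibly `Inf`) to force it.
#' @return A `DETable` data.frame: `protein_id`, `log2fc`, `fold_change`
#'   (`2^|log2fc|`), `t_mod`, `p`, and the estimated prior as attributes
#'   `d0` and `s0_sq`. Proteins constant in both groups under `prior_df = 0`
#'   get `p = 1` and are flagged in `degenerate`.
#' @export
moderated_ttest <- function(X, labels, proteins = NULL, prior_df = NULL) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$scale != "log2") stop("differential expression expects log2 values")
  labels <- labels[subject_ids(X)]
  if (anyNA(labels)) stop("labels must cover every subject id")
  g1 <- labels == 1L | labels == "1"
  g2 <- labels == 2L | labels == "2"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  if (is.null(proteins)) proteins <- protein_ids(X)
  v <- X$values[, proteins, drop = FALSE]
  m1 <- colMeans(v[g1, , drop = FALSE])
  m2 <- colMeans(v[g2, , drop = FALSE])
  log2fc <- m2 - m1
  ss1 <- colSums(sweep(v[g1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(v[g2, , drop = FALSE], 2, m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = NA_real_)
  } else {
    s0 <- fit_variance_prior(s2, d)$s0_sq
    prior <- list(d0 = prior_df, s0_sq = s0)
  }
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * prior$s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  t_mod <- ifelse(degenerate, 0, log2fc / se)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[degenerate] <- 1
  out <- data.frame(protein_id = proteins, log2fc = unname(log2fc),
                    fold_change = 2^abs(unname(log2fc)),
                    t_mod = unname(t_mod), p = unname(p),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "group_sizes") <- c(n1 = n1, n2 = n2)
  class(out) <- c("DETable", "data.frame")
  out
}

# Method-of-moments fit of the scaled-F prior on residual variances:
# z = log(s^2) has mean log(s0^2) + digamma(d/2) - log(d/2) +
# [log(d0/2) - digamma(d0/2)] and variance trigamma(d/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_sq = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(z) - trigamma(d / 2)
  if (ev <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing
# trigamma function (cf. the standard empirical-Bayes derivation).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m \, p_{(j)} / j)}, returned in
#' the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the fold-change / FDR significance rule
#'
#' A protein is significant when its fold change strictly exceeds
#' `fc_threshold` and its BH q-value is strictly below `q_threshold`; the
#' direction of the log2 fold change splits significant proteins into the
#' Cluster-2 and Cluster-1 up-sets.
#'
#' @param de a `DETable` from [moderated_ttest()].
#' @param fc_threshold fold-change cutoff (default 1.5).
#' @param q_threshold FDR cutoff (default 0.05).
#' @return The `DETable` augmented with `q`, `direction`
#'   (`up_in_2`/`up_in_1`/`none`) and `significant`; the up-sets are
#'   available as attributes `up_in_2` and `up_in_1`.
#' @export
call_significant <- function(de, fc_threshold = 1.5, q_threshold = 0.05) {
  stopifnot(inherits(de, "DETable"))
  de$q <- bh_fdr(de$p)
  de$significant <- de$fold_change > fc_threshold & de$q < q_threshold
  de$direction <- ifelse(!de$significant, "none",
                         ifelse(de$log2fc > 0, "up_in_2", "up_in_1"))
  attr(de, "up_in_2") <- de$protein_id[de$direction == "up_in_2"]
  attr(de, "up_in_1") <- de$protein_id[de$direction == "up_in_1"]
  de
}

#' Up-regulated protein sets of a significance-called DE table
#' @param de a `DETable` processed by [call_significant()].
#' @param side `"up_in_2"` or `"up_in_1"`.
#' @return Character vector of protein ids.
#' @export
up_set <- function(de, side = c("up_in_2", "up_in_1")) {
  side <- match.arg(side)
  if (is.null(de$direction)) stop("run call_significant() first")
  de$protein_id[de$direction == side]
}
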