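# Shared fixtures and independent oracles for the test suite.

# A reduced two-cluster cohort that keeps the statistical regime of the
# full scenarios (same effect range and noise) at a fraction of the size.
medium_config <- function(seed = 1L, ...) {
  generator_config(n_subjects = 120L, n_proteins = 600L,
                   cluster_sizes = c(64L, 56L),
                   up_in_c2 = 40L, up_in_c1 = 3L, seed = seed, ...)
}

# A tiny noise-free deterministic cohort for construction-level checks.
clean_config <- function(...) {
  generator_config(n_subjects = 10L, n_proteins = 20L,
                   cluster_sizes = c(5L, 5L),
                   up_in_c2 = 1L, up_in_c1 = 0L,
                   effect_log2fc_range = c(1, 1), noise_sd = 0,
                   n_plates = 1L, plate_shift_sd = 0, hyb_drift_sd = 0,
                   control_noise_sd = 0, seed = 99L, ...)
}

# Small log2 matrix straight from values (no technical effects).
log2_matrix <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%03d", seq_len(ncol(values)))
  expression_matrix(values, scale = "log2")
}

# Exhaustive upper-tail hypergeometric oracle: enumerate every n-subset of
# an N-element universe and count overlaps >= k with a fixed K-set.
hyper_enum_p <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)  # first K elements form the term
  mean(hits >= k)
}

# Two-sided Fisher oracle by enumeration over fixed-margin tables using
# the probability-mass rule.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, N - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Ordinary pooled-variance two-sample t oracle.
pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Classic Benjamini-Hochberg rejection set (step-up on sorted p-values).
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# A small fully-specified fixture for the signature selection procedure:
# 40 up-in-2 proteins spanning four annotated families, 6 up-in-1 proteins,
# and a monotone ladder of clinical odds ratios.
signature_fixture <- function() {
  up2 <- sprintf("U%02d", 1:40)
  up1 <- sprintf("D%02d", 1:6)
  de <- structure(
    data.frame(protein_id = c(up2, up1),
               log2fc = c(seq(2, 1.0, length.out = 40),
                          -seq(1.6, 1.1, length.out = 6)),
               fold_change = 2^c(seq(2, 1.0, length.out = 40),
                                 seq(1.6, 1.1, length.out = 6)),
               t_mod = 6, p = 1e-6, degenerate = FALSE,
               q = 1e-4,
               significant = TRUE,
               direction = rep(c("up_in_2", "up_in_1"), c(40, 6))),
    class = c("DETable", "data.frame"))
  universe <- c(de$protein_id, sprintf("N%03d", 1:200))
  anno <- data.frame(
    term_id = rep(c("T1", "T2", "T3", "T4"), each = 10),
    protein_id = c(up2[1:10], up2[11:20], up2[21:30], up2[31:40]),
    family = rep(c("immunity", "repair", "metabolism", "injury"),
                 each = 10))
  enr <- enrich(up2, anno, universe)
  or_table <- structure(
    data.frame(protein_id = c(up2, up1),
               outcome = "emphysema",
               OR = exp(seq(-1, 1, length.out = 46)),
               ci_low = 0.1, ci_high = 10, p = 0.01, q = 0.02,
               separation = FALSE),
    class = c("AssociationTable", "data.frame"))
  list(de = de, enr = enr, or_table = or_table)
}
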