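#' Four-step intensity standardization
#'
#' Applies the aptamer-assay standardization sequence to a raw RFU matrix.
#' Each step is a median-ratio scaling run to its fixed point, and the
#' steps are arranged so that their fixed points are jointly consistent —
#' the composite map is a projection (applying it twice returns the first
#' result to within `tol`):
#'
#' 1. **Hybridization normalization** — every sample is divided by the
#'    median, over its hybridization-control probes, of the ratio of that
#'    probe's intensity to the probe's run-wide median; iterated until the
#'    ratios are 1. The hybridization columns are left untouched by the
#'    later steps, so this per-sample drift correction stays fixed.
#' 2. **Plate scaling** — every plate is multiplied by (grand median of
#'    the plate medians) / (its own plate median), medians taken over
#'    assay (non-control) values.
#' 3. **Median signal normalization** — every sample is scaled so that its
#'    median over assay proteins equals the run-wide median of those
#'    sample medians; computed and applied within dilution group when the
#'    panel defines several. Steps 2 and 3 are alternated until both
#'    median constraints hold simultaneously (they are jointly feasible;
#'    the alternation settles in a few passes).
#' 4. **Calibration** — each calibrator probe is multiplied, per plate, by
#'    (reference value for that probe) / (its plate median), aligning the
#'    calibrator probes across plates to the reference. The reference is
#'    the per-probe run-wide median, or the corresponding medians of
#'    `reference` when an external reference run is supplied. A
#'    calibrator-derived plate correction is a plate scalar, which plate
#'    scaling has already fixed for the assay columns, so calibration acts
#'    on the calibrator columns: it reconciles the plate-alignment
#'    standards with the (internal or external) reference without
#'    disturbing the assay fixed points.
#'
#' @param raw an `ExpressionMatrix` on the raw scale, not yet normalized.
#' @param meta the matching [panel_meta()]; at least one hybridization
#'   control and one calibrator probe must be flagged.
#' @param reference optional `ExpressionMatrix` of a reference run
#'   supplying the calibration targets.
#' @param tol convergence tolerance on the log scale factors.
#' @param max_iter iteration cap per fixed-point loop.
#' @param force re-normalize even if the input is tagged normalized
#'   (normally an error).
#'
#' @return A normalized raw-scale `ExpressionMatrix`; attribute
#'   `sample_factors` holds the per-sample median ratio raw/normalized
#'   over assay proteins, i.e. the recovered technical scale factor of
#'   each sample.
#' @export
standardize <- function(raw, meta, reference = NULL, tol = 1e-10,
                        max_iter = 100L, force = FALSE) {
  stopifnot(inherits(raw, "ExpressionMatrix"))
  if (raw$scale != "raw") stop("standardize expects a raw-scale matrix")
  if (raw$normalized && !force)
    stop("input is already normalized; pass force = TRUE to re-normalize")
  if (!setequal(meta$protein_id, protein_ids(raw)))
    stop("panel metadata does not match the matrix columns")
  hyb <- meta$protein_id[meta$is_hyb_control]
  cal <- meta$protein_id[meta$is_calibrator]
  if (length(hyb) < 1L) stop("normalization requires >= 1 hybridization control")
  if (length(cal) < 1L) stop("normalization requires >= 1 calibrator probe")
  assay <- assay_proteins(meta)
  groups <- split(assay, meta$dilution_group[match(assay, meta$protein_id)])
  x <- raw$values
  plate <- raw$plate
  plates <- split(seq_len(nrow(x)), plate)

  # step 1: hybridization normalization (per-sample, from hyb probes)
  for (it in seq_len(max_iter)) {
    hx <- x[, hyb, drop = FALSE]
    probe_med <- apply(hx, 2, stats::median)
    if (any(probe_med == 0)) stop("zero hybridization-control median")
    r <- apply(sweep(hx, 2, probe_med, "/"), 1, stats::median)
    if (any(r == 0)) stop("zero hybridization-control median")
    x <- x / r
    if (max(abs(log(r))) < tol) break
  }

  # steps 2 + 3: plate scaling and median signal normalization, alternated
  # to their joint fixed point (plate factors also applied to calibrators)
  nothyb <- setdiff(colnames(x), hyb)
  for (it in seq_len(max_iter)) {
    pm <- vapply(plates, function(i) stats::median(x[i, assay]), numeric(1))
    if (any(pm == 0)) stop("zero plate median")
    cq <- stats::median(pm) / pm
    x[, nothyb] <- x[, nothyb, drop = FALSE] * cq[plate]
    delta <- max(abs(log(cq)))
    for (g in groups) {
      sm <- apply(x[, g, drop = FALSE], 1, stats::median)
      if (any(sm == 0)) stop("zero sample median")
      gs <- stats::median(sm) / sm
      x[, g] <- x[, g, drop = FALSE] * gs
      delta <- max(delta, abs(log(gs)))
    }
    if (delta < tol) break
  }

  # step 4: calibration of the calibrator probes across plates
  ref_cal <- if (!is.null(reference)) {
    miss <- setdiff(cal, protein_ids(reference))
    if (length(miss))
      stop("reference run lacks calibrator(s): ", paste(miss, collapse = ", "))
    apply(reference$values[, cal, drop = FALSE], 2, stats::median)
  } else NULL
  for (it in seq_len(max_iter)) {
    ref <- if (!is.null(ref_cal)) ref_cal
           else apply(x[, cal, drop = FALSE], 2, stats::median)
    if (any(ref == 0)) stop("zero calibrator median")
    delta <- 0
    for (q in names(plates)) {
      i <- plates[[q]]
      med_q <- apply(x[i, cal, drop = FALSE], 2, stats::median)
      if (any(med_q == 0)) stop("zero calibrator median")
      f <- ref / med_q
      x[i, cal] <- sweep(x[i, cal, drop = FALSE], 2, f, "*")
      delta <- max(delta, abs(log(f)))
    }
    if (delta < tol) break
  }

  out <- expression_matrix(x, scale = "raw", plate = plate,
                           run_id = raw$run_id, normalized = TRUE)
  attr(out, "sample_factors") <-
    apply(raw$values[, assay, drop = FALSE] / x[, assay, drop = FALSE], 1,
          stats::median)
  out
}

#' Log2-transform a raw expression matrix
#'
#' @param X an `ExpressionMatrix` on the raw scale with strictly positive
#'   values.
#' @return The same matrix with `log2` values and scale tag.
#' @export
log2_transform <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$scale != "raw") stop("log2_transform expects a raw-scale matrix")
  if (any(X$values <= 0)) stop("nonpositive values cannot be log2-transformed")
  out <- X
  out$values <- log2(X$values)
  out$scale <- "log2"
  out
}
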