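#' Configuration for the synthetic cohort generator
#'
#' Defines the planted structure of a simulated aptamer cohort: two patient
#' clusters with protein sets shifted up on the log2 scale in one cluster or
#' the other, technical plate and per-sample hybridization effects on the
#' raw RFU scale, cluster-correlated binary clinical covariates, and (for
#' paired designs) a visit-to-visit transition structure.
#'
#' Planted effects are additive on the log2 scale (multiplicative on RFU)
#' and drawn once per protein, uniformly from `effect_log2fc_range`; they
#' are constant across subjects so that the group-mean log2 fold change of a
#' planted protein equals its planted effect in expectation.
#'
#' @param n_subjects,n_proteins cohort and panel dimensions (the panel
#'   counts assay proteins only; control probes are added on top).
#' @param cluster_sizes integer pair: planted sizes of Cluster 1 and 2.
#' @param up_in_c2,up_in_c1 number of proteins planted higher in Cluster 2
#'   (respectively Cluster 1).
#' @param effect_log2fc_range interval the per-protein log2 effects are
#'   drawn from.
#' @param baseline_log2_mean,baseline_log2_sd location and between-protein
#'   spread of baseline log2 intensity.
#' @param noise_sd within-group residual sd on the log2 scale.
#' @param n_plates number of plates; subjects are assigned at random.
#' @param plate_shift_sd sd of the per-plate log2 technical shift (the plate
#'   factor applied to raw RFU is `2^shift`).
#' @param hyb_drift_sd sd of the per-sample log2 hybridization drift.
#' @param covariate_prevalences named list; each element a numeric pair
#'   `c(cluster1 = p1, cluster2 = p2)` of within-cluster prevalences of a
#'   binary clinical covariate.
#' @param transition_counts named integer vector
#'   `c(stay1, stay2, to_mixed, to1)` for paired-visit designs: subjects
#'   staying in Cluster 1, staying in Cluster 2, moving from Cluster 1 to a
#'   mixed profile, and switching from Cluster 2 to Cluster 1.
#' @param shared_up_fraction fraction of a reference cohort's Cluster-2
#'   up-set that is re-planted when simulating a second cohort.
#' @param up_c2_ids,up_c1_ids optional explicit panel indices for the
#'   planted sets; defaults place the Cluster-2 set first, then the
#'   Cluster-1 set.
#' @param n_hyb_controls,n_cal_controls number of hybridization-control and
#'   calibrator probes appended to the panel (technical signal only).
#' @param control_noise_sd residual sd of the control probes (log2 scale);
#'   control probes are spiked at fixed concentration and so vary much less
#'   than serum analytes.
#' @param seed RNG seed making the generated cohort reproducible.
#'
#' @return A list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_subjects = 241L,
                             n_proteins = 1305L,
                             cluster_sizes = c(126L, 115L),
                             up_in_c2 = 90L,
                             up_in_c1 = 6L,
                             effect_log2fc_range = c(0.8, 1.5),
                             baseline_log2_mean = 10.6,
                             baseline_log2_sd = 1.5,
                             noise_sd = 0.5,
                             n_plates = 3L,
                             plate_shift_sd = 0.2,
                             hyb_drift_sd = 0.15,
                             covariate_prevalences = list(),
                             transition_counts = NULL,
                             shared_up_fraction = NA_real_,
                             up_c2_ids = NULL,
                             up_c1_ids = NULL,
                             n_hyb_controls = 3L,
                             n_cal_controls = 3L,
                             control_noise_sd = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_proteins = as.integer(n_proteins),
    cluster_sizes = as.integer(cluster_sizes),
    up_in_c2 = as.integer(up_in_c2), up_in_c1 = as.integer(up_in_c1),
    effect_log2fc_range = as.numeric(effect_log2fc_range),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_sd = noise_sd, n_plates = as.integer(n_plates),
    plate_shift_sd = plate_shift_sd, hyb_drift_sd = hyb_drift_sd,
    covariate_prevalences = covariate_prevalences,
    transition_counts = transition_counts,
    shared_up_fraction = shared_up_fraction,
    up_c2_ids = up_c2_ids, up_c1_ids = up_c1_ids,
    n_hyb_controls = as.integer(n_hyb_controls),
    n_cal_controls = as.integer(n_cal_controls),
    control_noise_sd = control_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "GeneratorConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1L || n_proteins < 1L)
      stop("configuration error: nonpositive cohort dimensions")
    if (length(cluster_sizes) != 2L || any(cluster_sizes < 0L))
      stop("configuration error: cluster_sizes must be two nonnegative counts")
    if (sum(cluster_sizes) != n_subjects)
      stop("configuration error: cluster_sizes must sum to n_subjects")
    if (up_in_c2 < 0L || up_in_c1 < 0L || up_in_c2 + up_in_c1 > n_proteins)
      stop("configuration error: planted up-sets exceed the panel")
    if (length(effect_log2fc_range) != 2L ||
        effect_log2fc_range[1] > effect_log2fc_range[2])
      stop("configuration error: malformed effect_log2fc_range")
    if (noise_sd < 0 || plate_shift_sd < 0 || hyb_drift_sd < 0)
      stop("configuration error: negative spread parameter")
    if (n_plates < 1L)
      stop("configuration error: need at least one plate")
    for (pv in covariate_prevalences)
      if (any(pv < 0) || any(pv > 1))
        stop("configuration error: covariate prevalence outside [0, 1]")
    if (!is.null(transition_counts)) {
      if (length(transition_counts) != 4L || any(transition_counts < 0))
        stop("configuration error: transition_counts must be 4 nonnegative counts")
      if (sum(transition_counts) != n_subjects)
        stop("configuration error: transition_counts must sum to the paired cohort size")
    }
  })
  invisible(cfg)
}

#' Named default scenarios
#'
#' Pre-registered generator configurations mirroring the cohort structures
#' the pipeline is designed around:
#' \describe{
#'   \item{`cobra_v1`}{learning cohort, 241 subjects, 1305 proteins, planted
#'     clusters of 126/115 with 90 proteins up in Cluster 2 and 6 up in
#'     Cluster 1, effects in \[0.8, 1.5\] log2 units, Table-2-style
#'     cluster-conditional covariates.}
#'   \item{`mlcc`}{independent validation cohort, 47 subjects (34/13), 114
#'     proteins up in Cluster 2 of which 71 are re-planted from the
#'     `cobra_v1` up-set (shared fraction 71/90), 6 non-overlapping proteins
#'     up in Cluster 1.}
#'   \item{`paired_visits`}{163 subjects seen twice; transitions
#'     stay-1 = 68, stay-2 = 40, Cluster 1 to mixed = 29, Cluster 2 to
#'     Cluster 1 = 26 (so 97/66 at visit 1).}
#'   \item{`healthy`}{50 control subjects with no planted structure.}
#' }
#'
#' @param name scenario name.
#' @param seed optional seed override (the per-scenario default otherwise).
#' @return A `GeneratorConfig`.
#' @export
scenario_config <- function(name = c("cobra_v1", "mlcc", "paired_visits",
                                     "healthy"),
                            seed = NULL) {
  name <- match.arg(name)
  covs <- list(
    emphysema          = c(cluster1 = 0.52, cluster2 = 0.31),
    exacerbations      = c(cluster1 = 0.61, cluster2 = 0.44),
    unscheduled_visits = c(cluster1 = 0.53, cluster2 = 0.33),
    hypertension       = c(cluster1 = 0.39, cluster2 = 0.24),
    diabetes           = c(cluster1 = 0.17, cluster2 = 0.06)
  )
  cfg <- switch(
    name,
    cobra_v1 = generator_config(
      n_subjects = 241L, cluster_sizes = c(126L, 115L),
      up_in_c2 = 90L, up_in_c1 = 6L,
      covariate_prevalences = covs, seed = 20221L),
    mlcc = generator_config(
      n_subjects = 47L, cluster_sizes = c(34L, 13L),
      up_in_c2 = 114L, up_in_c1 = 6L,
      shared_up_fraction = 71 / 90,
      # 71 proteins shared with the cobra_v1 Cluster-2 up-set (panel
      # indices 1..90), 43 new; Cluster-1 side disjoint from cobra's 91..96.
      up_c2_ids = c(1:71, 97:139), up_c1_ids = 140:145,
      covariate_prevalences = covs["emphysema"], seed = 20222L),
    paired_visits = generator_config(
      n_subjects = 163L, cluster_sizes = c(97L, 66L),
      up_in_c2 = 90L, up_in_c1 = 6L,
      transition_counts = c(stay1 = 68L, stay2 = 40L,
                            to_mixed = 29L, to1 = 26L),
      covariate_prevalences = covs, seed = 20223L),
    healthy = generator_config(
      n_subjects = 50L, cluster_sizes = c(50L, 0L),
      up_in_c2 = 0L, up_in_c1 = 0L, seed = 20224L)
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

make_panel <- function(cfg) {
  ids <- c(sprintf("P%04d", seq_len(cfg$n_proteins)),
           if (cfg$n_hyb_controls) sprintf("HYB%d", seq_len(cfg$n_hyb_controls)),
           if (cfg$n_cal_controls) sprintf("CAL%d", seq_len(cfg$n_cal_controls)))
  panel_meta(ids,
             is_hyb_control = grepl("^HYB", ids),
             is_calibrator = grepl("^CAL", ids))
}

planted_sets <- function(cfg) {
  ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  i2 <- if (!is.null(cfg$up_c2_ids)) cfg$up_c2_ids else seq_len(cfg$up_in_c2)
  i1 <- if (!is.null(cfg$up_c1_ids)) cfg$up_c1_ids
        else cfg$up_in_c2 + seq_len(cfg$up_in_c1)
  if (length(i2) != cfg$up_in_c2 || length(i1) != cfg$up_in_c1 ||
      anyDuplicated(c(i2, i1)) || any(c(i2, i1) > cfg$n_proteins))
    stop("configuration error: planted protein indices infeasible")
  list(up_c2 = ids[i2], up_c1 = ids[i1])
}

# Core builder: log2 signal = baseline + effect * membership + noise for
# assay proteins; control probes carry baseline + small noise only. Raw
# RFU = 2^log2 * plate factor * per-sample hybridization factor.
build_raw_matrix <- function(cfg, mult_c1, mult_c2, baseline, eff_c1, eff_c2,
                             subject_ids, plate, run_id) {
  meta <- make_panel(cfg)
  ids <- meta$protein_id
  n <- length(subject_ids)
  p <- length(ids)
  is_ctrl <- meta$is_hyb_control | meta$is_calibrator
  log2x <- matrix(rep(baseline, each = n), nrow = n,
                  dimnames = list(subject_ids, ids))
  if (length(eff_c2))
    log2x[, names(eff_c2)] <- log2x[, names(eff_c2)] +
      outer(mult_c2, eff_c2)
  if (length(eff_c1))
    log2x[, names(eff_c1)] <- log2x[, names(eff_c1)] +
      outer(mult_c1, eff_c1)
  noise <- matrix(stats::rnorm(n * p), n, p)
  noise[, !is_ctrl] <- noise[, !is_ctrl] * cfg$noise_sd
  noise[, is_ctrl] <- noise[, is_ctrl] * cfg$control_noise_sd
  log2x <- log2x + noise
  plate_factor <- 2^stats::rnorm(cfg$n_plates, 0, cfg$plate_shift_sd)
  names(plate_factor) <- sprintf("plate%d", seq_len(cfg$n_plates))
  hyb_factor <- 2^stats::rnorm(n, 0, cfg$hyb_drift_sd)
  names(hyb_factor) <- subject_ids
  raw <- 2^log2x * plate_factor[plate] * hyb_factor
  list(matrix = expression_matrix(raw, scale = "raw", plate = plate,
                                  run_id = run_id),
       meta = meta, plate_factor = plate_factor, hyb_factor = hyb_factor)
}

#' Generate a single-visit cohort with planted cluster structure
#'
#' Draws a raw-RFU expression matrix whose log2 signal decomposes as
#' baseline + planted effect x cluster membership + Gaussian noise, with
#' multiplicative plate and per-sample hybridization effects layered on the
#' raw scale, plus hybridization-control and calibrator probes carrying the
#' technical effects but no biology. Everything planted is recorded in the
#' returned truth bundle.
#'
#' @param config a [generator_config()].
#' @return A list: `matrix` (raw `ExpressionMatrix`), `meta` (`PanelMeta`),
#'   `annotation` (subject table with cluster-conditional covariates),
#'   `truth` (planted labels, up-set ids, per-protein effects, plate and
#'   hybridization factors).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  subj <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(
    sample(rep.int(1:2, config$cluster_sizes)), subj)
  sets <- planted_sets(config)
  baseline <- stats::rnorm(config$n_proteins +
                             config$n_hyb_controls + config$n_cal_controls,
                           config$baseline_log2_mean, config$baseline_log2_sd)
  eff_c2 <- stats::setNames(
    stats::runif(config$up_in_c2, config$effect_log2fc_range[1],
                 config$effect_log2fc_range[2]), sets$up_c2)
  eff_c1 <- stats::setNames(
    stats::runif(config$up_in_c1, config$effect_log2fc_range[1],
                 config$effect_log2fc_range[2]), sets$up_c1)
  plate <- stats::setNames(
    sprintf("plate%d", sample(rep_len(seq_len(config$n_plates), n))), subj)
  built <- build_raw_matrix(config, as.numeric(labels == 1),
                            as.numeric(labels == 2), baseline,
                            eff_c1, eff_c2, subj, plate, "run1")
  ann <- data.frame(subject_id = subj, visit = 1L,
                    plate = unname(plate), stringsAsFactors = FALSE)
  if (length(config$covariate_prevalences)) {
    cov <- generate_covariates(labels, config$covariate_prevalences,
                               seed = NULL)
    ann <- cbind(ann, cov[match(ann$subject_id, cov$subject_id), -1,
                          drop = FALSE])
  }
  truth <- list(labels = labels, up_c2 = sets$up_c2, up_c1 = sets$up_c1,
                effects_c2 = eff_c2, effects_c1 = eff_c1,
                plate = plate, plate_factor = built$plate_factor,
                hyb_factor = built$hyb_factor,
                covariate_prevalences = config$covariate_prevalences)
  list(matrix = built$matrix, meta = built$meta, annotation = ann,
       truth = truth)
}

#' Generate a paired-visit cohort with a planted transition structure
#'
#' Visit-1 profiles follow the transition origin (Cluster 1 for stayers and
#' mixed-to-be subjects, Cluster 2 for stayers and switchers); visit-2
#' profiles follow the destination, where a "mixed" destination keeps the
#' Cluster-1 profile and additionally receives 50% of every Cluster-2
#' planted effect. Visit-2 intensities are re-drawn with fresh noise, plate
#' factors and hybridization drift; subject ids are shared across visits.
#'
#' @param config a [generator_config()] with `transition_counts` set, named
#'   `c(stay1, stay2, to_mixed, to1)`.
#' @return A list: `visit1`, `visit2` (raw `ExpressionMatrix`), `meta`,
#'   `annotation`, `truth` (including per-visit labels with the mixed
#'   destination marked, and the planted transition table).
#' @export
generate_paired_visits <- function(config) {
  validate_config(config)
  tc <- config$transition_counts
  if (is.null(tc))
    stop("configuration error: transition_counts required for a paired design")
  if (is.null(names(tc))) names(tc) <- c("stay1", "stay2", "to_mixed", "to1")
  if (tc[["stay1"]] + tc[["to_mixed"]] != config$cluster_sizes[1] ||
      tc[["stay2"]] + tc[["to1"]] != config$cluster_sizes[2])
    stop("configuration error: transition_counts inconsistent with cluster_sizes")
  set.seed(config$seed)
  n <- config$n_subjects
  subj <- sprintf("S%03d", seq_len(n))
  dest <- sample(rep.int(c("stay1", "stay2", "to_mixed", "to1"),
                         tc[c("stay1", "stay2", "to_mixed", "to1")]))
  names(dest) <- subj
  lab_v1 <- stats::setNames(ifelse(dest %in% c("stay1", "to_mixed"), 1L, 2L),
                            subj)
  lab_v2 <- stats::setNames(
    c(stay1 = "1", stay2 = "2", to_mixed = "mixed", to1 = "1")[dest], subj)
  sets <- planted_sets(config)
  nprot <- config$n_proteins + config$n_hyb_controls + config$n_cal_controls
  baseline <- stats::rnorm(nprot, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  eff_c2 <- stats::setNames(
    stats::runif(config$up_in_c2, config$effect_log2fc_range[1],
                 config$effect_log2fc_range[2]), sets$up_c2)
  eff_c1 <- stats::setNames(
    stats::runif(config$up_in_c1, config$effect_log2fc_range[1],
                 config$effect_log2fc_range[2]), sets$up_c1)
  plate <- stats::setNames(
    sprintf("plate%d", sample(rep_len(seq_len(config$n_plates), n))), subj)
  m1_c1 <- as.numeric(lab_v1 == 1L)
  m1_c2 <- as.numeric(lab_v1 == 2L)
  m2_c1 <- as.numeric(lab_v2 %in% c("1", "mixed"))
  m2_c2 <- ifelse(lab_v2 == "2", 1, ifelse(lab_v2 == "mixed", 0.5, 0))
  b1 <- build_raw_matrix(config, m1_c1, m1_c2, baseline, eff_c1, eff_c2,
                         subj, plate, "visit1")
  b2 <- build_raw_matrix(config, m2_c1, m2_c2, baseline, eff_c1, eff_c2,
                         subj, plate, "visit2")
  transition <- table(origin = lab_v1, destination = lab_v2)
  ann <- data.frame(subject_id = subj, plate = unname(plate),
                    stringsAsFactors = FALSE)
  if (length(config$covariate_prevalences)) {
    cov <- generate_covariates(lab_v1, config$covariate_prevalences,
                               seed = NULL)
    ann <- cbind(ann, cov[match(ann$subject_id, cov$subject_id), -1,
                          drop = FALSE])
  }
  truth <- list(labels_v1 = lab_v1, labels_v2 = lab_v2,
                destination = dest, transition = transition,
                up_c2 = sets$up_c2, up_c1 = sets$up_c1,
                effects_c2 = eff_c2, effects_c1 = eff_c1, plate = plate)
  list(visit1 = b1$matrix, visit2 = b2$matrix, meta = b1$meta,
       annotation = ann, truth = truth)
}

#' Generate a structure-free control cohort
#'
#' Healthy controls: same panel, baselines and technical effects as a
#' disease cohort but no planted cluster structure. Used as the negative
#' control of the whole pipeline.
#'
#' @param config a [generator_config()] with `up_in_c1 = up_in_c2 = 0`.
#' @return As [generate_cohort()] but without truth labels or up-sets.
#' @export
generate_healthy <- function(config) {
  validate_config(config)
  if (config$up_in_c2 != 0L || config$up_in_c1 != 0L)
    stop("configuration error: a control cohort must have no planted sets")
  out <- generate_cohort(config)
  out$truth$labels <- NULL
  out$truth$up_c2 <- out$truth$up_c1 <- character(0)
  out
}

#' Draw cluster-conditional binary clinical covariates
#'
#' Each covariate is a Bernoulli draw per subject with a prevalence that
#' depends on the subject's cluster, emulating clinical tables where, e.g.,
#' emphysema is present in 52% of Cluster 1 but 31% of Cluster 2.
#'
#' @param labels named vector of cluster labels (1/2) per subject id.
#' @param covariate_prevalences named list of `c(cluster1, cluster2)`
#'   probability pairs.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return A `data.frame` with `subject_id` and one 0/1 column per covariate.
#' @export
generate_covariates <- function(labels, covariate_prevalences, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (pv in covariate_prevalences) {
    if (length(pv) != 2L || any(pv < 0) || any(pv > 1))
      stop("covariate prevalences must be probability pairs in [0, 1]")
  }
  lab <- as.integer(labels)
  out <- data.frame(subject_id = names(labels), stringsAsFactors = FALSE)
  for (nm in names(covariate_prevalences)) {
    p <- covariate_prevalences[[nm]][lab]
    out[[nm]] <- stats::rbinom(length(lab), 1L, p)
  }
  out
}

#' Write a generated scenario to disk
#'
#' Writes the expression matrix (or matrices) as wide CSV, the panel
#' metadata and subject annotation as CSV, and the truth bundle as JSON.
#'
#' @param scenario output of [generate_cohort()], [generate_paired_visits()]
#'   or [generate_healthy()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  mats <- if (!is.null(scenario$visit1))
    list(visit1 = scenario$visit1, visit2 = scenario$visit2)
  else list(matrix = scenario$matrix)
  for (nm in names(mats)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    write_matrix(mats[[nm]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(outdir, "panel_meta.csv")
  write_panel_meta(scenario$meta, mp)
  ap <- file.path(outdir, "annotation.csv")
  utils::write.csv(scenario$annotation, ap, row.names = FALSE, quote = FALSE)
  tp <- file.path(outdir, "truth.json")
  truth <- scenario$truth
  truth$transition <- if (!is.null(truth$transition))
    as.data.frame(truth$transition)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, mp, ap, tp))
}
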