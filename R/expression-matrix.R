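#' Construct an expression matrix
#'
#' The central container of the pipeline: a subjects-by-proteins intensity
#' matrix tagged with its scale. Raw aptamer intensities are relative
#' fluorescence units (RFU, nonnegative); after [log2_transform()] the tag
#' switches to `"log2"`. Plate membership is carried alongside so that the
#' standardization steps can undo plate-level technical effects.
#'
#' @param values numeric matrix, subjects in rows and proteins in columns;
#'   both dimensions must carry unique names (subject ids / protein ids).
#' @param scale `"raw"` or `"log2"`. Raw matrices must be nonnegative.
#' @param plate named character or factor mapping each subject id to a
#'   plate id; defaults to a single plate.
#' @param run_id identifier of the assay run (free text).
#' @param normalized logical; has the four-step standardization been applied?
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale`, `plate`, `run_id`, `normalized`.
#' @export
expression_matrix <- function(values, scale = c("raw", "log2"),
                              plate = NULL, run_id = "run1",
                              normalized = FALSE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity values must be numeric")
  if (anyNA(values)) stop("missing values are not allowed")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry subject ids (rownames) and protein ids (colnames)")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate subject id(s): ", paste(dup_s, collapse = ", "))
  dup_p <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_p))
    stop("duplicate protein id(s): ", paste(dup_p, collapse = ", "))
  if (scale == "raw" && any(values < 0))
    stop("raw RFU intensities must be nonnegative")
  if (is.null(plate)) {
    plate <- stats::setNames(rep("plate1", nrow(values)), rownames(values))
  } else {
    plate <- stats::setNames(as.character(plate), names(plate))
    if (is.null(names(plate)) ||
        !setequal(names(plate), rownames(values)))
      stop("plate must be a named vector covering every subject id")
    plate <- plate[rownames(values)]
  }
  structure(
    list(values = values, scale = scale, plate = plate,
         run_id = run_id, normalized = normalized),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d subjects x %d proteins [%s%s], %d plate(s), run '%s'\n",
    nrow(x$values), ncol(x$values), x$scale,
    if (x$normalized) ", normalized" else "",
    length(unique(x$plate)), x$run_id))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

subject_ids <- function(x) rownames(x$values)
protein_ids <- function(x) colnames(x$values)

#' Construct a panel metadata table
#'
#' Per-protein annotation of the aptamer panel. Control probes
#' (hybridization controls, calibrators) carry technical signal only and are
#' excluded from all biological analyses; they are what makes the
#' standardization steps identifiable.
#'
#' @param protein_id character vector of panel protein ids.
#' @param target_name human-readable target names (defaults to the ids).
#' @param is_hyb_control,is_calibrator logical flags per protein.
#' @param dilution_group optional grouping used for median signal
#'   normalization; a single group by default.
#'
#' @return A `data.frame` with class `PanelMeta`.
#' @export
panel_meta <- function(protein_id, target_name = protein_id,
                       is_hyb_control = FALSE, is_calibrator = FALSE,
                       dilution_group = "all") {
  if (anyDuplicated(protein_id))
    stop("duplicate protein id(s) in panel metadata")
  df <- data.frame(
    protein_id = as.character(protein_id),
    target_name = as.character(target_name),
    is_hyb_control = rep_len(as.logical(is_hyb_control), length(protein_id)),
    is_calibrator = rep_len(as.logical(is_calibrator), length(protein_id)),
    dilution_group = rep_len(as.character(dilution_group), length(protein_id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("PanelMeta", "data.frame")
  df
}

#' Non-control protein ids of a panel
#' @param meta a [panel_meta()] table.
#' @return character vector of assay (non-control) protein ids.
#' @export
assay_proteins <- function(meta) {
  meta$protein_id[!meta$is_hyb_control & !meta$is_calibrator]
}

#' Read / write an expression matrix as wide CSV
#'
#' The on-disk format is a wide CSV: one row per subject, first column
#' `subject_id`, optional second column `plate`, remaining columns the
#' protein intensities. Panel metadata travels in a companion CSV with
#' columns `protein_id`, `target_name`, `is_hyb_control`, `is_calibrator`,
#' `dilution_group`.
#'
#' @param path path to the matrix CSV.
#' @param meta_path optional path to the panel metadata CSV; when absent a
#'   minimal all-assay panel is synthesized from the column names.
#' @param scale scale tag of the stored values.
#' @return `read_matrix`: a list with elements `matrix` (an
#'   `ExpressionMatrix`) and `meta` (a `PanelMeta`).
#' @export
read_matrix <- function(path, meta_path = NULL, scale = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop("matrix CSV must start with a 'subject_id' column")
  has_plate <- identical(names(df)[2], "plate")
  first_data <- if (has_plate) 3L else 2L
  prot <- names(df)[first_data:ncol(df)]
  dup <- unique(prot[duplicated(prot)])
  if (length(dup))
    stop("duplicate protein id(s) in file: ", paste(dup, collapse = ", "))
  vals <- as.matrix(df[, first_data:ncol(df), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric intensity values (ragged file?)")
  rownames(vals) <- df$subject_id
  plate <- if (has_plate) stats::setNames(df$plate, df$subject_id) else NULL
  m <- expression_matrix(vals, scale = scale, plate = plate)
  meta <- if (!is.null(meta_path)) read_panel_meta(meta_path)
          else panel_meta(prot)
  list(matrix = m, meta = meta)
}

#' @rdname read_matrix
#' @param x an `ExpressionMatrix` to write.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(subject_id = subject_ids(x),
                   plate = unname(x$plate),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_matrix
#' @export
read_panel_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_meta(df$protein_id, df$target_name,
             df$is_hyb_control, df$is_calibrator, df$dilution_group)
}

#' @rdname read_matrix
#' @param meta a `PanelMeta` to write.
#' @export
write_panel_meta <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
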