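#' Lesions x features table
#'
#' Container for the radiomics matrix: patient ids, lesion class labels
#' (-1 low Gleason group, +1 high), the numeric feature matrix with
#' canonical column names, and an image-type tag per column (parsed from
#' the `type:` prefix of canonical names, or `"unknown"`).
#'
#' @param patient_id Vector of patient ids, one per lesion (row).
#' @param label Numeric vector of labels in {-1, +1}.
#' @param features Numeric matrix (lesions x features) with unique,
#'   non-empty column names; all entries must be finite.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(patient_id, label, features) {
  features <- as.matrix(features)
  if (length(patient_id) != nrow(features) || length(label) != nrow(features))
    stop("ragged rows: ids/labels/features disagree")
  if (!all(label %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (is.null(colnames(features)) || anyDuplicated(colnames(features)))
    stop("feature columns must have unique names")
  if (!all(is.finite(features))) stop("non-finite feature values")
  tags <- sub(":.*$", "", colnames(features))
  tags[!tags %in% .image_types] <- "unknown"
  structure(list(patient_id = patient_id, label = as.numeric(label),
                 features = features, image_type = tags),
            class = "feature_table")
}

#' Assemble a feature table from per-lesion feature rows
#'
#' @param patient_id,label As in [feature_table()].
#' @param rows Numeric matrix or list of identically named feature vectors.
#' @return A `feature_table` with columns in the rows' (enumeration) order.
#' @export
build_table <- function(patient_id, label, rows) {
  if (is.list(rows) && !is.matrix(rows)) {
    nm <- names(rows[[1]])
    for (r in rows) if (!identical(names(r), nm))
      stop("mismatched feature names across lesions")
    rows <- do.call(rbind, rows)
  }
  feature_table(patient_id, label, rows)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d lesions x %d features (%d low / %d high)\n",
              nrow(x$features), ncol(x$features),
              sum(x$label == -1), sum(x$label == 1)))
  cat("image types:", paste(unique(x$image_type), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature table by image types
#'
#' Keeps columns whose image-type tag is in `types`, preserving order.
#'
#' @param table A `feature_table`.
#' @param types Non-empty character vector of image types.
#' @return A `feature_table`.
#' @export
subset_by_image_types <- function(table, types) {
  if (length(types) == 0L) stop("types must be non-empty")
  if (!all(types %in% table$image_type))
    stop("unknown image type(s): ",
         paste(setdiff(types, table$image_type), collapse = ", "))
  keep <- table$image_type %in% types
  feature_table(table$patient_id, table$label,
                table$features[, keep, drop = FALSE])
}

#' Z-score normalize a feature table
#'
#' Per-column standardization to zero mean and unit variance using the
#' statistics of `reference_rows` only (so held-out rows can be transformed
#' by training-set statistics without leakage). Columns with zero reference
#' standard deviation map to 0.
#'
#' @param table A `feature_table`.
#' @param reference_rows Row indices supplying mean/sd (default all rows).
#' @return A `feature_table` with normalized features.
#' @export
normalize_features <- function(table, reference_rows = seq_len(nrow(table$features))) {
  if (length(reference_rows) < 2L) stop("need >= 2 reference rows")
  x <- table$features
  ref <- x[reference_rows, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  z <- sweep(x, 2, mu, `-`)
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), `/`)
  z[, sdv == 0] <- 0
  feature_table(table$patient_id, table$label, z)
}

#' Write / read a feature table as CSV
#'
#' The layout of the deposited lesion-radiomics file: first column the
#' patient id, second column the Gleason group label (-1 low, +1 high),
#' remaining columns the features, with a header row of names. Numbers are
#' written with 17 significant digits so write -> read round-trips to full
#' double precision. Reading matches columns positionally (id, label,
#' features) and keeps header names as given.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_csv`: `path` invisibly; `read_feature_csv`: a
#'   `feature_table`.
#' @export
write_feature_csv <- function(table, path) {
  hdr <- c("patient_id", "gleason_group", colnames(table$features))
  num <- cbind(table$label, table$features)
  lines <- vapply(seq_len(nrow(num)), function(i) {
    paste(c(as.character(table$patient_id[i]),
            sprintf("%.17g", num[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(hdr, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing feature CSV: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  if (nrow(dt) == 0L || ncol(dt) < 3L) stop("malformed feature CSV: ", path)
  lab <- as.numeric(dt[[2]])
  if (!all(lab %in% c(-1, 1))) stop("label column must contain only -1/+1")
  x <- as.matrix(dt[, -(1:2)])
  storage.mode(x) <- "double"
  feature_table(dt[[1]], lab, x)
}
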