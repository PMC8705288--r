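#' @importFrom stats rnorm runif sd predict coef
#' @importFrom utils read.csv write.csv head
NULL

VALID_LABELS <- c(0L, 1L, 2L, 4L)

#' Construct a labeled brain volume
#'
#' A `labeled_volume` couples a 3D integer segmentation-label grid with an
#' optional aligned intensity grid. Labels follow the BraTS scheme:
#' 0 = background/healthy tissue, 1 = necrotic and non-enhancing tumor core
#' (NCR/NET), 2 = peritumoral edema (ED), 4 = enhancing tumor (ET).
#'
#' @param labels 3D integer array of segmentation labels.
#' @param intensity Optional 3D numeric array aligned with `labels`.
#' @param subject_id Subject identifier string.
#' @param axis_roles Character vector of length 3 mapping array axes to
#'   anatomical axes. Default: axis 1 sagittal (left-right), axis 2 coronal
#'   (anterior-posterior), axis 3 axial (superior-inferior), matching the
#'   BraTS 240x240x155 layout.
#' @return Object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, intensity = NULL, subject_id = "subject",
                           axis_roles = c("sagittal", "coronal", "axial")) {
  if (length(dim(labels)) != 3L) {
    stop("ostvol_shape_error: labels must be a 3D array", call. = FALSE)
  }
  if (any(dim(labels) < 2L)) {
    stop("ostvol_shape_error: every dimension must have at least 2 voxels",
         call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), VALID_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("ostvol_label_error: label values outside {0,1,2,4}: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(intensity)) {
    if (!identical(dim(intensity), dim(labels))) {
      stop("ostvol_shape_error: intensity and label grids have different shapes",
           call. = FALSE)
    }
    storage.mode(intensity) <- "double"
  }
  if (!is.character(axis_roles) || length(axis_roles) != 3L ||
      !setequal(axis_roles, c("sagittal", "coronal", "axial"))) {
    stop("ostvol_axis_error: axis_roles must be a permutation of sagittal/coronal/axial",
         call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 labels = labels,
                 intensity = intensity,
                 shape = dim(labels),
                 axis_roles = axis_roles),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("Labeled brain volume '%s': %s voxels (%s)\n", x$subject_id,
              paste(x$shape, collapse = " x "),
              paste(x$axis_roles, collapse = "/")))
  tab <- table(factor(x$labels, levels = VALID_LABELS))
  cat(sprintf("  labels: bg=%d NCR/NET=%d ED=%d ET=%d; intensity: %s\n",
              tab[["0"]], tab[["1"]], tab[["2"]], tab[["4"]],
              if (is.null(x$intensity)) "absent" else "present"))
  invisible(x)
}

#' Read a labeled volume from NIfTI files
#'
#' Reads a segmentation-label NIfTI volume and, optionally, an aligned
#' intensity (modality) volume. Label values are validated against the
#' BraTS set {0, 1, 2, 4}.
#'
#' @param path_labels Path to the label NIfTI file (`.nii` / `.nii.gz`).
#' @param path_intensity Optional path to an intensity NIfTI file with
#'   identical geometry.
#' @param subject_id Subject identifier; defaults to the label file stem.
#' @param axis_roles Anatomical role of each array axis, used when a file
#'   carries no usable orientation metadata (BraTS default).
#' @return A [labeled_volume].
#' @export
read_labeled_volume <- function(path_labels, path_intensity = NULL,
                                subject_id = NULL,
                                axis_roles = c("sagittal", "coronal", "axial")) {
  if (!file.exists(path_labels)) {
    stop(sprintf("ostvol_io_error: label file not found: %s", path_labels),
         call. = FALSE)
  }
  # plain array, stripped of niftiImage attributes
  as_plain <- function(img) array(as.vector(img), dim = dim(img))
  labels <- tryCatch(as_plain(RNifti::readNifti(path_labels)),
                     error = function(e) {
                       stop(sprintf("ostvol_io_error: cannot read NIfTI '%s': %s",
                                    path_labels, conditionMessage(e)), call. = FALSE)
                     })
  intensity <- NULL
  if (!is.null(path_intensity)) {
    if (!file.exists(path_intensity)) {
      stop(sprintf("ostvol_io_error: intensity file not found: %s",
                   path_intensity), call. = FALSE)
    }
    intensity <- as_plain(RNifti::readNifti(path_intensity))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path_labels))
  }
  labeled_volume(round(labels), intensity, subject_id, axis_roles)
}

#' Write a labeled volume to NIfTI files
#'
#' @param volume A [labeled_volume].
#' @param path_labels Output path for the label volume.
#' @param path_intensity Optional output path for the intensity volume;
#'   required if the volume carries one and you want it written.
#' @return Invisibly, the label path.
#' @export
write_labeled_volume <- function(volume, path_labels, path_intensity = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  RNifti::writeNifti(volume$labels, path_labels)
  if (!is.null(path_intensity)) {
    if (is.null(volume$intensity)) {
      stop("ostvol_io_error: volume has no intensity grid to write", call. = FALSE)
    }
    RNifti::writeNifti(volume$intensity, path_intensity)
  }
  invisible(path_labels)
}

#' Read a clinical table
#'
#' Parses a BraTS-style survival CSV into a clinical data frame with one row
#' per subject: `subject_id`, `age` (years), `survival_days` (NA when
#' censored), `censored` (logical, alive at last follow-up) and `resection`
#' (GTR / STR / NA). A survival entry matching one of `alive_markers`
#' (case-insensitive) marks the subject censored.
#'
#' @param path CSV file path with a header row.
#' @param columns Named character vector mapping the roles `id`, `age`,
#'   `survival`, `resection` to column names in the file (BraTS 2019
#'   defaults).
#' @param alive_markers Strings in the survival column denoting an alive
#'   (censored) subject.
#' @return Data frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path,
                                columns = c(id = "BraTS19ID", age = "Age",
                                            survival = "Survival",
                                            resection = "ResectionStatus"),
                                alive_markers = c("ALIVE")) {
  if (!file.exists(path)) {
    stop(sprintf("ostvol_io_error: clinical table not found: %s", path),
         call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(unname(columns[c("id", "age", "survival", "resection")]),
                          names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("ostvol_column_error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  id <- trimws(raw[[columns[["id"]]]])
  if (anyDuplicated(id)) {
    stop(sprintf("ostvol_duplicate_error: duplicate subject_id: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(trimws(raw[[columns[["age"]]]])))
  if (anyNA(age) || any(age <= 0)) {
    stop("ostvol_parse_error: age must be a positive number for every subject",
         call. = FALSE)
  }
  surv_raw <- trimws(raw[[columns[["survival"]]]])
  censored <- toupper(surv_raw) %in% toupper(alive_markers) | surv_raw == ""
  survival_days <- rep(NA_integer_, length(surv_raw))
  num <- suppressWarnings(as.numeric(surv_raw[!censored]))
  if (anyNA(num) || any(num <= 0)) {
    stop("ostvol_parse_error: survival must be a positive number of days or an alive marker",
         call. = FALSE)
  }
  survival_days[!censored] <- as.integer(round(num))
  resection <- trimws(raw[[columns[["resection"]]]])
  resection[resection == "" | toupper(resection) == "NA"] <- NA_character_
  bad_res <- setdiff(unique(resection[!is.na(resection)]), c("GTR", "STR"))
  if (length(bad_res) > 0L) {
    stop(sprintf("ostvol_parse_error: unknown resection status: %s",
                 paste(bad_res, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(subject_id = id, age = age, survival_days = survival_days,
                    censored = censored, resection = resection,
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a clinical table
#'
#' Inverse of [read_clinical_table] with the same BraTS 2019 default column
#' names; censored subjects are written with the first alive marker.
#'
#' @param clinical Clinical data frame as returned by [read_clinical_table].
#' @param path Output CSV path.
#' @param columns,alive_markers See [read_clinical_table].
#' @return Invisibly, `path`.
#' @export
write_clinical_table <- function(clinical, path,
                                 columns = c(id = "BraTS19ID", age = "Age",
                                             survival = "Survival",
                                             resection = "ResectionStatus"),
                                 alive_markers = c("ALIVE")) {
  surv <- as.character(clinical$survival_days)
  surv[clinical$censored] <- alive_markers[[1L]]
  out <- data.frame(clinical$subject_id, clinical$age, surv,
                    ifelse(is.na(clinical$resection), "NA", clinical$resection),
                    stringsAsFactors = FALSE)
  names(out) <- unname(columns[c("id", "age", "survival", "resection")])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table
#'
#' Serializes one feature vector per subject to CSV with columns
#' `subject_id`, `class` and one column per scheduled feature name.
#'
#' @param subject_ids Character vector of subject IDs.
#' @param features Matrix (subjects x features) or list of equal-length
#'   feature vectors; column/schedule names become the feature headers.
#' @param path Output CSV path.
#' @param classes Optional survival class per subject (factor or character);
#'   `NA` where unknown.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(subject_ids, features, path, classes = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    lens <- lengths(features)
    if (length(unique(lens)) > 1L) {
      stop("ostvol_length_error: feature vectors have inconsistent lengths",
           call. = FALSE)
    }
    nms <- if (length(features) > 0L) names(features[[1L]]) else character()
    features <- do.call(rbind, lapply(features, as.numeric))
    if (is.null(features)) features <- matrix(numeric(), 0L, length(nms))
    colnames(features) <- nms
  }
  features <- as.matrix(features)
  if (length(subject_ids) != nrow(features)) {
    stop("ostvol_length_error: one feature vector per subject required",
         call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)))
  }
  if (is.null(classes)) classes <- rep(NA_character_, length(subject_ids))
  out <- data.frame(subject_id = as.character(subject_ids),
                    class = as.character(classes),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(features))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table]
#'
#' @param path CSV path.
#' @return Data frame with `subject_id`, `class` and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "class") %in% names(out))) {
    stop("ostvol_column_error: feature table must have subject_id and class columns",
         call. = FALSE)
  }
  out
}
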