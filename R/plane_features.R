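APPROACHES <- c("mid_sagittal", "mid_coronal", "mid_horizontal")

# anatomical axis each sectional plane is orthogonal to
approach_axis_role <- function(approach) {
  switch(match.arg(approach, APPROACHES),
         mid_sagittal = "sagittal",
         mid_coronal = "coronal",
         mid_horizontal = "axial")
}

#' Axis split by a sectional-plane approach
#'
#' Resolves which array axis a given approach halves, from the volume's
#' `axis_roles`: the mid-sagittal plane splits the sagittal (left-right)
#' axis, the mid-coronal plane the coronal (anterior-posterior) axis, and
#' the mid-horizontal plane the axial (superior-inferior) axis.
#'
#' @param volume A [labeled_volume].
#' @param approach One of `"mid_sagittal"`, `"mid_coronal"`,
#'   `"mid_horizontal"`.
#' @return Integer axis index (1-3).
#' @export
split_axis <- function(volume, approach) {
  role <- approach_axis_role(approach)
  which(volume$axis_roles == role)
}

#' Half-ranges of a mid-plane split
#'
#' Splits `1..dim_size` at `floor(dim_size / 2)`: the lower half covers
#' indices `1..floor(dim_size/2)`, the upper half the rest, so for odd sizes
#' the middle slice belongs to the upper half. The two ranges are disjoint
#' and exhaustive, which makes every per-half voxel count sum exactly to the
#' whole-volume count.
#'
#' @param dim_size Number of voxels along the split axis (>= 2).
#' @return List with integer vectors `lower` and `upper`.
#' @export
#' @examples
#' split_indices(240)  # lower 1..120, upper 121..240
#' split_indices(155)  # lower 1..77,  upper 78..155
split_indices <- function(dim_size) {
  if (!is.numeric(dim_size) || length(dim_size) != 1L || dim_size < 2 ||
      dim_size != floor(dim_size)) {
    stop("ostvol_split_error: dim_size must be an integer >= 2", call. = FALSE)
  }
  half <- floor(dim_size / 2)
  list(lower = seq_len(half), upper = seq.int(half + 1L, dim_size))
}

#' Subregion voxel-count volumes
#'
#' Counts voxels of the brain mask and of each tumor subregion, either over
#' the whole volume or restricted to an index range along one axis. All
#' volumes are raw voxel counts (BraTS volumes are resampled to uniform
#' spacing, so counts are proportional to physical volume).
#'
#' @param volume A [labeled_volume].
#' @param mask A [brain_mask] aligned with `volume`.
#' @param axis Optional axis index to restrict.
#' @param index_range Optional integer vector of indices along `axis`.
#' @return Named integer vector: `Vb` (brain), `Vwt` (whole tumor, labels
#'   1+2+4), `Vet` (enhancing tumor, label 4), `Vncr` (NCR/NET, label 1),
#'   `Ved` (edema, label 2).
#' @export
subregion_volumes <- function(volume, mask, axis = NULL, index_range = NULL) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(mask, "brain_mask"))
  if (!identical(dim(mask$mask), dim(volume$labels))) {
    stop("ostvol_shape_error: mask and volume shapes differ", call. = FALSE)
  }
  labels <- volume$labels
  m <- mask$mask
  if (!is.null(axis)) {
    stopifnot(!is.null(index_range), axis %in% 1:3)
    idx <- list(TRUE, TRUE, TRUE)
    idx[[axis]] <- index_range
    labels <- labels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    m <- m[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  }
  vet <- sum(labels == 4L)
  vncr <- sum(labels == 1L)
  ved <- sum(labels == 2L)
  c(Vb = sum(m), Vwt = vet + vncr + ved, Vet = vet, Vncr = vncr, Ved = ved)
}

#' Twelve-feature volumetric vector for one sectional-plane approach
#'
#' The core feature extractor: halves the brain volume by the requested
#' sectional plane and reports, in fixed order, the five subregion volumes
#' of the lower half, the five of the upper half, and the two whole-volume
#' totals (brain and whole tumor). "Lower" and "upper" refer to array index
#' order along the split axis; the anatomical meaning follows the volume's
#' `axis_roles` and is recorded in the feature names.
#'
#' @param volume A [labeled_volume].
#' @param mask A [brain_mask] for the same volume; computed from the
#'   intensity grid if omitted.
#' @param approach One of `"mid_sagittal"`, `"mid_coronal"`,
#'   `"mid_horizontal"`.
#' @return Named numeric vector of length 12 with attribute `approach`.
#'   Order: `lower_Vb, lower_Vwt, lower_Vet, lower_Vncr, lower_Ved,
#'   upper_Vb, ..., upper_Ved, whole_Vb, whole_Vwt`.
#' @export
extract_approach_features <- function(volume, mask = NULL,
                                      approach = c("mid_sagittal",
                                                   "mid_coronal",
                                                   "mid_horizontal")) {
  approach <- match.arg(approach)
  if (is.null(mask)) mask <- brain_mask(volume)
  ax <- split_axis(volume, approach)
  halves <- split_indices(volume$shape[ax])
  lower <- subregion_volumes(volume, mask, ax, halves$lower)
  upper <- subregion_volumes(volume, mask, ax, halves$upper)
  whole <- subregion_volumes(volume, mask)
  fv <- c(lower, upper, whole[c("Vb", "Vwt")])
  names(fv) <- c(paste0("lower_", names(lower)), paste0("upper_", names(upper)),
                 "whole_Vb", "whole_Vwt")
  attr(fv, "approach") <- approach
  fv
}

#' Encode resection status as a binary feature
#'
#' Gross total resection (GTR) encodes to 1; subtotal resection (STR) and
#' unknown status both encode to 0.
#'
#' @param status Character vector with entries `"GTR"`, `"STR"` or `NA`.
#' @return Integer vector of 0/1.
#' @export
encode_resection <- function(status) {
  status <- as.character(status)
  bad <- setdiff(unique(status[!is.na(status)]), c("GTR", "STR"))
  if (length(bad) > 0L) {
    stop(sprintf("ostvol_parse_error: unknown resection status: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.integer(!is.na(status) & status == "GTR")
}

#' Fuse clinical features onto a radiomic feature vector
#'
#' Appends the subject's age (years) to the 12 volumetric features, and
#' optionally the binary resection encoding, yielding the 13- or 14-feature
#' vectors used by the clinically fused models.
#'
#' @param fv Length-12 feature vector from [extract_approach_features].
#' @param age Age in years (positive).
#' @param resection Resection status (`"GTR"`, `"STR"`, `NA`); required when
#'   `include_resection` is `TRUE`.
#' @param include_resection Append the resection feature?
#' @return Named numeric vector of length 13 or 14.
#' @export
fuse_clinical <- function(fv, age, resection = NULL, include_resection = FALSE) {
  if (length(fv) != 12L) {
    stop("ostvol_length_error: fuse_clinical expects a 12-feature radiomic vector",
         call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age <= 0) {
    stop("ostvol_parse_error: age must be a positive number", call. = FALSE)
  }
  approach <- attr(fv, "approach")
  out <- c(fv, age = as.numeric(age))
  if (include_resection) {
    out <- c(out, resection = as.numeric(encode_resection(resection)))
  }
  attr(out, "approach") <- approach
  out
}
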