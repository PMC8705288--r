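#' Synthetic cohort configuration
#'
#' Parameters of the BraTS-style synthetic cohort generator. The defaults
#' emulate the study cohort: 81 short-term, 55 mid-term and 76 long-term
#' subjects (212 in total), GTR rates per class matching the published
#' cross-tabulation with all remaining subjects of unknown resection status,
#' and 240 x 240 x 155 voxel geometry. The class-informative signal is the
#' whole-tumor volume fraction (non-overlapping ranges, decreasing with
#' survival class) together with age (mean decreasing with survival class);
#' tumor laterality is a nuisance parameter.
#'
#' @param n_short,n_mid,n_long Subjects per survival class.
#' @param n_censored Additional censored (alive) subjects with no class.
#' @param shape Volume geometry in voxels; the `"tiny"` preset uses
#'   40 x 40 x 30 for fast in-memory work.
#' @param seed Master seed; per-subject seeds derive from it
#'   deterministically.
#' @param tumor_fraction_ranges Named list of per-class intervals of
#'   whole-tumor volume as a fraction of brain volume; must lie in (0, 0.5)
#'   and decrease with survival class.
#' @param age_means,age_sd Per-class mean age (years) and common SD; ages
#'   are clamped to \[18, 90\].
#' @param laterality_bias Probability the tumor centroid lies in the lower
#'   (left) sagittal half.
#' @param gtr_rates Per-class probability of GTR resection; the remainder
#'   are unknown (NA).
#' @param preset `"tiny"` switches to the small fast geometry.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_short = 81L, n_mid = 55L, n_long = 76L,
                          n_censored = 0L,
                          shape = c(240L, 240L, 155L),
                          seed = 1L,
                          tumor_fraction_ranges = list(
                            short = c(0.10, 0.18),
                            mid   = c(0.05, 0.10),
                            long  = c(0.01, 0.05)),
                          age_means = c(short = 65, mid = 58, long = 52),
                          age_sd = 8,
                          laterality_bias = 0.5,
                          gtr_rates = c(short = 35 / 81, mid = 27 / 55,
                                        long = 39 / 76),
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tiny")
    shape <- c(40L, 40L, 30L)
  }
  stopifnot(n_short >= 0, n_mid >= 0, n_long >= 0, n_censored >= 0,
            length(shape) == 3L, all(shape >= 2L),
            laterality_bias >= 0, laterality_bias <= 1)
  for (cl in survival_class_levels()) {
    rng <- tumor_fraction_ranges[[cl]]
    if (is.null(rng) || length(rng) != 2L || rng[1L] <= 0 || rng[2L] >= 0.5 ||
        rng[1L] > rng[2L]) {
      stop("ostvol_config_error: tumor_fraction_ranges must give an interval in (0, 0.5) per class",
           call. = FALSE)
    }
  }
  structure(list(n_short = as.integer(n_short), n_mid = as.integer(n_mid),
                 n_long = as.integer(n_long), n_censored = as.integer(n_censored),
                 shape = as.integer(shape), seed = as.integer(seed),
                 tumor_fraction_ranges = tumor_fraction_ranges,
                 age_means = age_means, age_sd = age_sd,
                 laterality_bias = laterality_bias, gtr_rates = gtr_rates),
            class = "cohort_config")
}

# logical mask of an axis-aligned ellipsoid rasterized on a voxel grid
ellipsoid_mask <- function(shape, center, semiaxes) {
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - center[i]) / semiaxes[i])^2)
  outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+") <= 1
}

# day interval each survival class spans (generator side)
class_day_interval <- function(class) {
  switch(class,
         short = c(30L, 299L),
         mid   = c(300L, 450L),
         long  = c(451L, 1800L))
}

#' Generate one synthetic subject
#'
#' Emits a labeled volume (brain = ellipsoid of bright intensity on zero
#' background; tumor = nested ellipsoids, NCR/NET core inside an enhancing
#' shell inside an edema envelope, entirely within the brain), a clinical
#' record, and a ground-truth record with every voxel count the feature
#' pipeline should recover. The whole-tumor fraction is drawn from the
#' class's configured range; survival days uniformly from the class's day
#' interval (short \[30, 299\], mid \[300, 450\], long \[451, 1800\]).
#'
#' @param class `"short"`, `"mid"`, `"long"`, or `"censored"`.
#' @param config A [cohort_config].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier string.
#' @return List with `volume` ([labeled_volume]), `clinical` (one-row data
#'   frame), `truth` (list; see Details).
#' @export
generate_subject <- function(class, config, subject_seed,
                             subject_id = sprintf("synth_%s_%d", class, subject_seed)) {
  stopifnot(inherits(config, "cohort_config"))
  class <- match.arg(class, c(survival_class_levels(), "censored"))
  set.seed(subject_seed)
  shape <- config$shape
  center <- (shape + 1) / 2
  brain_ax <- 0.45 * shape * runif(3, 0.92, 1.0)
  brain <- ellipsoid_mask(shape, center, brain_ax)
  vb_true <- sum(brain)

  # effective class for the imaging phenotype of a censored subject
  pheno <- if (class == "censored") sample(survival_class_levels(), 1L) else class
  frac_rng <- config$tumor_fraction_ranges[[pheno]]
  frac <- runif(1, frac_rng[1L], frac_rng[2L])
  s <- frac^(1 / 3)                       # linear scale: voxel count ~ s^3
  tumor_ax <- s * brain_ax
  if (any(tumor_ax >= 0.95 * brain_ax)) {
    stop("ostvol_tumor_fit_error: requested tumor fraction cannot fit inside the brain",
         call. = FALSE)
  }
  # place the tumor center so the edema envelope stays inside the brain:
  # in brain-normalized coordinates the tumor is a ball of radius s, so
  # containment is exactly ||center_offset / brain_ax|| <= 1 - s
  r <- 0.95 * (1 - s)
  dc <- c(0, 0, 0)
  left <- runif(1) < config$laterality_bias
  for (try in seq_len(200L)) {
    cand <- runif(3, -1, 1) * brain_ax * r
    # axis 1 is sagittal under the default axis roles; bias controls side
    cand[1L] <- if (left) -abs(cand[1L]) else abs(cand[1L])
    if (sqrt(sum((cand / brain_ax)^2)) <= r) {
      dc <- cand
      break
    }
  }
  tcen <- center + dc
  ed_env <- ellipsoid_mask(shape, tcen, tumor_ax) & brain
  et_env <- ellipsoid_mask(shape, tcen, 0.75 * tumor_ax) & brain
  ncr_env <- ellipsoid_mask(shape, tcen, 0.45 * tumor_ax) & brain

  labels <- array(0L, shape)
  labels[ed_env] <- 2L
  labels[et_env] <- 4L
  labels[ncr_env] <- 1L

  intensity <- array(0, shape)
  nb <- sum(brain)
  intensity[brain] <- 100 + rnorm(nb, 0, 8)
  intensity[labels == 1L] <- 30 + rnorm(sum(labels == 1L), 0, 5)  # dark necrosis

  vol <- labeled_volume(labels, intensity, subject_id)

  censored <- class == "censored"
  survival_days <- NA_integer_
  if (!censored) {
    iv <- class_day_interval(class)
    survival_days <- sample(seq.int(iv[1L], iv[2L]), 1L)
  }
  age <- min(90, max(18, rnorm(1, config$age_means[[pheno]], config$age_sd)))
  resection <- if (runif(1) < config$gtr_rates[[pheno]]) "GTR" else NA_character_

  clinical <- data.frame(subject_id = subject_id, age = age,
                         survival_days = survival_days, censored = censored,
                         resection = resection, stringsAsFactors = FALSE)

  truth <- list(subject_id = subject_id, class = if (censored) NA_character_ else class,
                tumor_fraction = frac, brain_voxels = vb_true,
                centroid = tcen, brain_center = center,
                brain_semiaxes = brain_ax, tumor_semiaxes = tumor_ax,
                counts = subject_truth_counts(labels, brain))
  list(volume = vol, clinical = clinical, truth = truth)
}

# measure per-axis half counts + whole counts directly off the emitted grids
subject_truth_counts <- function(labels, brain) {
  count_range <- function(l, b) {
    vet <- sum(l == 4L); vncr <- sum(l == 1L); ved <- sum(l == 2L)
    c(Vb = sum(b), Vwt = vet + vncr + ved, Vet = vet, Vncr = vncr, Ved = ved)
  }
  out <- list(whole = count_range(labels, brain))
  for (ax in 1:3) {
    halves <- split_indices(dim(labels)[ax])
    for (side in c("lower", "upper")) {
      idx <- list(TRUE, TRUE, TRUE)
      idx[[ax]] <- halves[[side]]
      l <- labels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
      b <- brain[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
      out[[paste0("axis", ax, "_", side)]] <- count_range(l, b)
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Generates `n_short + n_mid + n_long` class-labeled subjects plus
#' `n_censored` alive subjects, with per-subject seeds derived
#' deterministically from the master seed. The default configuration yields
#' the 81/55/76 composition of the study cohort.
#'
#' @param config A [cohort_config].
#' @return List of class `synthetic_cohort`: `subjects` (list of
#'   [generate_subject] results), `clinical` (data frame), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- c(rep("short", config$n_short), rep("mid", config$n_mid),
               rep("long", config$n_long), rep("censored", config$n_censored))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(classes))
  subjects <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    subjects[[i]] <- generate_subject(classes[i], config, seeds[i],
                                      subject_id = sprintf("synth_%03d", i))
  }
  clinical <- if (length(subjects) == 0L) {
    data.frame(subject_id = character(), age = numeric(),
               survival_days = integer(), censored = logical(),
               resection = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(subjects, `[[`, "clinical"))
  }
  class(clinical) <- c("clinical_table", "data.frame")
  structure(list(subjects = subjects, clinical = clinical, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cl <- bin_survival_days(x$clinical$survival_days[!x$clinical$censored])
  cat(sprintf("Synthetic cohort: %d subjects (%s; %d censored), geometry %s\n",
              nrow(x$clinical),
              paste(sprintf("%s=%d", levels(cl), tabulate(cl, 3L)), collapse = " "),
              sum(x$clinical$censored),
              paste(x$config$shape, collapse = " x ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one label + one intensity NIfTI per subject and the cohort
#' clinical CSV, mirroring the on-disk layout the extraction command
#' consumes.
#'
#' @param cohort A [generate_cohort] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    id <- s$volume$subject_id
    write_labeled_volume(s$volume,
                         file.path(dir, paste0(id, "_seg.nii.gz")),
                         file.path(dir, paste0(id, "_t1.nii.gz")))
  }
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  invisible(dir)
}
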