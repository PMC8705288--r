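#' Extract a cohort feature table
#'
#' Runs brain extraction and sectional-plane feature extraction for every
#' non-censored subject of a cohort, optionally fusing age and resection
#' status, and returns the design matrix with survival-class labels.
#' Censored subjects carry no class and are skipped.
#'
#' @param cohort A [generate_cohort] result, or a list of subjects shaped
#'   like its `subjects` element.
#' @param approach Sectional plane: `"mid_sagittal"`, `"mid_coronal"` or
#'   `"mid_horizontal"`.
#' @param fuse `"none"` (12 features), `"age"` (13) or `"age_resection"`
#'   (14).
#' @return List: `features` (matrix), `classes` (factor), `subject_ids`,
#'   `approach`, `thresholds` (per-subject Otsu thresholds).
#' @export
extract_features <- function(cohort,
                             approach = c("mid_sagittal", "mid_coronal",
                                          "mid_horizontal"),
                             fuse = c("none", "age", "age_resection")) {
  approach <- match.arg(approach)
  fuse <- match.arg(fuse)
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects else cohort
  keep <- !vapply(subjects, function(s) isTRUE(s$clinical$censored), TRUE)
  subjects <- subjects[keep]
  rows <- vector("list", length(subjects))
  thresholds <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    m <- brain_mask(s$volume)
    thresholds[i] <- m$threshold
    fv <- extract_approach_features(s$volume, m, approach)
    rows[[i]] <- switch(fuse,
      none = fv,
      age = fuse_clinical(fv, s$clinical$age),
      age_resection = fuse_clinical(fv, s$clinical$age, s$clinical$resection,
                                    include_resection = TRUE))
  }
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(subjects, function(s) s$volume$subject_id, "")
  classes <- bin_survival_days(vapply(subjects,
                                      function(s) s$clinical$survival_days, 0))
  list(features = features, classes = classes,
       subject_ids = rownames(features), approach = approach,
       thresholds = thresholds)
}

#' Run the full survival-prediction experiment on a cohort
#'
#' End-to-end: extract plane features (optionally fused with clinical
#' covariates), split stratified 70/15/15, optionally select the hidden
#' size by k-fold cross-validation on the training subset, fit the network
#' (early-stopped on the validation subset), and evaluate.
#'
#' @param cohort A [generate_cohort] result.
#' @param approach,fuse See [extract_features].
#' @param hidden Hidden size, or `"cv"` to select over `grid` by
#'   cross-validation.
#' @param grid Hidden-size grid when `hidden = "cv"`.
#' @param fractions Split fractions (train, val, test).
#' @param seed Seed controlling split, initialization and CV folds.
#' @param ... Further [ost_net] arguments.
#' @return List of class `ost_experiment`: `model`, `eval` ([evaluate_model]
#'   report), `split`, `hidden`, `cv` (when selected), `approach`, `fuse`.
#' @export
run_experiment <- function(cohort,
                           approach = c("mid_sagittal", "mid_coronal",
                                        "mid_horizontal"),
                           fuse = c("age", "none", "age_resection"),
                           hidden = 50L, grid = c(40L, 50L, 100L, 150L, 200L),
                           fractions = c(0.70, 0.15, 0.15), seed = 1L, ...) {
  approach <- match.arg(approach)
  fuse <- match.arg(fuse)
  fx <- extract_features(cohort, approach, fuse)
  split <- stratified_split(fx$classes, fractions, seed)
  cv <- NULL
  if (identical(hidden, "cv")) {
    cv <- select_hidden_size(fx$features[split$train, , drop = FALSE],
                             fx$classes[split$train], grid = grid, seed = seed, ...)
    hidden <- cv$hidden
  }
  model <- ost_net(fx$features[split$train, , drop = FALSE],
                   fx$classes[split$train], hidden = hidden, seed = seed,
                   x_val = fx$features[split$val, , drop = FALSE],
                   y_val = fx$classes[split$val], ...)
  ev <- evaluate_model(model, fx$features, fx$classes, split)
  structure(list(model = model, eval = ev, split = split, hidden = hidden,
                 cv = cv, approach = approach, fuse = fuse,
                 features = fx$features, classes = fx$classes, seed = seed),
            class = "ost_experiment")
}

#' @export
print.ost_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %s + %s, hidden = %d, seed = %d\n",
              x$approach, x$fuse, x$hidden, x$seed))
  print(x$eval)
  invisible(x)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort and writes per-subject NIfTI volumes, the
#' clinical CSV, a ground-truth CSV and a manifest recording the seed and
#' per-file checksums.
#'
#' @param config A [cohort_config].
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
cmd_simulate <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  truth <- do.call(rbind, lapply(cohort$subjects, function(s) {
    w <- s$truth$counts$whole
    data.frame(subject_id = s$truth$subject_id, class = s$truth$class,
               tumor_fraction = s$truth$tumor_fraction,
               brain_voxels = s$truth$brain_voxels,
               Vwt = w[["Vwt"]], Vet = w[["Vet"]], Vncr = w[["Vncr"]],
               Ved = w[["Ved"]], stringsAsFactors = FALSE)
  }))
  write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  files <- sort(list.files(dir, full.names = TRUE))
  manifest <- data.frame(
    file = basename(files),
    md5 = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(manifest, "seed") <- config$seed
  write.csv(cbind(seed = config$seed, manifest),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Extract features from an on-disk cohort
#'
#' Reads the NIfTI volumes and clinical CSV written by [cmd_simulate] and
#' writes one feature table per requested approach. Censored subjects are
#' skipped.
#'
#' @param dir Cohort directory.
#' @param out_dir Output directory for the feature CSVs.
#' @param approach One approach name or `"all"`.
#' @param fuse See [extract_features].
#' @return Invisibly, character vector of written paths.
#' @export
cmd_extract <- function(dir, out_dir = dir, approach = "all",
                        fuse = c("none", "age", "age_resection")) {
  fuse <- match.arg(fuse)
  clinical <- read_clinical_table(
    file.path(dir, "clinical.csv"),
    columns = c(id = "BraTS19ID", age = "Age", survival = "Survival",
                resection = "ResectionStatus"))
  subjects <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$subject_id[i]
    seg <- file.path(dir, paste0(id, "_seg.nii.gz"))
    t1 <- file.path(dir, paste0(id, "_t1.nii.gz"))
    if (!file.exists(seg) || !file.exists(t1)) {
      stop(sprintf("ostvol_io_error: missing volume files for subject %s", id),
           call. = FALSE)
    }
    list(volume = read_labeled_volume(seg, t1, subject_id = id),
         clinical = clinical[i, , drop = FALSE])
  })
  approaches <- if (identical(approach, "all")) APPROACHES else approach
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ap in approaches) {
    fx <- extract_features(subjects, ap, fuse)
    path <- file.path(out_dir, sprintf("features_%s_%s.csv", ap, fuse))
    write_feature_table(fx$subject_ids, fx$features, path,
                        classes = as.character(fx$classes))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Train and evaluate from a feature table on disk
#'
#' @param feature_csv Feature table written by [cmd_extract].
#' @param out_dir Where to write the JSON report and model file.
#' @param hidden Hidden size or `"cv"`.
#' @param seed Seed for split/fit.
#' @param ... Passed to [ost_net].
#' @return Invisibly, the [evaluate_model] report.
#' @export
cmd_train_eval <- function(feature_csv, out_dir = dirname(feature_csv),
                           hidden = "cv", seed = 1L, ...) {
  tab <- read_feature_table(feature_csv)
  if (anyNA(tab$class)) {
    stop("ostvol_class_error: feature table contains unlabeled subjects",
         call. = FALSE)
  }
  x <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "class")),
                     drop = FALSE])
  y <- factor(tab$class, levels = survival_class_levels())
  split <- stratified_split(y, seed = seed)
  cv <- NULL
  if (identical(hidden, "cv")) {
    cv <- select_hidden_size(x[split$train, , drop = FALSE], y[split$train],
                             seed = seed, ...)
    hidden <- cv$hidden
  }
  model <- ost_net(x[split$train, , drop = FALSE], y[split$train],
                   hidden = hidden, seed = seed,
                   x_val = x[split$val, , drop = FALSE], y_val = y[split$val], ...)
  ev <- evaluate_model(model, x, y, split)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ost_net(model, file.path(out_dir, "model.txt"))
  report <- list(seed = seed, hidden = hidden,
                 accuracy = as.list(ev$accuracy),
                 overall_accuracy = ev$overall_accuracy,
                 subset_sizes = as.list(ev$subset_sizes),
                 confusion = unclass(ev$confusion),
                 auc = as.list(ev$auc),
                 cv_accuracy = if (!is.null(cv)) as.list(cv$cv_accuracy))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(as.data.frame(ev$confusion),
            file.path(out_dir, "confusion.csv"), row.names = FALSE)
  invisible(ev)
}
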