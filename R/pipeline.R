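#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving the image geometry. Masks are
#' written as uint8; `read_mask()` returns a logical array.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol Numeric/integer array (logical for masks).
#' @param template Optional image or path whose header supplies the
#'   affine and pixel dimensions.
#' @return `read_volume()`: an array (RNifti image); `write_volume()` /
#'   `write_mask()`: the path, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tryCatch(RNifti::readNifti(path),
           error = function(e) stop("failed to read NIfTI file '", path,
                                    "': ", conditionMessage(e)))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, template = NULL) {
  if (is.null(template)) RNifti::writeNifti(vol, path)
  else RNifti::writeNifti(RNifti::asNifti(vol, reference = template), path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(vol, path, template = NULL) {
  m <- array(as.integer(vol), dim(vol))
  img <- if (is.null(template)) RNifti::asNifti(m)
         else RNifti::asNifti(m, reference = template)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  array(as.vector(v) > 0.5, dim(v))
}

#' Read and write a 4D DCE series with its JSON sidecar
#'
#' The 4D intensity stack is stored as NIfTI; acquisition times, the
#' injection duration and the voxel spacing travel in a JSON sidecar
#' next to the image (`<name>.json`), or can be supplied directly.
#'
#' @param path NIfTI path of the 4D stack.
#' @param timepoints,tau Override the sidecar values (seconds).
#' @param series A [dce_series()].
#' @return `read_series()`: a `dce_series`; `write_series()`: the path,
#'   invisibly.
#' @export
read_series <- function(path, timepoints = NULL, tau = NULL) {
  vol <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  tp <- if (!is.null(timepoints)) timepoints else meta$timepoints
  tu <- if (!is.null(tau)) tau else meta$tau
  if (is.null(tp) || is.null(tu))
    stop("timepoints/tau not given and no sidecar found at ", side)
  sp <- if (!is.null(meta$voxel_spacing)) meta$voxel_spacing
        else attr(RNifti::niftiHeader(vol), "pixdim")[2:4]
  if (is.null(sp) || length(sp) != 3L) sp <- c(1, 1, 1)
  dce_series(array(as.numeric(vol), dim(vol)), tp, tu, sp)
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  RNifti::writeNifti(series$intensities, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(timepoints = series$timepoints,
                            tau = series$tau,
                            voxel_spacing = series$voxel_spacing),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the settings of every stage of the detection pipeline. With
#' `subjects = NULL` the run simulates `n_subjects` phantoms (per-subject
#' seeds derived from `seed`); otherwise `subjects` is a manifest list,
#' one entry per subject with `series` (NIfTI path or `dce_series`) and
#' `lesion_mask` (path or logical array).
#'
#' @param n_subjects Number of phantoms to simulate.
#' @param phantom Base [phantom_spec()] for simulation.
#' @param subjects Optional subject manifest (overrides simulation).
#' @param train_subjects Indices of the subjects supplying training and
#'   verification voxels.
#' @param texture A [texture_config()].
#' @param nn An [nn_config()].
#' @param thresholds Decision thresholds to sweep.
#' @param universe `"body"` (evaluation restricted to body tissue and
#'   texture-valid voxels; air never counts as a true negative) or
#'   `"all"` (every voxel).
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Optional directory for run artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 6L, phantom = phantom_spec(),
                            subjects = NULL, train_subjects = 1:2,
                            texture = texture_config(), nn = nn_config(),
                            thresholds = default_thresholds(),
                            universe = c("body", "all"), seed = 1L,
                            outdir = NULL) {
  universe <- match.arg(universe)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1))
    stop("'thresholds' must be strictly increasing within (0, 1)")
  structure(list(n_subjects = as.integer(n_subjects), phantom = phantom,
                 subjects = subjects,
                 train_subjects = as.integer(train_subjects),
                 texture = texture, nn = nn, thresholds = thresholds,
                 universe = universe, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

.load_subject <- function(entry, i) {
  series <- entry$series
  if (is.character(series)) series <- read_series(series)
  lesion <- entry$lesion_mask
  if (is.character(lesion)) lesion <- read_mask(lesion)
  list(name = if (!is.null(entry$name)) entry$name else sprintf("S%02d", i),
       series = series, lesion_mask = lesion,
       reader2_mask = if (is.character(entry$reader2_mask))
         read_mask(entry$reader2_mask) else entry$reader2_mask)
}

.validate_manifest <- function(subjects) {
  for (entry in subjects)
    for (f in c("series", "lesion_mask", "reader2_mask")) {
      v <- entry[[f]]
      if (is.character(v) && !file.exists(v))
        stop("manifest references a missing file: ", v)
    }
  invisible(TRUE)
}

#' Run the full detection pipeline
#'
#' Executes simulate/ingest -> voxelwise model fit -> texture stage ->
#' classifier training -> threshold sweep -> evaluation against the
#' primary-reader ground truth, plus the paired t-test comparison with
#' the (simulated or supplied) second reader. Training and verification
#' voxels are excluded from all reported fractions. Re-running with an
#' identical configuration reproduces identical metrics.
#'
#' @param config A [pipeline_config()].
#' @return A `cad_run` object: per-subject and pooled TPF/FPF tables,
#'   the scatter table, per-threshold t-tests, the trained model, the
#'   per-subject artifacts, and run provenance (seed, config
#'   fingerprint).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  simulate <- is.null(config$subjects)
  if (!simulate) .validate_manifest(config$subjects)
  n <- if (simulate) config$n_subjects else length(config$subjects)
  if (!length(config$train_subjects) || max(config$train_subjects) > n)
    stop("'train_subjects' must index the available subjects")
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    if (simulate) {
      spec <- config$phantom
      spec$seed <- config$seed + i
      ph <- generate_phantom(spec)
      subjects[[i]] <- list(name = sprintf("S%02d", i), series = ph$series,
                            lesion_mask = ph$truth_mask,
                            reader2_mask = NULL, phantom = ph)
    } else {
      subjects[[i]] <- .load_subject(config$subjects[[i]], i)
    }
  }
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    baseline <- array(s$series$intensities[, , , 1L],
                      dim(s$series$intensities)[1:3])
    s$body_mask <- compute_body_mask(baseline)
    s$pk <- fit_volume(s$series, s$body_mask)
    s$tex <- texture_stage(s$pk, config$texture)
    if (is.null(s$reader2_mask) && simulate)
      s$reader2_mask <- simulate_second_reader(
        s$lesion_mask, config$phantom$reader2_error,
        seed = config$seed + 200L + i)
    subjects[[i]] <- s
  }
  # pooled, balanced training/verification voxels from the designated
  # training subjects
  tr_feat <- ve_feat <- NULL; tr_lab <- ve_lab <- integer(0)
  for (i in config$train_subjects) {
    s <- subjects[[i]]
    sets <- build_training_and_verification_sets(
      s$lesion_mask, s$body_mask, s$tex$validity_mask, s$tex,
      seed = config$seed + 100L + i)
    subjects[[i]]$sets <- sets
    tr_feat <- rbind(tr_feat, sets$training$features)
    ve_feat <- rbind(ve_feat, sets$verification$features)
    tr_lab <- c(tr_lab, sets$training$labels)
    ve_lab <- c(ve_lab, sets$verification$labels)
  }
  pooled_train <- structure(list(coords = NA, features = tr_feat,
                                 labels = tr_lab, seed = config$seed),
                            class = "voxel_set")
  pooled_verify <- structure(list(coords = NA, features = ve_feat,
                                  labels = ve_lab, seed = config$seed),
                             class = "voxel_set")
  model <- train_nn(pooled_train, pooled_verify, config$nn)
  per_subject <- list(); reader2 <- list()
  pooled_counts <- NULL
  completeness <- numeric(0)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    scores <- predict_scores(model, s$tex, s$body_mask)
    subjects[[i]]$scores <- scores
    universe <- if (config$universe == "body")
      s$body_mask & s$tex$validity_mask else array(TRUE, dim(s$body_mask))
    excl <- array(FALSE, dim(s$body_mask))
    if (!is.null(s$sets))
      excl[c(s$sets$training$coords, s$sets$verification$coords)] <- TRUE
    ev <- evaluate_thresholds(scores, s$lesion_mask, config$thresholds,
                              exclusion_mask = excl,
                              universe_mask = universe)
    per_subject[[s$name]] <- ev
    cc <- ev[, c("TP", "FP", "TN", "FN")]
    pooled_counts <- if (is.null(pooled_counts)) cc else pooled_counts + cc
    r2 <- tpf_fpf(confusion_counts(s$reader2_mask, s$lesion_mask,
                                   exclusion_mask = excl,
                                   universe_mask = universe))
    reader2[[s$name]] <- r2
    # lesion-level completeness at the lowest threshold
    lab <- label_components(s$lesion_mask)
    pred_lo <- threshold_scores(scores, config$thresholds[1L])
    hits <- vapply(seq_len(max(lab)), function(c)
      any(pred_lo[lab == c]), logical(1L))
    completeness <- c(completeness, mean(hits))
  }
  pooled <- data.frame(threshold = config$thresholds, pooled_counts)
  pooled$TPF <- pooled$TP / (pooled$TP + pooled$FN)
  pooled$FPF <- pooled$FP / (pooled$FP + pooled$TN)
  ttests <- lapply(seq_along(config$thresholds), function(k) {
    tpf_c <- vapply(per_subject, function(ev) ev$TPF[k], numeric(1L))
    fpf_c <- vapply(per_subject, function(ev) ev$FPF[k], numeric(1L))
    tpf_r <- vapply(reader2, function(r) r[["TPF"]], numeric(1L))
    fpf_r <- vapply(reader2, function(r) r[["FPF"]], numeric(1L))
    list(threshold = config$thresholds[k],
         TPF = paired_difference_ttest(tpf_c, tpf_r),
         FPF = paired_difference_ttest(fpf_c, fpf_r))
  })
  run <- structure(list(per_subject = per_subject, pooled = pooled,
                        reader2 = reader2,
                        scatter = scatter_table(per_subject, reader2),
                        ttests = ttests,
                        detection_completeness = completeness,
                        model = model, subjects = subjects,
                        config = config, seed = config$seed,
                        fingerprint = fingerprint(
                          jsonlite::toJSON(config[setdiff(names(config), "subjects")],
                                           force = TRUE, auto_unbox = TRUE))),
                   class = "cad_run")
  if (!is.null(config$outdir)) .write_run(run, config$outdir)
  run
}

.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$pooled, file.path(outdir, "pooled_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$scatter, file.path(outdir, "scatter_table.csv"),
                   row.names = FALSE)
  tt <- do.call(rbind, lapply(run$ttests, function(t)
    data.frame(threshold = t$threshold,
               t_TPF = t$TPF$t_statistic, p_TPF = t$TPF$p_value,
               t_FPF = t$FPF$t_statistic, p_FPF = t$FPF$p_value)))
  utils::write.csv(tt, file.path(outdir, "ttests.csv"), row.names = FALSE)
  for (s in run$subjects) {
    base <- file.path(outdir, s$name)
    write_volume(s$pk$A, paste0(base, "_A.nii.gz"))
    write_volume(s$pk$k_ep, paste0(base, "_kep.nii.gz"))
    write_volume(s$pk$k_el, paste0(base, "_kel.nii.gz"))
    write_volume(s$scores, paste0(base, "_scores.nii.gz"))
    write_mask(s$body_mask, paste0(base, "_body.nii.gz"))
  }
  jsonlite::write_json(list(seed = run$seed, fingerprint = run$fingerprint,
                            r_version = as.character(getRversion()),
                            thresholds = run$config$thresholds,
                            universe = run$config$universe,
                            n_subjects = length(run$subjects)),
                       file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.cad_run <- function(x, ...) {
  cat(sprintf("<cad_run> %d subjects, seed %d, config %s\n",
              length(x$subjects), x$seed, x$fingerprint))
  cat("Pooled voxelwise performance (training/verification voxels excluded):\n")
  print(x$pooled[, c("threshold", "TPF", "FPF")], row.names = FALSE,
        digits = 4)
  r2 <- do.call(rbind, x$reader2)
  cat(sprintf("Second reader: mean TPF %.4f, mean FPF %.4f\n",
              mean(r2[, "TPF"], na.rm = TRUE),
              mean(r2[, "FPF"], na.rm = TRUE)))
  cat(sprintf("Lesion detection completeness at threshold %.2f: %.0f%%\n",
              x$config$thresholds[1L],
              100 * mean(x$detection_completeness)))
  invisible(x)
}
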