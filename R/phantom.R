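#' Digital phantom specification
#'
#' Describes a synthetic DCE-MR breast acquisition: an ellipsoidal body
#' of normally-enhancing tissue with embedded benign and malignant
#' lesions, imaged at one baseline plus five post-contrast time points
#' 120 s apart with a 7 s bolus. Malignant kinetics have markedly faster
#' back-transfer (k_ep) and higher amplitude than normal tissue,
#' mirroring the leaky, dense microvasculature of tumors; benign lesions
#' sit in between.
#'
#' @param shape Volume shape (X, Y, Z), default `c(64, 64, 16)`.
#' @param timepoints Acquisition times in seconds.
#' @param tau Injection duration, seconds.
#' @param body List `center`, `radii` of the body ellipsoid (voxels).
#' @param lesions List of lesions, each `list(center, radii, class)`
#'   with class `"malignant"` or `"benign"`.
#' @param kinetics Named list of `(A_amp, k_ep, k_el)` per tissue class.
#' @param baseline Pre-contrast signal level inside the body.
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   the baseline signal.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param motion_amplitude In-plane motion shift amplitude in voxels
#'   (0 disables the artifact).
#' @param reader2_error List `radius` (morphological perturbation
#'   radius) and `miss_prob` (per-lesion miss probability) for the
#'   simulated second reader.
#' @param voxel_spacing Voxel size in mm.
#' @param seed Integer seed driving every random component.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L),
                         timepoints = seq(0, 600, by = 120),
                         tau = 7,
                         body = list(center = c(32.5, 32.5, 8.5),
                                     radii = c(26, 26, 7)),
                         lesions = list(
                           list(center = c(24, 24, 8), radii = c(5, 5, 2),
                                class = "malignant"),
                           list(center = c(42, 40, 9), radii = c(4, 4, 2),
                                class = "benign")),
                         kinetics = list(
                           normal = c(A_amp = 0.2, k_ep = 0.2, k_el = 0.01),
                           benign = c(A_amp = 1.0, k_ep = 0.4, k_el = 0.02),
                           malignant = c(A_amp = 2.0, k_ep = 1.2, k_el = 0.05)),
                         baseline = 100,
                         noise_sd = 0.02,
                         noise_model = c("gaussian", "rician"),
                         motion_amplitude = 0,
                         reader2_error = list(radius = 1L, miss_prob = 0.2),
                         voxel_spacing = c(5, 5, 2.5),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (timepoints[1L] != 0) stop("timepoints must start at 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  for (l in lesions)
    if (!l$class %in% c("malignant", "benign"))
      stop("lesion class must be 'malignant' or 'benign'")
  structure(list(shape = as.integer(shape), timepoints = timepoints,
                 tau = tau, body = body, lesions = lesions,
                 kinetics = kinetics, baseline = baseline,
                 noise_sd = noise_sd, noise_model = noise_model,
                 motion_amplitude = motion_amplitude,
                 reader2_error = reader2_error,
                 voxel_spacing = voxel_spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic DCE-MRI phantom
#'
#' Builds the 4D intensity series from the two-compartment forward model
#' (see [brix_enhancement()]): inside the body every voxel follows
#' \eqn{S(t) = S_0 (1 + E(t))} with the kinetics of its tissue class,
#' air is zero, and i.i.d. noise of standard deviation
#' `noise_sd * baseline` is added to every voxel (clamped at 0). With
#' `motion_amplitude > 0`, a random rigid in-plane shift is applied to a
#' subset of frames. Fully deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `dce_phantom` object: `series` ([dce_series()]),
#'   `truth_mask` (malignant voxels), `benign_mask`, `body_mask`
#'   (geometric truth), `class_map` (0 air, 1 normal, 2 benign,
#'   3 malignant) and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  body <- ellipsoid_mask(shp, spec$body$center, spec$body$radii)
  class_map <- array(0L, shp)
  class_map[body] <- 1L
  truth <- benign <- array(FALSE, shp)
  for (l in spec$lesions) {
    m <- ellipsoid_mask(shp, l$center, l$radii)
    if (any(m & !body))
      stop("lesion extends outside the body ellipsoid")
    if (l$class == "malignant") { truth <- truth | m; class_map[m] <- 3L }
    else { benign <- benign | m; class_map[m] <- 2L }
  }
  if (any(truth & benign)) stop("malignant and benign lesions overlap")
  nt <- length(spec$timepoints)
  curves <- vapply(c("normal", "benign", "malignant"), function(cl) {
    k <- spec$kinetics[[cl]]
    brix_enhancement(spec$timepoints, k[["A_amp"]], k[["k_ep"]],
                     k[["k_el"]], spec$tau)
  }, numeric(nt))
  intens <- array(0, c(shp, nt))
  s0 <- spec$baseline
  for (ti in seq_len(nt)) {
    vol <- array(0, shp)
    for (ci in 1:3)
      vol[class_map == ci] <- s0 * (1 + curves[ti, ci])
    intens[, , , ti] <- vol
  }
  if (spec$noise_sd > 0) {
    sd_abs <- spec$noise_sd * s0
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(length(intens), 0, sd_abs),
                             dim(intens)))
    if (spec$noise_model == "rician") {
      im <- with_seed(spec$seed + 1L,
                      array(stats::rnorm(length(intens), 0, sd_abs),
                            dim(intens)))
      intens <- sqrt((intens + noise)^2 + im^2)
    } else {
      intens <- intens + noise
      intens[intens < 0] <- 0
    }
  }
  series <- dce_series(intens, spec$timepoints, spec$tau,
                       spec$voxel_spacing)
  if (spec$motion_amplitude > 0)
    series <- add_motion_artifact(series, spec$motion_amplitude,
                                  seed = spec$seed + 2L)
  structure(list(series = series, truth_mask = truth,
                 benign_mask = benign, body_mask = body,
                 class_map = class_map, spec = spec),
            class = "dce_phantom")
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat(sprintf("<dce_phantom> %s, %d time points; body %d voxels, malignant %d, benign %d\n",
              paste(x$spec$shape, collapse = " x "),
              length(x$spec$timepoints), sum(x$body_mask),
              sum(x$truth_mask), sum(x$benign_mask)))
  invisible(x)
}

#' Simulate a second reader's segmentation
#'
#' Perturbs the ground-truth malignancy mask the way an independent
#' radiologist might disagree with the primary reader: each
#' 26-connected lesion component is independently missed with
#' probability `miss_prob`, and surviving components are randomly either
#' eroded or dilated by `radius` voxels.
#'
#' @param truth_mask Non-empty 3D logical array.
#' @param reader2_error List with `radius` and `miss_prob`.
#' @param seed Integer seed.
#' @return 3D logical mask.
#' @export
simulate_second_reader <- function(truth_mask,
                                   reader2_error = list(radius = 1L,
                                                        miss_prob = 0.2),
                                   seed = 1L) {
  stop_if_not_mask(truth_mask, "truth_mask")
  if (!any(truth_mask)) stop("'truth_mask' is empty")
  lab <- label_components(truth_mask)
  ncomp <- max(lab)
  out <- array(FALSE, dim(truth_mask))
  with_seed(seed, {
    miss <- stats::runif(ncomp) < reader2_error$miss_prob
    grow <- stats::runif(ncomp) < 0.5
  })
  for (c in seq_len(ncomp)) {
    if (miss[c]) next
    m <- lab == c
    r <- reader2_error$radius
    if (r > 0) m <- if (grow[c]) dilate3(m, r) else erode3(m, r)
    out <- out | m
  }
  out
}

#' Add an edge motion artifact to a series
#'
#' Applies a small random rigid in-plane (x, y) integer shift to a
#' random subset of post-baseline frames, emulating patient motion that
#' concentrates frame-to-frame intensity differences at the body edge.
#' `amplitude = 0` returns the series unchanged.
#'
#' @param series A [dce_series()].
#' @param amplitude Maximum shift in voxels (>= 0).
#' @param seed Integer seed.
#' @return The perturbed `dce_series`.
#' @export
add_motion_artifact <- function(series, amplitude, seed = 1L) {
  stopifnot(inherits(series, "dce_series"))
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (amplitude == 0) return(series)
  nt <- dim(series$intensities)[4L]
  with_seed(seed, {
    affected <- which(stats::runif(nt - 1L) < 0.5) + 1L
    if (!length(affected)) affected <- 1L + sample.int(nt - 1L, 1L)
    shifts <- matrix(sample(seq(-amplitude, amplitude), 2L * length(affected),
                            replace = TRUE), ncol = 2L)
  })
  for (i in seq_along(affected)) {
    off <- c(shifts[i, ], 0L)
    if (all(off == 0L)) next
    fr <- array(series$intensities[, , , affected[i]],
                dim(series$intensities)[1:3])
    series$intensities[, , , affected[i]] <- shift3(fr, off, fill = 0)
  }
  series
}
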