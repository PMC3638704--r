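#' Construct a DCE-MRI series object
#'
#' Bundles a 4D intensity volume with its acquisition time vector and the
#' contrast bolus injection duration. The first time point is the
#' pre-contrast baseline (t = 0); typical breast protocols acquire one
#' baseline plus five post-contrast volumes 120 s apart.
#'
#' @param intensities 4D numeric array (x, y, z, t), non-negative.
#' @param timepoints Seconds since injection start; strictly increasing,
#'   starting at 0, length >= 3 and equal to the time extent of
#'   `intensities`.
#' @param tau Bolus injection duration in seconds (default 7).
#' @param voxel_spacing Voxel edge lengths in mm per axis.
#' @return A `dce_series` object (list with the validated fields).
#' @examples
#' s <- dce_series(array(100, c(4, 4, 2, 6)), seq(0, 600, by = 120))
#' dim(s$intensities)
#' @export
dce_series <- function(intensities, timepoints, tau = 7,
                       voxel_spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 4L)
    stop("'intensities' must be a 4D array (x, y, z, t)")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3L || any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing with length >= 3")
  if (timepoints[1L] != 0)
    stop("first time point must be the t = 0 baseline")
  if (length(timepoints) != dim(intensities)[4L])
    stop("length(timepoints) must equal the time extent of 'intensities'")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a positive scalar (seconds)")
  structure(list(intensities = intensities, timepoints = timepoints,
                 tau = tau, voxel_spacing = voxel_spacing),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<dce_series> %d x %d x %d volume, %d time points (0-%g s), tau = %g s\n",
              d[1L], d[2L], d[3L], d[4L], max(x$timepoints), x$tau))
  invisible(x)
}

# h(k, t) = (exp(k * min(t, tau)) - 1) / k * exp(-k t), the uptake kernel
# of a constant-rate infusion of duration tau. Times in minutes, k in
# 1/min; expm1 keeps the small-k regime accurate, k = 0 uses the limit
# min(t, tau).
.brix_h <- function(k, t, tau) {
  m <- pmin(t, tau)
  if (k == 0) m else expm1(k * m) / k * exp(-k * t)
}

# d/dk of .brix_h, used for the k_ep -> k_el degenerate limit.
.brix_h_prime <- function(k, t, tau) {
  m <- pmin(t, tau)
  if (k == 0) return(m^2 / 2 - t * m)
  g <- expm1(k * m) / k
  gp <- (m * exp(k * m) * k - expm1(k * m)) / k^2
  exp(-k * t) * gp - t * .brix_h(k, t, tau)
}

#' Two-compartment (Brix-type) relative enhancement curve
#'
#' Forward model for the relative signal enhancement of a voxel after a
#' constant-rate contrast bolus of duration `tau`:
#' \deqn{E(t) = \frac{A}{\tau'} \, k_{ep} \,
#'   \frac{h(k_{el}, t) - h(k_{ep}, t)}{k_{ep} - k_{el}},\qquad
#'   h(k, t) = \frac{e^{k \min(t,\tau')} - 1}{k} e^{-k t},}
#' with \eqn{\tau'} the injection duration in minutes. `A` is a
#' dimensionless amplitude, `k_ep` the compartment back-transfer rate and
#' `k_el` the plasma elimination rate (both 1/min). The analytic limits
#' are substituted when a rate is 0 or when |k_ep - k_el| < 1e-6/min, so
#' the curve is continuous in all arguments and E(0) = 0.
#'
#' @param t Time(s) since injection start, seconds (vectorized).
#' @param A_amp Dimensionless model amplitude, >= 0 for physical curves.
#' @param k_ep Back-transfer rate, 1/min, >= 0.
#' @param k_el Elimination rate, 1/min, >= 0.
#' @param tau Injection duration, seconds, > 0.
#' @return Relative enhancement E(t), same length as `t`.
#' @examples
#' brix_enhancement(c(0, 120, 600), A_amp = 2, k_ep = 0.8, k_el = 0.05)
#' @export
brix_enhancement <- function(t, A_amp, k_ep, k_el, tau = 7) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (k_ep < 0 || k_el < 0) stop("rates must be non-negative")
  if (tau <= 0) stop("'tau' must be positive")
  tm <- t / 60
  taum <- tau / 60
  eps <- 1e-6
  if (abs(k_ep - k_el) < eps) {
    k <- (k_ep + k_el) / 2
    return(-(A_amp / taum) * k * .brix_h_prime(k, tm, taum))
  }
  (A_amp / taum) * k_ep *
    (.brix_h(k_el, tm, taum) - .brix_h(k_ep, tm, taum)) / (k_ep - k_el)
}

#' Default fit bounds and initialization grid
#'
#' Box constraints for the voxelwise curve fit and the multi-start grid
#' of rate initializations. The bounds cover the physiological range of
#' breast DCE enhancement; the grid spans slow to fast wash-out so the
#' bounded least-squares fit does not get trapped in a local minimum.
#'
#' @return `pk_fit_bounds()`: list with `A_amp`, `k_ep`, `k_el` ranges.
#'   `pk_init_grid()`: data.frame of (k_ep, k_el) starting values, 1/min.
#' @export
pk_fit_bounds <- function() {
  list(A_amp = c(0, 50), k_ep = c(0, 10), k_el = c(0, 2))
}

#' @rdname pk_fit_bounds
#' @export
pk_init_grid <- function() {
  expand.grid(k_ep = c(0.1, 0.5, 2.0), k_el = c(0.01, 0.1, 0.5))
}

# Fast unchecked model evaluation against precomputed time vectors
# (tm = t in minutes, m = pmin(tm, taum)); used only inside the fitter.
.brix_E_fast <- function(A, kep, kel, tm, m, taum) {
  if (abs(kep - kel) < 1e-6) {
    k <- (kep + kel) / 2
    if (k == 0) return(tm * 0)
    g <- expm1(k * m) / k
    gp <- (m * exp(k * m) * k - expm1(k * m)) / k^2
    f <- g * exp(-k * tm)
    return(-(A / taum) * k * (exp(-k * tm) * gp - tm * f))
  }
  he <- if (kel == 0) m else expm1(kel * m) / kel * exp(-kel * tm)
  hp <- if (kep == 0) m else expm1(kep * m) / kep * exp(-kep * tm)
  (A / taum) * kep * (he - hp) / (kep - kel)
}

# Precompute the unit-amplitude model curves at the acquisition times for
# every start in the initialization grid (amplitude screening), plus the
# time grids used to locate the curve peak.
.pk_prepare <- function(timepoints, tau, init_grid) {
  gm <- t(vapply(seq_len(nrow(init_grid)), function(i) {
    brix_enhancement(timepoints, 1, init_grid$k_ep[i], init_grid$k_el[i], tau)
  }, numeric(length(timepoints))))
  tmax <- max(timepoints)
  taum <- tau / 60
  t_coarse <- seq(0, tmax, length.out = 121L)
  prep <- list(gm = gm, g2 = rowSums(gm^2), init_grid = init_grid,
               tm = timepoints / 60, m = pmin(timepoints / 60, taum),
               taum = taum, tmax = tmax,
               tc = t_coarse / 60, mc = pmin(t_coarse / 60, taum),
               step_coarse = tmax / 120)
  prep
}

# Curve peak by coarse grid + local refinement at <= 1 s resolution (the
# infusion curve is unimodal in time).
.pk_peak <- function(A, kep, kel, prep) {
  ec <- .brix_E_fast(A, kep, kel, prep$tc, prep$mc, prep$taum)
  i <- which.max(ec)
  lo <- max(0, (i - 2L) * prep$step_coarse)
  hi <- min(prep$tmax, i * prep$step_coarse)
  tf <- seq(lo, hi, by = min(1, (hi - lo) / 20)) / 60
  max(0, max(.brix_E_fast(A, kep, kel, tf, pmin(tf, prep$taum), prep$taum)))
}

.pk_empty_fit <- function(rss = 0) {
  structure(list(A_amp = 0, k_ep = 0, k_el = 0, k_pe = NA_real_,
                 k_in = NA_real_, A_peak = 0, rss = rss,
                 converged = FALSE),
            class = "pk_fit")
}

# Core fit on a relative-enhancement vector. The model is linear in the
# amplitude, so each grid start is screened with the amplitude profiled
# out analytically; the best `n_refine` starts are polished with bounded
# Levenberg-Marquardt.
.pk_fit_core <- function(e_obs, timepoints, tau, bounds, prep, n_refine = 3L) {
  gm <- prep$gm; g2 <- prep$g2
  a_star <- as.vector(gm %*% e_obs) / ifelse(g2 > 0, g2, Inf)
  a_star <- pmin(bounds$A_amp[2L], pmax(bounds$A_amp[1L], a_star))
  rss0 <- vapply(seq_len(nrow(gm)), function(i)
    sum((a_star[i] * gm[i, ] - e_obs)^2), numeric(1L))
  ord <- order(rss0)[seq_len(min(n_refine, length(rss0)))]
  tm <- prep$tm; m <- prep$m; taum <- prep$taum
  resid_fn <- function(p) .brix_E_fast(p[1L], p[2L], p[3L], tm, m, taum) - e_obs
  lower <- c(bounds$A_amp[1L], bounds$k_ep[1L], bounds$k_el[1L])
  upper <- c(bounds$A_amp[2L], bounds$k_ep[2L], bounds$k_el[2L])
  best <- NULL; best_rss <- Inf; conv <- FALSE
  for (i in ord) {
    start <- c(max(a_star[i], 1e-3), prep$init_grid$k_ep[i], prep$init_grid$k_el[i])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_rss) {
      best_rss <- rss; best <- fit$par
      conv <- fit$info %in% 1:4
    }
  }
  if (is.null(best)) {
    i <- ord[1L]
    best <- c(a_star[i], prep$init_grid$k_ep[i], prep$init_grid$k_el[i])
    best_rss <- rss0[i]; conv <- FALSE
  }
  # the infusion model is invariant under (A, k_ep, k_el) ->
  # (A k_ep / k_el, k_el, k_ep); report the canonical branch k_ep >= k_el
  # (back-transfer faster than elimination)
  if (best[3L] > best[2L] && best[2L] > 0 && best[3L] <= upper[2L] &&
      best[2L] <= upper[3L]) {
    best <- c(best[1L] * best[2L] / best[3L], best[3L], best[2L])
  }
  a_peak <- if (best[1L] == 0) 0 else .pk_peak(best[1L], best[2L], best[3L], prep)
  structure(list(A_amp = best[1L], k_ep = best[2L], k_el = best[3L],
                 k_pe = NA_real_, k_in = NA_real_, A_peak = a_peak,
                 rss = best_rss, converged = conv),
            class = "pk_fit")
}

#' Fit the two-compartment model to one voxel's time-intensity curve
#'
#' Converts the raw signal to relative enhancement
#' \eqn{(S(t) - S(0)) / S(0)} and estimates (A, k_ep, k_el) by bounded
#' nonlinear least squares with a multi-start initialization grid. The
#' reported peak enhancement `A_peak` is the maximum of the fitted curve
#' over a fine (<= 1 s step) time grid spanning the acquisition window.
#' Because the infusion model is invariant under exchanging the two
#' rates (with the amplitude rescaled), estimates are reported on the
#' canonical branch `k_ep >= k_el`.
#'
#' @param timepoints Acquisition times in seconds, first entry 0.
#' @param intensities Signal values at `timepoints`; the baseline
#'   `intensities[1]` must be positive for the voxel to be fittable.
#' @param tau Injection duration in seconds.
#' @param bounds Box constraints as from [pk_fit_bounds()].
#' @param init_grid Multi-start (k_ep, k_el) grid as from [pk_init_grid()].
#' @param n_refine Number of screened starts polished with
#'   Levenberg-Marquardt (the remaining starts are evaluated with the
#'   amplitude profiled out analytically).
#' @return A `pk_fit` object: `A_amp`, `k_ep`, `k_el` (1/min), `A_peak`,
#'   residual sum of squares `rss`, and a `converged` flag. A voxel with
#'   non-positive baseline is flagged unfittable (all parameters 0,
#'   `converged = FALSE`).
#' @examples
#' t <- seq(0, 600, by = 120)
#' s <- 100 * (1 + brix_enhancement(t, 2, 0.8, 0.05))
#' fit_voxel_curve(t, s)
#' @export
fit_voxel_curve <- function(timepoints, intensities, tau = 7,
                            bounds = pk_fit_bounds(),
                            init_grid = pk_init_grid(), n_refine = 3L) {
  timepoints <- as.numeric(timepoints)
  if (length(intensities) != length(timepoints))
    stop("'intensities' and 'timepoints' lengths differ")
  if (length(timepoints) < 4L)
    stop("need the baseline plus at least 3 post-baseline samples")
  s0 <- intensities[1L]
  if (!is.finite(s0) || s0 <= 0) return(.pk_empty_fit())
  e_obs <- (intensities - s0) / s0
  prep <- .pk_prepare(timepoints, tau, init_grid)
  .pk_fit_core(e_obs, timepoints, tau, bounds, prep, n_refine)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> A_amp = %.4g, k_ep = %.4g /min, k_el = %.4g /min\n",
              x$A_amp, x$k_ep, x$k_el))
  cat(sprintf("  A_peak = %.4g, rss = %.3g, converged = %s\n",
              x$A_peak, x$rss, x$converged))
  invisible(x)
}

#' Voxelwise model fitting over a masked volume
#'
#' Applies [fit_voxel_curve()] to every voxel inside `body_mask` and
#' assembles the three pharmacokinetic parameter pseudoimages. The A
#' pseudoimage stores the fitted-curve peak enhancement (`A_peak`).
#' Voxels outside the mask are 0 in every output volume. The computation
#' is deterministic given the series, mask, bounds and grid.
#'
#' @param series A [dce_series()].
#' @param body_mask 3D logical array matching the spatial shape of the
#'   series; if `NULL` it is derived from the baseline volume with
#'   [compute_body_mask()].
#' @inheritParams fit_voxel_curve
#' @return A `pk_pseudoimages` object: volumes `A`, `k_ep`, `k_el`, the
#'   `body_mask`, `fit_quality` (residual sum of squares) and a logical
#'   `converged` volume.
#' @export
fit_volume <- function(series, body_mask = NULL, bounds = pk_fit_bounds(),
                       init_grid = pk_init_grid(), n_refine = 3L) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$intensities)
  sp <- d[1:3]
  if (is.null(body_mask))
    body_mask <- compute_body_mask(array(series$intensities[, , , 1L], sp))
  stop_if_not_mask(body_mask, "body_mask")
  if (!identical(dim(body_mask), sp))
    stop("'body_mask' shape does not match the series spatial shape")
  A <- kep <- kel <- rssv <- array(0, sp)
  conv <- array(FALSE, sp)
  vox <- which(body_mask)
  if (length(vox)) {
    prep <- .pk_prepare(series$timepoints, series$tau, init_grid)
    nt <- d[4L]
    nsp <- prod(sp)
    for (v in vox) {
      s <- series$intensities[v + (seq_len(nt) - 1L) * nsp]
      s0 <- s[1L]
      if (!is.finite(s0) || s0 <= 0) next
      f <- .pk_fit_core((s - s0) / s0, series$timepoints, series$tau,
                        bounds, prep, n_refine)
      A[v] <- f$A_peak; kep[v] <- f$k_ep; kel[v] <- f$k_el
      rssv[v] <- f$rss; conv[v] <- f$converged
    }
  }
  structure(list(A = A, k_ep = kep, k_el = kel, body_mask = body_mask,
                 fit_quality = rssv, converged = conv),
            class = "pk_pseudoimages")
}

#' @export
print.pk_pseudoimages <- function(x, ...) {
  n <- sum(x$body_mask)
  cat(sprintf("<pk_pseudoimages> %s volume, %d voxels fitted (%.1f%% converged)\n",
              paste(dim(x$A), collapse = " x "), n,
              if (n) 100 * sum(x$converged) / n else 0))
  if (n)
    cat(sprintf("  in-mask medians: A = %.3g, k_ep = %.3g /min, k_el = %.3g /min\n",
                stats::median(x$A[x$body_mask]),
                stats::median(x$k_ep[x$body_mask]),
                stats::median(x$k_el[x$body_mask])))
  invisible(x)
}

#' Segment body tissue from the baseline volume
#'
#' Otsu's threshold on the pre-contrast intensities followed by one
#' morphological closing (radius-1 ball) to fill small holes. A constant
#' volume yields an all-false mask with a warning.
#'
#' @param baseline_volume 3D non-negative numeric array.
#' @return 3D logical mask.
#' @export
compute_body_mask <- function(baseline_volume) {
  if (length(dim(baseline_volume)) != 3L)
    stop("'baseline_volume' must be a 3D array")
  if (any(baseline_volume < 0)) stop("baseline must be non-negative")
  thr <- otsu_threshold(baseline_volume)
  if (is.na(thr)) {
    warning("constant baseline volume; returning an all-false mask")
    return(array(FALSE, dim(baseline_volume)))
  }
  close3(baseline_volume > thr, 1L)
}
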