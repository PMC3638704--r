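#' Texture analysis configuration
#'
#' Settings for the scanning-volume-of-interest (SVOI) co-occurrence
#' analysis. The default 5 x 5 x 2 window keeps the short axis
#' through-plane; pair distance is the chessboard d = 1 along the three
#' principal directions; parameter values are quantized to G = 16 gray
#' levels.
#'
#' @param svoi_shape Integer (M, N, L) window shape; L must not exceed M
#'   or N.
#' @param distance Chessboard pair distance d >= 1.
#' @param directions List of integer unit offsets.
#' @param levels Gray-level count G >= 2.
#' @param statistics Ordered statistic names; defaults to the ten
#'   co-occurrence statistics used by the pipeline.
#' @return A `texture_config` list.
#' @export
texture_config <- function(svoi_shape = c(5L, 5L, 2L), distance = 1L,
                           directions = list(c(1L, 0L, 0L), c(0L, 1L, 0L),
                                             c(0L, 0L, 1L)),
                           levels = 16L,
                           statistics = haralick_statistic_names()) {
  svoi_shape <- as.integer(svoi_shape)
  if (length(svoi_shape) != 3L || any(svoi_shape < 1L))
    stop("'svoi_shape' must be three positive integers")
  if (svoi_shape[3L] > svoi_shape[1L] || svoi_shape[3L] > svoi_shape[2L])
    stop("the through-plane extent L must not exceed the in-plane extents")
  if (distance < 1L) stop("'distance' must be >= 1")
  if (levels < 2L) stop("'levels' must be >= 2")
  for (dir in directions) {
    if (length(dir) != 3L || sum(abs(dir)) == 0L)
      stop("each direction must be a nonzero integer 3-offset")
    if (any(abs(dir) * distance >= svoi_shape))
      stop("direction offset times distance must fit inside the SVOI")
  }
  bad <- setdiff(statistics, haralick_statistic_names())
  if (length(bad)) stop("unknown statistics: ", paste(bad, collapse = ", "))
  structure(list(svoi_shape = svoi_shape, distance = as.integer(distance),
                 directions = directions, levels = as.integer(levels),
                 statistics = statistics),
            class = "texture_config")
}

#' @rdname texture_config
#' @export
haralick_statistic_names <- function() {
  c("angular_second_moment", "correlation", "contrast",
    "inverse_difference_moment", "variance", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "difference_variance")
}

.dir_code <- function(dir) paste0(ifelse(dir < 0, "m", ""), abs(dir), collapse = "")

#' Quantize a parameter volume to gray levels
#'
#' Linear binning of the in-mask values between their 1st and 99th
#' percentiles into `levels` bins (clipping outside that span), so a few
#' extreme fit values cannot compress the dynamic range of the
#' co-occurrence analysis. Voxels outside the mask get level 1.
#'
#' @param param_volume 3D numeric array.
#' @param body_mask 3D logical array, non-empty.
#' @param levels Number of gray levels G >= 2.
#' @return Integer array of the same shape with values in 1..G.
#' @export
quantize_volume <- function(param_volume, body_mask, levels = 16L) {
  stop_if_not_mask(body_mask, "body_mask")
  if (!identical(dim(param_volume), dim(body_mask)))
    stop("volume and mask shapes differ")
  if (!any(body_mask)) stop("'body_mask' is empty")
  if (levels < 2L) stop("'levels' must be >= 2")
  v <- param_volume[body_mask]
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  out <- array(1L, dim(param_volume))
  if (q[2L] <= q[1L]) {
    warning("constant in-mask volume; all voxels assigned level 1")
    return(out)
  }
  lv <- 1L + as.integer(floor((param_volume[body_mask] - q[1L]) /
                                (q[2L] - q[1L]) * levels))
  out[body_mask] <- pmin(as.integer(levels), pmax(1L, lv))
  out
}

#' Gray-level co-occurrence matrix of a 3D window
#'
#' Tallies ordered gray-level pairs (v[x], v[x + d * theta]) over every
#' in-window position, symmetrizes by also counting the reversed pair,
#' and normalizes to relative frequencies P(a, b) summing to 1.
#'
#' @param window 3D integer array with values in 1..G.
#' @param direction Integer unit offset (e.g. `c(1, 0, 0)`).
#' @param d Pair distance (voxels) along the direction.
#' @param G Number of gray levels.
#' @return A `cooc_matrix` object: the G x G matrix `P`, the `direction`,
#'   `d`, and `pair_count` (ordered pairs tallied, i.e. twice the number
#'   of forward pairs).
#' @examples
#' w <- array(rep(1:2, length.out = 50), c(5, 5, 2))
#' cooccurrence_matrix(w, c(1, 0, 0), 1, 2)$P[1:2, 1:2]
#' @export
cooccurrence_matrix <- function(window, direction, d = 1L, G) {
  if (length(dim(window)) != 3L) stop("'window' must be a 3D array")
  if (any(window < 1L) || any(window > G))
    stop("window values must lie in 1..G")
  off <- as.integer(direction) * as.integer(d)
  dw <- dim(window)
  lo <- pmax(1L, 1L - off)
  hi <- pmin(dw, dw - off)
  if (any(hi < lo)) stop("no valid voxel pair for this offset")
  a <- window[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  b <- window[(lo[1L] + off[1L]):(hi[1L] + off[1L]),
              (lo[2L] + off[2L]):(hi[2L] + off[2L]),
              (lo[3L] + off[3L]):(hi[3L] + off[3L]), drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) + (as.vector(b) - 1L) * G, G * G), G, G)
  sym <- counts + t(counts)
  structure(list(P = sym / sum(sym), direction = as.integer(direction),
                 d = as.integer(d), pair_count = sum(sym)),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> G = %d, direction (%s), d = %d, %d pairs\n",
              nrow(x$P), paste(x$direction, collapse = ","), x$d,
              x$pair_count))
  invisible(x)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Computes the ten co-occurrence statistics used by the classifier, in
#' this order: angular second moment, correlation, contrast, inverse
#' difference moment, variance, sum average, sum variance, sum entropy,
#' entropy, difference variance. Entropies are in bits (log base 2) with
#' the 0 log 0 = 0 convention; correlation of a zero-variance matrix is
#' defined as 0; sum variance is taken about the sum average (the
#' accepted correction of the original formula). Difference entropy and
#' the information/maximal correlation measures are deliberately not
#' part of the set.
#'
#' @param P A `cooc_matrix` or a normalized symmetric matrix.
#' @return Named numeric vector of length 10.
#' @export
haralick_stats <- function(P) {
  if (inherits(P, "cooc_matrix")) P <- P$P
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("'P' must be square")
  if (abs(sum(P) - 1) > 1e-8) stop("'P' must be normalized to sum 1")
  if (max(abs(P - t(P))) > 1e-10) stop("'P' must be symmetric")
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)                      # == colSums(P) by symmetry
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  psum <- vapply(2:(2 * G), function(n) sum(P[i + j == n]), numeric(1L))
  pdiff <- vapply(0:(G - 1L), function(n) sum(P[abs(i - j) == n]), numeric(1L))
  nsum <- 2:(2 * G)
  ndiff <- 0:(G - 1L)
  xlog2 <- function(p) { r <- p * log2(p); r[p == 0] <- 0; r }
  sa <- sum(nsum * psum)
  da <- sum(ndiff * pdiff)
  corr <- if (sig2 < 1e-12) 0 else (sum(i * j * P) - mu^2) / sig2
  c(angular_second_moment = sum(P^2),
    correlation = corr,
    contrast = sum(ndiff^2 * pdiff),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    variance = sum((i - mu)^2 * P),
    sum_average = sa,
    sum_variance = sum((nsum - sa)^2 * psum),
    sum_entropy = -sum(xlog2(psum)),
    entropy = -sum(xlog2(P)),
    difference_variance = sum((ndiff - da)^2 * pdiff))[haralick_statistic_names()]
}

# Centroid offset (0-based) of a window axis: middle voxel for odd
# lengths, the lower of the two middle voxels for even lengths.
.centroid_offset <- function(len) {
  ifelse(len %% 2L == 0L, len %/% 2L - 1L, (len - 1L) %/% 2L)
}

# Vectorized sliding-window engine for one direction. Returns a matrix
# (anchor positions x statistics). Window anchors are the lowest-corner
# voxel of each fully-contained SVOI, enumerated in column-major order.
.sliding_stats_one_dir <- function(qvol, svoi, dir, d, G, statistics) {
  dv <- dim(qvol)
  off <- dir * d
  aoff <- abs(off)
  # forward-pair code volume: code = a + (b - 1) * G at each position
  # whose partner lies inside the volume
  lo <- pmax(1L, 1L - off); hi <- pmin(dv, dv - off)
  a <- qvol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  b <- qvol[(lo[1L] + off[1L]):(hi[1L] + off[1L]),
            (lo[2L] + off[2L]):(hi[2L] + off[2L]),
            (lo[3L] + off[3L]):(hi[3L] + off[3L]), drop = FALSE]
  code <- a + (b - 1L) * G
  dim(code) <- dim(a)
  # a window anchored (lowest corner) at `p` contains the forward pairs
  # whose lower-coordinate voxel spans a box of shape svoi - |off|
  wbox <- svoi - aoff
  nanch <- dim(qvol) - svoi + 1L
  npos <- prod(nanch)
  counts <- matrix(0, npos, G * G)
  for (k in seq_len(G * G)) {
    ind <- array(as.numeric(code == k), dim(code))
    bs <- box_sum3(ind, wbox)
    # anchors in the code volume start at max(1, 1 + off) relative to the
    # full volume; both give the same valid anchor count
    counts[, k] <- as.vector(bs[seq_len(nanch[1L]), seq_len(nanch[2L]),
                                seq_len(nanch[3L]), drop = FALSE])
  }
  # symmetrize: add the transposed-code counts
  ij <- cbind(i = rep(seq_len(G), times = G), j = rep(seq_len(G), each = G))
  perm <- ij[, "j"] + (ij[, "i"] - 1L) * G
  counts <- counts + counts[, perm, drop = FALSE]
  tot <- rowSums(counts)
  P <- counts / tot
  iv <- ij[, "i"]; jv <- ij[, "j"]
  xlog2 <- function(p) { r <- p * log2(p); r[p == 0] <- 0; r }
  mu <- as.vector(P %*% iv)
  Ei2 <- as.vector(P %*% iv^2)
  sig2 <- Ei2 - mu^2
  Eij <- as.vector(P %*% (iv * jv))
  contrast <- as.vector(P %*% (iv - jv)^2)
  sa <- as.vector(P %*% (iv + jv))
  Es2 <- as.vector(P %*% (iv + jv)^2)
  da <- as.vector(P %*% abs(iv - jv))
  # sum marginal needed for sum entropy
  nsum <- 2:(2 * G)
  Msum <- outer(iv + jv, nsum, "==") * 1
  psum <- P %*% Msum
  out <- cbind(
    angular_second_moment = rowSums(P^2),
    correlation = ifelse(sig2 < 1e-12, 0, (Eij - mu^2) / sig2),
    contrast = contrast,
    inverse_difference_moment = as.vector(P %*% (1 / (1 + (iv - jv)^2))),
    variance = sig2,
    sum_average = sa,
    sum_variance = Es2 - sa^2,
    sum_entropy = -rowSums(xlog2(psum)),
    entropy = -rowSums(xlog2(P)),
    difference_variance = contrast - da^2)
  out[, statistics, drop = FALSE]
}

#' Sliding-window texture pseudoimages for one parameter volume
#'
#' Raster-scans the SVOI through the quantized volume; wherever the full
#' window fits, one co-occurrence matrix per direction is computed and
#' the statistics are assigned to the window centroid (for the even
#' through-plane extent, the lower of the two central slices). Border
#' voxels the window cannot cover are 0 and flagged false in the
#' validity mask.
#'
#' @param quantized_volume Integer 3D array with values in 1..G.
#' @param config A [texture_config()].
#' @return A `texture_maps` object: named list `maps` of 3D volumes (one
#'   per statistic x direction), `validity_mask`, `manifest` data frame
#'   and the `config`.
#' @export
sliding_texture_maps <- function(quantized_volume, config = texture_config()) {
  dv <- dim(quantized_volume)
  if (length(dv) != 3L) stop("'quantized_volume' must be a 3D array")
  svoi <- config$svoi_shape
  if (any(dv < svoi)) stop("volume is smaller than the SVOI")
  G <- config$levels
  nanch <- dv - svoi + 1L
  coff <- vapply(svoi, .centroid_offset, integer(1L))
  cx <- seq_len(nanch[1L]) + coff[1L]
  cy <- seq_len(nanch[2L]) + coff[2L]
  cz <- seq_len(nanch[3L]) + coff[3L]
  cidx <- as.vector(outer(outer(cx, (cy - 1L) * dv[1L], "+"),
                          (cz - 1L) * dv[1L] * dv[2L], "+"))
  validity <- array(FALSE, dv)
  validity[cidx] <- TRUE
  maps <- list()
  manifest <- NULL
  for (dir in config$directions) {
    stats_mat <- .sliding_stats_one_dir(quantized_volume, svoi, dir,
                                        config$distance, G,
                                        config$statistics)
    dc <- .dir_code(dir)
    for (s in config$statistics) {
      vol <- array(0, dv)
      vol[cidx] <- stats_mat[, s]
      key <- paste(s, dc, sep = ".")
      maps[[key]] <- vol
      manifest <- rbind(manifest,
                        data.frame(statistic = s, direction = dc,
                                   key = key, stringsAsFactors = FALSE))
    }
  }
  structure(list(maps = maps, validity_mask = validity,
                 manifest = manifest, config = config),
            class = "texture_maps")
}

#' Full texture stage over the three parameter pseudoimages
#'
#' Quantizes each pharmacokinetic parameter volume (A, k_ep, k_el) and
#' concatenates its sliding-window texture maps; with the default
#' configuration this yields 90 feature volumes (3 parameters x 10
#' statistics x 3 directions).
#'
#' @param pseudo A `pk_pseudoimages` object from [fit_volume()] (or any
#'   list with `A`, `k_ep`, `k_el` volumes and a `body_mask`).
#' @param config A [texture_config()].
#' @return A `texture_maps` object whose manifest gains a `parameter`
#'   column; map keys are `parameter.statistic.direction`.
#' @export
texture_stage <- function(pseudo, config = texture_config()) {
  for (p in c("A", "k_ep", "k_el"))
    if (is.null(pseudo[[p]])) stop("missing parameter volume: ", p)
  maps <- list()
  manifest <- NULL
  validity <- NULL
  for (p in c("A", "k_ep", "k_el")) {
    q <- quantize_volume(pseudo[[p]], pseudo$body_mask, config$levels)
    tm <- sliding_texture_maps(q, config)
    validity <- tm$validity_mask
    for (k in names(tm$maps)) maps[[paste(p, k, sep = ".")]] <- tm$maps[[k]]
    mf <- tm$manifest
    mf$parameter <- p
    mf$key <- paste(p, mf$key, sep = ".")
    manifest <- rbind(manifest, mf[, c("parameter", "statistic",
                                       "direction", "key")])
  }
  structure(list(maps = maps, validity_mask = validity,
                 manifest = manifest, config = config),
            class = "texture_maps")
}

#' @export
print.texture_maps <- function(x, ...) {
  cat(sprintf("<texture_maps> %d feature volumes (%s), %d valid voxels\n",
              length(x$maps),
              paste(dim(x$validity_mask), collapse = " x "),
              sum(x$validity_mask)))
  invisible(x)
}

#' Extract the per-voxel feature matrix from texture maps
#'
#' @param tex A `texture_maps` object.
#' @param voxels Linear voxel indices (1-based, column-major); defaults
#'   to every valid voxel.
#' @return Numeric matrix, one row per voxel, one column per feature
#'   volume (column names are the map keys).
#' @export
texture_feature_matrix <- function(tex, voxels = which(tex$validity_mask)) {
  m <- vapply(tex$maps, function(v) v[voxels], numeric(length(voxels)))
  if (length(voxels) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(tex$maps)))
  m
}
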