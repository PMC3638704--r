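# Internal array helpers shared across the pipeline stages.

# Sliding box sum over a 3D array. Returns an array of dimension
# dim(a) - w + 1 whose element [i,j,k] is sum(a[i:(i+w1-1), j:(j+w2-1),
# k:(k+w3-1)]). Implemented as a cumulative sum + lagged difference per
# axis so cost is linear in the array size, independent of window size.
box_sum3 <- function(a, w) {
  stopifnot(length(dim(a)) == 3L, length(w) == 3L)
  w <- as.integer(w)
  if (any(w < 1L) || any(w > dim(a)))
    stop("window does not fit inside the array")
  for (ax in 1:3) {
    d <- dim(a)
    if (w[ax] == 1L) next
    p <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, p)
    dm <- dim(m)
    dim(m) <- c(dm[1L], prod(dm[-1L]))
    for (i in 2:dm[1L]) m[i, ] <- m[i, ] + m[i - 1L, ]
    nr <- dm[1L]; ww <- w[ax]
    res <- m[ww:nr, , drop = FALSE]
    if (ww < nr)
      res[2:(nr - ww + 1L), ] <- res[2:(nr - ww + 1L), , drop = FALSE] -
        m[1:(nr - ww), , drop = FALSE]
    dim(res) <- c(nr - ww + 1L, dm[-1L])
    a <- aperm(res, order(p))
  }
  a
}

# Shift a 3D array by an integer offset, filling exposed voxels.
shift3 <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1L + o):d[ax]; src[[ax]] <- 1L:(d[ax] - o)
    } else {
      dst[[ax]] <- 1L:(d[ax] + o); src[[ax]] <- (1L - o):d[ax]
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Integer offsets inside a Euclidean ball of radius r (excluding origin
# for r = 0 the set is empty).
ball_offsets <- function(r) {
  if (r <= 0) return(matrix(integer(0), ncol = 3L))
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= r^2 & rowSums(abs(g)) > 0, , drop = FALSE]
}

dilate3 <- function(mask, r = 1L) {
  if (r <= 0) return(mask)
  out <- mask
  offs <- ball_offsets(r)
  for (i in seq_len(nrow(offs)))
    out <- out | shift3(mask, offs[i, ], fill = FALSE)
  out
}

# erosion treats voxels beyond the array boundary as background
erode3 <- function(mask, r = 1L) {
  if (r <= 0) return(mask)
  out <- mask
  offs <- ball_offsets(r)
  for (i in seq_len(nrow(offs)))
    out <- out & shift3(mask, offs[i, ], fill = FALSE)
  out
}

close3 <- function(mask, r = 1L) erode3(dilate3(mask, r), r)

# Otsu's histogram threshold: maximizes between-class variance over
# nbins equal-width bins. Returns a scalar threshold on the value scale.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  br[which.max(bcv) + 1L]
}

# Label 26-connected components of a 3D logical mask (flood fill).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  idx_all <- which(mask)
  nxt <- 0L
  arr_ind <- arrayInd(idx_all, d)
  rownames(arr_ind) <- NULL
  pos_of <- integer(prod(d))
  pos_of[idx_all] <- seq_along(idx_all)
  for (s in seq_along(idx_all)) {
    if (lab[idx_all[s]] != 0L) next
    nxt <- nxt + 1L
    queue <- idx_all[s]
    lab[queue] <- nxt
    while (length(queue)) {
      cur <- arrayInd(queue, d)
      nb <- NULL
      for (i in seq_len(nrow(offs))) {
        cand <- sweep(cur, 2L, offs[i, ], "+")
        ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
          cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
          cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
        if (!any(ok)) next
        lin <- cand[ok, 1L] + (cand[ok, 2L] - 1L) * d[1L] +
          (cand[ok, 3L] - 1L) * d[1L] * d[2L]
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) { lab[lin] <- nxt; nb <- c(nb, lin) }
      }
      queue <- unique(nb)
    }
  }
  lab
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards so library functions stay referentially
# transparent with respect to the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Solid ellipsoid membership on the voxel grid (1-based centers).
ellipsoid_mask <- function(shape, center, radii) {
  stopifnot(length(shape) == 3L, length(center) == 3L, length(radii) == 3L)
  ix <- ((seq_len(shape[1L]) - center[1L]) / radii[1L])^2
  iy <- ((seq_len(shape[2L]) - center[2L]) / radii[2L])^2
  iz <- ((seq_len(shape[3L]) - center[3L]) / radii[3L])^2
  array(outer(outer(ix, iy, "+"), iz, "+") <= 1, shape)
}

# Small rolling fingerprint of a character scalar (run provenance only).
fingerprint <- function(x) {
  v <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (c in v) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_if_not_mask <- function(m, name) {
  if (!is.logical(m) || length(dim(m)) != 3L)
    stop(sprintf("'%s' must be a 3D logical array", name))
}
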