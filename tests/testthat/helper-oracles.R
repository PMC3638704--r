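# Independent reference implementations used as oracles. These are
# deliberately naive (nested loops, literal textbook formulas) and share
# no code with the package internals.

oracle_glcm <- function(window, direction, d, G) {
  dm <- dim(window)
  off <- direction * d
  P <- matrix(0, G, G)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 >= 1 && x2 <= dm[1] && y2 >= 1 && y2 <= dm[2] &&
        z2 >= 1 && z2 <= dm[3]) {
      a <- window[x, y, z]; b <- window[x2, y2, z2]
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

oracle_haralick <- function(P) {
  G <- nrow(P)
  px <- numeric(G)
  for (i in 1:G) for (j in 1:G) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:G) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:G) sig2 <- sig2 + (i - mu)^2 * px[i]
  asm <- ent <- con <- idm <- varr <- eij <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    if (p > 0) ent <- ent - p * log2(p)
    con <- con + 0          # contrast accumulated from the diff marginal
    idm <- idm + p / (1 + (i - j)^2)
    varr <- varr + (i - mu)^2 * p
    eij <- eij + i * j * p
  }
  psum <- numeric(2 * G)
  pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (n in 2:(2 * G)) sa <- sa + n * psum[n]
  sv <- 0; for (n in 2:(2 * G)) sv <- sv + (n - sa)^2 * psum[n]
  se <- 0; for (n in 2:(2 * G)) if (psum[n] > 0) se <- se - psum[n] * log2(psum[n])
  contrast <- 0; for (n in 0:(G - 1)) contrast <- contrast + n^2 * pdiff[n + 1]
  da <- 0; for (n in 0:(G - 1)) da <- da + n * pdiff[n + 1]
  dv <- 0; for (n in 0:(G - 1)) dv <- dv + (n - da)^2 * pdiff[n + 1]
  corr <- if (sig2 < 1e-12) 0 else (eij - mu^2) / sig2
  c(angular_second_moment = asm, correlation = corr, contrast = contrast,
    inverse_difference_moment = idm, variance = varr, sum_average = sa,
    sum_variance = sv, sum_entropy = se, entropy = ent,
    difference_variance = dv)
}

random_window <- function(seed, G = 8L, shape = c(5L, 5L, 2L)) {
  set.seed(seed)
  array(sample.int(G, prod(shape), replace = TRUE), shape)
}

random_sym_P <- function(seed, G = 8L) {
  set.seed(seed)
  M <- matrix(runif(G * G), G, G)
  M <- M + t(M)
  M / sum(M)
}

# small phantom settings that keep unit tests fast
small_spec <- function(...,
                       lesions = list(list(center = c(9, 9, 4),
                                           radii = c(3, 3, 2),
                                           class = "malignant"),
                                      list(center = c(17, 15, 5),
                                           radii = c(2.5, 2.5, 1.5),
                                           class = "benign"))) {
  phantom_spec(shape = c(24L, 24L, 8L),
               body = list(center = c(12.5, 12.5, 4.5),
                           radii = c(10, 10, 3.5)),
               lesions = lesions, ...)
}
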