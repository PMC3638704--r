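test_that("quantization maps the in-mask range onto 1..G", {
  mask <- array(TRUE, c(10, 10, 4))
  set.seed(2)
  vol <- array(runif(400), dim(mask))
  q <- quantize_volume(vol, mask, 16L)
  expect_true(all(q >= 1L & q <= 16L))
  expect_identical(q[which.min(vol)], 1L)
  expect_identical(q[which.max(vol)], 16L)

  expect_warning(qc <- quantize_volume(array(3, dim(mask)), mask, 16L),
                 "constant")
  expect_true(all(qc == 1L))
})

test_that("quantization matches an independent digitization oracle", {
  mask <- array(TRUE, c(8, 8, 4))
  set.seed(31)
  vol <- array(rnorm(256), dim(mask))
  G <- 4L
  q <- quantize_volume(vol, mask, G)
  qs <- quantile(vol, c(0.01, 0.99), names = FALSE)
  breaks <- seq(qs[1], qs[2], length.out = G + 1)
  oracle <- vapply(as.vector(vol), function(x) {
    lvl <- 1L
    for (b in breaks[2:G]) if (x >= b) lvl <- lvl + 1L
    lvl
  }, integer(1))
  expect_identical(as.vector(q), oracle)
  expect_identical(tabulate(q, G), tabulate(oracle, G))
})

test_that("co-occurrence matrices are symmetric, normalized and exact", {
  # constant window: single diagonal entry
  w <- array(3L, c(5, 5, 2))
  cm <- cooccurrence_matrix(w, c(1, 0, 0), 1, 8)
  expect_equal(cm$P[3, 3], 1)
  expect_equal(sum(cm$P), 1)

  # perfect alternation along x
  w <- array(0L, c(5, 5, 2))
  w[] <- rep(rep(1:2, length.out = 5), 10)
  cm <- cooccurrence_matrix(w, c(1, 0, 0), 1, 2)
  expect_equal(cm$P[1, 2], 0.5)
  expect_equal(cm$P[2, 1], 0.5)
  expect_equal(cm$P[1, 1] + cm$P[2, 2], 0)
  expect_identical(cm$pair_count, 80L)  # 2 x 4 x 5 x 2 ordered pairs

  # oracle equivalence on seeded random windows, all three directions
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (s in 1:20) {
    w <- random_window(s)
    for (dir in dirs) {
      P <- cooccurrence_matrix(w, dir, 1, 8)$P
      expect_lt(max(abs(P - oracle_glcm(w, dir, 1, 8))), 1e-12)
      expect_lt(max(abs(P - t(P))), 1e-15)
      expect_equal(sum(P), 1, tolerance = 1e-12)
    }
  }
  expect_error(cooccurrence_matrix(array(1L, c(2, 2, 1)), c(0, 0, 1), 1, 2),
               "no valid")
})

test_that("Haralick statistics match hand evaluation and a literal oracle", {
  # degenerate single-entry distribution
  P <- matrix(0, 8, 8); P[3, 3] <- 1
  h <- haralick_stats(P)
  expect_equal(h[["angular_second_moment"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["inverse_difference_moment"]], 1)
  expect_equal(h[["variance"]], 0)
  expect_equal(h[["correlation"]], 0)   # zero-variance convention

  # uniform distribution over levels {1, 2}: direct hand evaluation
  P <- matrix(0.25, 2, 2)
  h <- haralick_stats(P)
  expect_equal(h[["angular_second_moment"]], 0.25)
  expect_equal(h[["entropy"]], 2)
  expect_equal(h[["contrast"]], 0.5)
  expect_equal(h[["inverse_difference_moment"]], 0.75)
  expect_equal(h[["sum_average"]], 3)

  # literal-formula oracle on random symmetric normalized matrices
  for (s in 1:50) {
    P <- random_sym_P(s)
    expect_lt(max(abs(haralick_stats(P) - oracle_haralick(P))), 1e-10)
  }

  expect_error(haralick_stats(matrix(1, 4, 4)), "normalized")
})

test_that("statistic ranges hold on random windows", {
  G <- 8L
  for (s in 1:30) {
    P <- cooccurrence_matrix(random_window(s, G), c(1, 0, 0), 1, G)
    h <- haralick_stats(P)
    expect_true(h[["angular_second_moment"]] >= 0 &&
                  h[["angular_second_moment"]] <= 1)
    expect_true(h[["entropy"]] >= 0 && h[["entropy"]] <= 2 * log2(G))
    expect_true(h[["inverse_difference_moment"]] > 0 &&
                  h[["inverse_difference_moment"]] <= 1)
    expect_true(h[["contrast"]] >= 0 && h[["contrast"]] <= (G - 1)^2)
  }
})

test_that("sliding maps produce 30 volumes and match per-window recomputation", {
  set.seed(13)
  vol <- array(sample.int(16, 16 * 16 * 8, replace = TRUE), c(16, 16, 8))
  cfg <- texture_config()
  tm <- sliding_texture_maps(vol, cfg)
  expect_length(tm$maps, 30L)
  expect_true(all(vapply(tm$maps, function(m) identical(dim(m), dim(vol)),
                         logical(1))))
  # values outside the validity mask are zero
  for (m in tm$maps) expect_true(all(m[!tm$validity_mask] == 0))

  # spot-check interior voxels against direct per-window recomputation
  set.seed(14)
  valid <- which(tm$validity_mask)
  coff <- c(2L, 2L, 0L)
  for (v in sample(valid, 5)) {
    cc <- arrayInd(v, dim(vol))[1, ]
    anchor <- cc - coff
    win <- vol[anchor[1]:(anchor[1] + 4), anchor[2]:(anchor[2] + 4),
               anchor[3]:(anchor[3] + 1)]
    for (dir in cfg$directions) {
      h <- haralick_stats(cooccurrence_matrix(win, dir, 1, 16))
      dc <- paste0(dir, collapse = "")
      for (s in names(h))
        expect_equal(tm$maps[[paste(s, dc, sep = ".")]][v], h[[s]],
                     tolerance = 1e-10)
    }
  }
  expect_error(sliding_texture_maps(array(1L, c(4, 4, 1)), cfg), "smaller")
})

test_that("sliding engine equals the naive reference on many random windows", {
  # full-pipeline per-window agreement, exercised through a volume whose
  # every valid window is a fresh random draw
  set.seed(99)
  vol <- array(sample.int(8, 9 * 9 * 4, replace = TRUE), c(9, 9, 4))
  cfg <- texture_config(levels = 8L)
  tm <- sliding_texture_maps(vol, cfg)
  valid <- which(tm$validity_mask)
  expect_length(valid, 5 * 5 * 3)
  for (v in valid) {
    cc <- arrayInd(v, dim(vol))[1, ]
    anchor <- cc - c(2L, 2L, 0L)
    win <- vol[anchor[1]:(anchor[1] + 4), anchor[2]:(anchor[2] + 4),
               anchor[3]:(anchor[3] + 1)]
    for (dir in cfg$directions) {
      ref <- oracle_haralick(oracle_glcm(win, dir, 1, 8))
      dc <- paste0(dir, collapse = "")
      got <- vapply(names(ref), function(s)
        tm$maps[[paste(s, dc, sep = ".")]][v], numeric(1))
      expect_lt(max(abs(got - ref)), 1e-10)
    }
  }
})

test_that("constant volumes give ASM 1 and entropy 0 on the validity mask", {
  vol <- array(5L, c(8, 8, 4))
  tm <- sliding_texture_maps(vol, texture_config())
  v <- tm$validity_mask
  expect_true(all(tm$maps[["angular_second_moment.100"]][v] == 1))
  expect_true(all(tm$maps[["entropy.001"]][v] == 0))
})

test_that("texture maps translate with the input volume", {
  set.seed(17)
  vol <- array(sample.int(16, 14 * 14 * 6, replace = TRUE), c(14, 14, 6))
  shifted <- vol
  shifted[2:14, , ] <- vol[1:13, , ]
  tm1 <- sliding_texture_maps(vol, texture_config())
  tm2 <- sliding_texture_maps(shifted, texture_config())
  common1 <- tm1$maps[["entropy.100"]][3:10, , ]
  common2 <- tm2$maps[["entropy.100"]][4:11, , ]
  expect_equal(common1, common2, tolerance = 1e-12)
})

test_that("texture stage yields 90 maps (30 per direction-restricted run)", {
  set.seed(21)
  shp <- c(12, 12, 6)
  mask <- array(TRUE, shp)
  pseudo <- list(A = array(runif(prod(shp)), shp),
                 k_ep = array(runif(prod(shp)), shp),
                 k_el = array(runif(prod(shp)), shp),
                 body_mask = mask)
  tex <- texture_stage(pseudo, texture_config())
  expect_length(tex$maps, 90L)
  expect_identical(nrow(tex$manifest), 90L)
  one_dir <- texture_stage(pseudo,
                           texture_config(directions = list(c(1L, 0L, 0L))))
  expect_length(one_dir$maps, 30L)

  # permuting the parameter volumes only re-keys the maps
  swapped <- pseudo
  swapped$A <- pseudo$k_ep; swapped$k_ep <- pseudo$A
  tex2 <- texture_stage(swapped, texture_config())
  expect_equal(tex2$maps[["A.entropy.100"]], tex$maps[["k_ep.entropy.100"]])
  expect_equal(tex2$maps[["k_ep.contrast.010"]], tex$maps[["A.contrast.010"]])

  pseudo$k_el <- NULL
  expect_error(texture_stage(pseudo, texture_config()), "missing parameter")
})
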