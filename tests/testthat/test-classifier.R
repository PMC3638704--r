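# shared fixture: a small texture stage over random parameter volumes
local_tex_fixture <- function(shape = c(14L, 14L, 6L), seed = 42L) {
  set.seed(seed)
  mask <- array(TRUE, shape)
  pseudo <- list(A = array(runif(prod(shape)), shape),
                 k_ep = array(runif(prod(shape)), shape),
                 k_el = array(runif(prod(shape)), shape),
                 body_mask = mask)
  tex <- texture_stage(pseudo, texture_config())
  lesion <- array(FALSE, shape)
  lesion[4:8, 4:8, 3:4] <- TRUE
  list(tex = tex, lesion = lesion, body = mask)
}

test_that("training/verification sets are balanced, disjoint, reproducible", {
  fx <- local_tex_fixture()
  sets <- build_training_and_verification_sets(fx$lesion, fx$body,
                                               fx$tex$validity_mask,
                                               fx$tex, seed = 7L)
  tr <- sets$training; ve <- sets$verification
  # disjoint and unique coordinates
  expect_length(intersect(tr$coords, ve$coords), 0L)
  expect_false(anyDuplicated(tr$coords) > 0)
  # balanced within each set and equal-sized overall (within 1)
  expect_lte(abs(sum(tr$labels == 1) - sum(tr$labels == 0)), 1L)
  expect_lte(abs(sum(ve$labels == 1) - sum(ve$labels == 0)), 1L)
  expect_lte(abs(length(tr$coords) - length(ve$coords)), 1L)
  # every coordinate is inside the evaluable region
  elig <- fx$body & fx$tex$validity_mask
  expect_true(all(elig[c(tr$coords, ve$coords)]))
  # lesion sample size: ceiling(L / 2) lesion voxels in total
  L <- sum(fx$lesion & elig)
  expect_identical(sum(tr$labels == 1) + sum(ve$labels == 1),
                   as.integer(ceiling(L / 2)))

  # determinism per seed, divergence across seeds
  sets2 <- build_training_and_verification_sets(fx$lesion, fx$body,
                                                fx$tex$validity_mask,
                                                fx$tex, seed = 7L)
  expect_identical(sort(sets2$training$coords), sort(tr$coords))
  sets3 <- build_training_and_verification_sets(fx$lesion, fx$body,
                                                fx$tex$validity_mask,
                                                fx$tex, seed = 8L)
  expect_false(setequal(sets3$training$coords, tr$coords))

  empty <- array(FALSE, dim(fx$lesion))
  expect_error(build_training_and_verification_sets(empty, fx$body,
                                                    fx$tex$validity_mask,
                                                    fx$tex), "empty")
})

# helper: balanced voxel_set around two Gaussian clouds in feature space
separable_sets <- function(n = 120L, p = 10L, sep = 4, seed = 5L,
                           shuffle_labels = FALSE) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p, -sep / 2), n / 2, p),
             matrix(rnorm(n / 2 * p, +sep / 2), n / 2, p))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(c(0L, 1L), each = n / 2)
  if (shuffle_labels) y <- sample(y)
  idx <- sample(n)
  half <- idx[seq_len(n / 2)]
  mk <- function(i) structure(list(coords = i, features = X[i, , drop = FALSE],
                                   labels = y[i], seed = seed),
                              class = "voxel_set")
  list(training = mk(half), verification = mk(setdiff(idx, half)))
}

test_that("the network separates well-separated clouds perfectly", {
  ss <- separable_sets()
  model <- train_nn(ss$training, ss$verification, nn_config(seed = 2L))
  expect_lt(min(model$history$train_mse), 0.05)
  pred <- predict(model, ss$verification) >= 0.5
  expect_identical(as.integer(pred), ss$verification$labels)
})

test_that("shuffled labels leave no learnable signal", {
  ss <- separable_sets(shuffle_labels = TRUE, seed = 9L)
  model <- train_nn(ss$training, ss$verification, nn_config(seed = 2L))
  expect_gte(min(model$history$verification_mse), 0.2)
})

test_that("training is deterministic for a fixed seed", {
  ss <- separable_sets()
  m1 <- train_nn(ss$training, ss$verification, nn_config(seed = 3L))
  m2 <- train_nn(ss$training, ss$verification, nn_config(seed = 3L))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(predict(m1, ss$verification),
                   predict(m2, ss$verification))
})

test_that("non-finite features are reported by name", {
  ss <- separable_sets()
  ss$training$features[3, 4] <- NaN
  expect_error(train_nn(ss$training, ss$verification), "f4")
})

test_that("the forward pass matches the affine closed form and clips", {
  # hand-built model: zero weights, output bias 0.5 -> every score 0.5
  p <- 3L; h <- 2L
  model <- structure(list(W1 = matrix(0, p, h), b1 = numeric(h),
                          w2 = matrix(0, h, 1), b2 = 0.5,
                          feature_names = paste0("f", 1:p), kept = 1:p,
                          scaler = list(mean = rep(0, p), sd = rep(1, p))),
                     class = "dce_nn")
  X <- matrix(rnorm(30), 10, p, dimnames = list(NULL, paste0("f", 1:p)))
  expect_identical(predict(model, X), rep(0.5, 10))
  # a linear unit in the tanh regime: w2 = 1, b2 = 0, tiny inputs
  model$W1[1, 1] <- 1e-4; model$w2[1, 1] <- 1
  model$b2 <- 0
  expect_equal(predict(model, X), pmin(1, pmax(0, tanh(X[, 1] * 1e-4))),
               tolerance = 1e-12)

  # clipping contract on extreme inputs
  model$W1[] <- 10; model$w2[] <- 10; model$b2 <- 0
  set.seed(1)
  Xbig <- matrix(rnorm(3e3, sd = 100), ncol = p)
  sc <- predict(model, Xbig)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict(model, Xbig[, 1:2]), "dimension mismatch")
})

test_that("thresholding uses >= semantics and yields nested masks", {
  sc <- array(c(0.38, 0.39, 0.40, 0.5, 0.7, 0.99), c(3, 2, 1))
  m <- threshold_scores(sc, 0.39)
  expect_identical(as.vector(m)[1:3], c(FALSE, TRUE, TRUE))
  expect_error(threshold_scores(sc, 1.2), "threshold")

  set.seed(4)
  scores <- array(runif(200), c(10, 10, 2))
  masks <- lapply(default_thresholds(), threshold_scores, scores = scores)
  expect_length(masks, 7L)
  for (k in 2:7) expect_true(all(masks[[k]] <= masks[[k - 1]]))
})

test_that("a saved model predicts identically after reloading", {
  ss <- separable_sets()
  m <- train_nn(ss$training, ss$verification, nn_config(hidden = 4L,
                                                        seed = 2L))
  f <- tempfile(fileext = ".json")
  save_nn_model(m, f)
  m2 <- load_nn_model(f)
  expect_equal(predict(m2, ss$verification), predict(m, ss$verification),
               tolerance = 1e-12)
  unlink(f)
})
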