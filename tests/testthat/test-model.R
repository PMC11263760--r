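test_that("forward pass matches the hand-unrolled oracle on tiny instances", {
  worst <- 0
  for (i in 1:50) {
    set.seed(1000 + i)
    V <- sample(2:3, 1); d <- sample(1:2, 1); Tt <- sample(1:4, 1)
    params <- imv_init(V, d, seed = 2000 + i)
    window <- matrix(rnorm(Tt * V), Tt, V)
    got <- imv_forward(params, window)
    want <- oracle_imv_forward(params, window)
    worst <- max(worst, abs(got$probability - want$probability),
                 max(abs(got$alpha - want$alpha)),
                 max(abs(got$beta - want$beta)))
  }
  expect_lt(worst, 1e-8)
})

test_that("attention weights are exactly normalized and collapse for T = 1", {
  for (i in 1:10) {
    set.seed(i)
    V <- sample(2:6, 1); Tt <- sample(2:10, 1)
    params <- imv_init(V, 3, seed = i)
    out <- imv_forward(params, matrix(rnorm(Tt * V), Tt, V))
    expect_lt(max(abs(rowSums(out$alpha) - 1)), 1e-6)
    expect_lt(abs(sum(out$beta) - 1), 1e-6)
    expect_gt(out$probability, 0)
    expect_lt(out$probability, 1)
  }
  p1 <- imv_init(3, 2, seed = 1)
  out1 <- imv_forward(p1, matrix(rnorm(3), 1, 3))
  expect_equal(unname(out1$alpha[, 1]), rep(1, 3))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(9)
  V <- 2; d <- 2; Tt <- 3; N <- 2
  params <- imv_init(V, d, seed = 31)
  x <- array(rnorm(N * Tt * V), c(N, Tt, V))
  y <- c(1, 0)
  w <- c(2, 1)
  lg <- akitrace:::imv_loss_grad(params, x, y, w)
  theta <- akitrace:::params_to_vector(params)
  gvec <- akitrace:::params_to_vector(lg$grad)
  eps <- 1e-5
  fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (akitrace:::imv_loss(akitrace:::vector_to_params(tp, params), x, y, w) -
       akitrace:::imv_loss(akitrace:::vector_to_params(tm, params), x, y, w)) /
      (2 * eps)
  }, numeric(1))
  informative <- abs(fd) > 1e-6
  rel <- abs(gvec - fd) / pmax(abs(fd), 1e-8)
  expect_lt(max(rel[informative]), 1e-4)
  expect_lt(max(abs(gvec - fd)), 1e-8)  # near-zero coordinates are exact too
})

test_that("batch prediction equals the single-window pass and is equivariant", {
  set.seed(12)
  V <- 4; Tt <- 6
  w <- make_planted_windows(30, V = V, Tt = Tt, k = 2, seed = 12)
  model <- structure(list(params = imv_init(V, 3, seed = 5),
                          variables = paste0("v", 1:V)),
                     class = "imv_model")
  pred <- predict(model, w)
  expect_true(all(pred$probabilities > 0 & pred$probabilities < 1))
  one <- imv_forward(model$params, w$data[7, , ])
  expect_equal(pred$probabilities[7], one$probability, tolerance = 1e-12)
  expect_equal(pred$beta[7, ], unname(one$beta), tolerance = 1e-12)
  perm <- sample(30)
  permuted <- w
  permuted$data <- w$data[perm, , , drop = FALSE]
  pred2 <- predict(model, permuted)
  expect_equal(pred2$probabilities, pred$probabilities[perm], tolerance = 1e-12)
  # variable-count mismatch is rejected
  bad <- array(0, c(2, Tt, V + 1))
  expect_error(predict(model, bad), "mismatch")
})

test_that("training is deterministic under a fixed seed", {
  w <- make_planted_windows(120, V = 3, Tt = 8, seed = 21)
  sp <- split_622(w, seed = 4)
  hy <- imv_hyperparams(d = 2, epochs = 5, patience = 5, seed = 13)
  m1 <- imv_train(sp$train, sp$validation, hy)
  m2 <- imv_train(sp$train, sp$validation, hy)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training separates planted signal and stays at chance on shuffled labels", {
  w <- make_planted_windows(400, seed = 31)
  sp <- split_622(w, seed = 6)
  hy <- imv_hyperparams(seed = 7, epochs = 80)
  m <- imv_train(sp$train, sp$validation, hy)
  pv <- predict(m, sp$validation)
  expect_gte(auroc(pv$probabilities, sp$validation$labels), 0.95)
  # validation loss of the returned model is the best epoch's
  expect_equal(min(m$history$val_loss), m$history$val_loss[m$best_epoch])
  # shuffled labels carry no signal
  set.seed(99)
  shuf <- w
  shuf$labels <- sample(shuf$labels)
  shuf$meta$label <- shuf$labels
  sps <- split_622(shuf, seed = 6)
  hy2 <- imv_hyperparams(seed = 8, epochs = 15, patience = 5)
  ms <- imv_train(sps$train, sps$validation, hy2)
  ps <- predict(ms, sps$validation)
  expect_lt(abs(auroc(ps$probabilities, sps$validation$labels) - 0.5), 0.1)
  # a single-class training set is rejected
  only1 <- sp$train
  only1$labels <- rep(1L, length(only1$labels))
  expect_error(imv_train(only1, sp$validation, hy), "both classes")
})

test_that("weights survive a JSON round trip", {
  w <- make_planted_windows(60, V = 3, Tt = 6, seed = 2)
  sp <- split_622(w, seed = 2)
  hy <- imv_hyperparams(d = 2, epochs = 3, patience = 3, seed = 3)
  m <- imv_train(sp$train, sp$validation, hy)
  path <- withr::local_tempfile(fileext = ".json")
  save_imv(m, path)
  m2 <- load_imv(path)
  p1 <- predict(m, sp$test)
  p2 <- predict(m2, sp$test)
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})
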