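test_that("the dot-product interaction map matches the double-loop oracle", {
  set.seed(21)
  for (i in 1:10) {
    Ed <- matrix(rnorm(4 * 2), 4, 2)
    Ep <- matrix(rnorm(3 * 2), 3, 2)
    expect_equal(interaction_map(Ed, Ep), oracle_interaction_map(Ed, Ep),
                 tolerance = 1e-12)
  }
  # orthogonal vectors give 0; identical vectors give the squared norm
  Ed <- rbind(c(1, 0), c(2, 3))
  Ep <- rbind(c(0, 1), c(2, 3))
  I <- interaction_map(Ed, Ep)
  expect_identical(I[1, 1], 0)
  expect_identical(I[2, 2], 13)
  expect_error(interaction_map(matrix(0, 2, 3), matrix(0, 2, 4)),
               "latent dimension")
})

test_that("sum and average interaction functions reduce the embedding pair", {
  Ed <- rbind(c(1, 2), c(0, -1))
  Ep <- rbind(c(3, 4))
  expect_equal(interaction_map(Ed, Ep, "sum"), rbind(10, 6))
  expect_equal(interaction_map(Ed, Ep, "average"), rbind(5, 3))
})

test_that("CNN aggregation equals direct-summation convolution with ReLU", {
  set.seed(31)
  for (i in 1:8) {
    I <- matrix(rnorm(25), 5, 5)
    K <- array(rnorm(27), c(3, 3, 3))
    b <- rnorm(3)
    expect_equal(aggregate_interaction(I, K, b), oracle_conv_relu(I, K, b),
                 tolerance = 1e-12)
  }
  # all-zero map with zero bias stays zero; identity kernel crops the map
  K0 <- array(0, c(3, 3, 1))
  expect_equal(aggregate_interaction(matrix(0, 5, 5), K0, 0),
               array(0, c(3, 3, 1)))
  Kid <- K0
  Kid[2, 2, 1] <- 1
  M <- matrix(abs(rnorm(25)) + 0.1, 5, 5)
  expect_equal(aggregate_interaction(M, Kid, 0)[, , 1], M[2:4, 2:4])
  # valid-convolution output arithmetic and the too-small error
  O <- aggregate_interaction(matrix(rnorm(24 * 48), 24, 48),
                             array(rnorm(27), c(3, 3, 3)), rnorm(3))
  expect_identical(dim(O), c(22L, 46L, 3L))
  expect_error(aggregate_interaction(matrix(0, 2, 2), K0, 0), "smaller")
})

test_that("the decoder is a logistic over the flattened features", {
  expect_identical(predict_probability(rnorm(4), rep(0, 4), 0), 0.5)
  expect_gt(predict_probability(rnorm(4), rep(0, 4), 30), 1 - 1e-12)
  # hand computation on a printed 4-vector
  O <- c(1, -2, 0.5, 3)
  w <- c(0.2, 0.1, -0.4, 0.05)
  expect_equal(predict_probability(O, w, 0.1),
               1 / (1 + exp(-(0.2 - 0.2 - 0.2 + 0.15 + 0.1))))
  expect_error(predict_probability(1:3, 1:4, 0), "expects 4")
})

test_that("binary cross-entropy matches closed forms and clamps at the edge", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -log(0.9))
  expect_warning(l <- bce_loss(c(1, 0), c(1, 0)), "clamped")
  expect_lt(l, 1e-6)
  expect_error(bce_loss(0.5, 2))
})

test_that("ablation variants share the computation up to their removed block", {
  # no_augembed with zero-layer full model: identical parameters, same output
  full0 <- tiny_model(seed = 6, variant = "full", n_layers = 0)
  noaug <- tiny_model(seed = 6, variant = "no_augembed", n_layers = 0)
  idx <- model_index_pair(full0, "CCON", "MKVAK")
  expect_equal(pair_forward(full0, idx$drug, idx$protein)$p,
               pair_forward(noaug, idx$drug, idx$protein)$p)

  # no_cnn feeds the flattened interaction map straight into the decoder
  nocnn <- tiny_model(seed = 6, variant = "no_cnn")
  expect_null(nocnn$params$cnn)
  fw <- pair_forward(nocnn, idx$drug, idx$protein)
  expect_identical(fw$cache$feat, as.numeric(fw$cache$I))
  expect_length(nocnn$params$dec$w,
                nocnn$config$max_len_drug * nocnn$config$max_len_protein)

  # every variant emits a probability strictly inside (0, 1)
  for (v in c("full", "no_cnn", "no_augembed", "no_interaction")) {
    m <- tiny_model(seed = 9, variant = v)
    p <- pair_forward(m, idx$drug, idx$protein)$p
    expect_true(p > 0 && p < 1)
  }
  expect_error(dti_model_config(variant = "bogus"))
})

test_that("backprop matches finite differences on every parameter group", {
  m <- tiny_model(seed = 3)
  idx <- model_index_pair(m, "CCON", "MKVAK")
  fw <- pair_forward(m, idx$drug, idx$protein)
  y <- 1
  g <- pair_backward(m, fw$cache, fw$p - y)
  loss_at <- function(params) {
    m$params <- params
    f <- pair_forward(m, idx$drug, idx$protein)
    -(y * log(f$p) + (1 - y) * log(1 - f$p))
  }
  h <- 1e-5
  flat_g <- params_flatten(g)
  set.seed(17)
  # sample entries with non-negligible analytic gradient across the whole
  # parameter vector and compare against central differences
  candidates <- which(abs(flat_g) > 1e-6)
  picks <- sample(candidates, 40)
  base <- params_flatten(m$params)
  rebuild <- function(flat) {
    # reshape a flat vector back into the params structure
    relist_params(flat, m$params)
  }
  for (i in picks) {
    up <- base; up[i] <- up[i] + h
    dn <- base; dn[i] <- dn[i] - h
    num <- (loss_at(rebuild(up)) - loss_at(rebuild(dn))) / (2 * h)
    expect_lt(abs(num - flat_g[i]) / max(abs(num), abs(flat_g[i])), 1e-3)
  }
})
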