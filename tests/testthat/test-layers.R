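test_that("conv1d_same: identity kernel, bias broadcast, loop oracle", {
  set.seed(11)
  X <- rmat(10, 4)
  # 1x1 identity convolution reproduces the input channels
  id <- array(0, c(1, 4, 4)); for (c in 1:4) id[1, c, c] <- 1
  expect_equal(conv1d_same(X, id, rep(0, 4)), X, tolerance = 1e-12)

  # all-zero input broadcasts the bias at every position
  k3 <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  out0 <- conv1d_same(matrix(0, 7, 4), k3, c(1.5, -2))
  expect_equal(out0, cbind(rep(1.5, 7), rep(-2, 7)), tolerance = 1e-12)

  for (r in 1:20) {
    k <- sample(c(3, 5, 7), 1)
    ker <- array(rnorm(k * 4 * 3), c(k, 4, 3))
    b <- rnorm(3)
    X <- rmat(10, 4)
    expect_equal(conv1d_same(X, ker, b), oracle_conv(X, ker, b), tolerance = 1e-6)
  }
  expect_error(conv1d_same(X, array(0, c(4, 4, 2))), "odd")
})

test_that("aa_conv_config enforces the d_conv + d_v = d_out accounting", {
  cfg <- aa_conv_config(d_out = 64, kernel_size = 7, n_heads = 8, input_channels = 4)
  expect_identical(cfg$d_v, 16L)       # d_out/4 rounded to a multiple of n_heads
  expect_identical(cfg$d_conv, 48L)
  expect_error(aa_conv_config(8, 3, 2, 4, d_v = 8), "channel accounting")
  expect_error(aa_conv_config(8, 3, 3, 4, d_v = 4), "multiple")
  expect_error(aa_conv_config(8, 4, 2, 4), "odd")
})

test_that("attention_augmented_conv concatenates [conv | attention]", {
  set.seed(12)
  cfg <- aa_conv_config(d_out = 6, kernel_size = 3, n_heads = 2, input_channels = 4, d_v = 2)
  pr <- random_branch_params(cfg)
  X <- rmat(8, 4)

  # zero conv weights: first d_conv channels 0 + bias, last d_v = MHA(X)
  zero <- pr
  zero$conv$kernels[] <- 0
  out <- attention_augmented_conv(X, cfg, zero$conv, zero$mha)
  expect_equal(out[, 1:4], matrix(0, 8, 4), tolerance = 1e-12)
  expect_equal(out[, 5:6], multi_head_attention(X, pr$mha), tolerance = 1e-12)

  # composition oracle
  expect_equal(attention_augmented_conv(X, cfg, pr$conv, pr$mha),
               cbind(oracle_conv(X, pr$conv$kernels, pr$conv$bias),
                     oracle_mha(X, pr$mha)),
               tolerance = 1e-6)

  # channel accounting violations are named
  bad <- random_mha_params(4, 2, 2, 2)   # emits 4 channels, config wants 2
  err <- expect_error(attention_augmented_conv(X, cfg, pr$conv, bad), "channel accounting")
  expect_match(conditionMessage(err), "d_out = 6")
})

test_that("cac_layer_forward: equal division, reduction to one branch, oracle", {
  cfg <- cac_layer_config(D = 192, input_channels = 4)
  expect_identical(vapply(cfg$branches, `[[`, integer(1), "d_out"), rep(64L, 3))
  expect_error(cac_layer_config(D = 10, input_channels = 4, i = 3), "divisible")

  set.seed(13)
  small <- cac_layer_config(D = 12, input_channels = 4, i = 3,
                            kernel_sizes = c(3, 5, 7), n_heads = 2, d_v = 2)
  pars <- lapply(small$branches, random_branch_params)
  prm <- lapply(pars, function(p) list(conv = p$conv, mha = p$mha))
  X <- rmat(9, 4)
  got <- cac_layer_forward(X, small, prm)
  # branch-by-branch oracle with explicit ReLU and concat
  want <- do.call(cbind, lapply(1:3, function(j) {
    pmax(cbind(oracle_conv(X, pars[[j]]$conv$kernels, pars[[j]]$conv$bias),
               oracle_mha(X, pars[[j]]$mha)), 0)
  }))
  expect_equal(got, want, tolerance = 1e-6)
  expect_identical(dim(got), c(9L, 12L))

  # i = 1 reduces to a single activated branch
  one <- cac_layer_config(D = 4, input_channels = 4, i = 1, kernel_sizes = 3,
                          n_heads = 1, d_v = 1)
  p1 <- random_branch_params(one$branches[[1]])
  expect_equal(cac_layer_forward(X, one, list(p1)),
               pmax(attention_augmented_conv(X, one$branches[[1]], p1$conv, p1$mha), 0))
})

test_that("max_pool follows the floor length formula", {
  expect_identical(nrow(max_pool(rmat(1000, 2))), 250L)
  x <- matrix(c(1, 3, 2, 0, 5, 5, 0, 1), 8, 1)
  expect_equal(max_pool(x), matrix(c(3, 5), 2, 1))
  expect_equal(max_pool(matrix(2, 9, 3)), matrix(2, 2, 3))   # constant input
  expect_error(max_pool(rmat(3, 2)), "shorter")
  # overlap-free stride keeps every window independent
  expect_equal(max_pool(matrix(1:10, 10, 1), pool_config(size = 3, stride = 2)),
               matrix(c(3, 5, 7, 9), 4, 1))
})

test_that("length is preserved through layers and changed only by pooling", {
  set.seed(14)
  small <- cac_layer_config(D = 6, input_channels = 4, i = 3,
                            kernel_sizes = c(3, 3, 5), n_heads = 1, d_v = 1)
  prm <- lapply(small$branches, random_branch_params)
  for (L in c(5L, 17L, 40L)) {
    out <- cac_layer_forward(rmat(L, 4), small, prm)
    expect_identical(nrow(out), L)
  }
})
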