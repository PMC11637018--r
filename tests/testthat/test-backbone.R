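test_that("forward output preserves spatial shape with num_classes channels", {
  set.seed(1)
  net <- build_network(tiny_network_spec())
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y <- net_forward(net, x)
  expect_equal(dim(y), c(16, 16, 8, 2))
  expect_true(all(is.finite(y)))
})

test_that("network depth is validated against the volume shape", {
  set.seed(1)
  net <- build_network(tiny_network_spec(levels = 4L))
  expect_error(net_forward(net, array(0, c(6, 6, 4))), "too deep")
})

test_that("ablation flags control which parameter groups exist", {
  set.seed(1)
  plain <- build_network(tiny_network_spec(use_residual = FALSE,
                                           use_cbam = FALSE))
  res <- build_network(tiny_network_spec(use_residual = TRUE,
                                         use_cbam = FALSE))
  full <- build_network(tiny_network_spec(use_residual = TRUE,
                                          use_cbam = TRUE))
  expect_false(any(c("cam", "sam", "proj") %in% param_group_names(plain)))
  expect_true("proj" %in% param_group_names(res))
  expect_false(any(c("cam", "sam") %in% param_group_names(res)))
  expect_true(all(c("cam", "sam", "proj") %in% param_group_names(full)))
  expect_lt(count_params(plain), count_params(res))
  expect_lt(count_params(res), count_params(full))
})

test_that("deterministic forwards repeat; dropout makes them stochastic", {
  set.seed(2)
  net <- build_network(tiny_network_spec(dropout_rate = 0.3,
                                         dropout_bottleneck = 0.5))
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y1 <- net_forward(net, x, dropout = FALSE)
  y2 <- net_forward(net, x, dropout = FALSE)
  expect_identical(y1, y2)
  set.seed(3)
  s1 <- net_forward(net, x, dropout = TRUE)
  s2 <- net_forward(net, x, dropout = TRUE)
  expect_gt(max(abs(s1 - s2)), 0)
})

test_that("identical specs built under the same seed are identical networks", {
  set.seed(9); n1 <- build_network(tiny_network_spec())
  set.seed(9); n2 <- build_network(tiny_network_spec())
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_identical(net_forward(n1, x), net_forward(n2, x))
})

test_that("channel attention weights lie in (0,1) and pooled branches agree on constants", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  r <- channel_attention(x, reduction = 3L)
  expect_true(all(r$weights > 0 & r$weights < 1))
  expect_equal(dim(r$output), dim(x))
  expect_error(channel_attention(x, reduction = 10L), "exceeds")
  # spatially constant features: max-pool and avg-pool descriptors coincide,
  # so each branch contributes the same pre-activation
  xc <- array(rep(c(1.5, -0.5, 2), each = 32), c(4, 4, 2, 3))
  rc <- channel_attention(xc, reduction = 3L, params = r$params)
  mlp <- function(v, p) {
    z1 <- pmax(drop(v %*% p$W1) + p$b1, 0)
    drop(z1 %*% p$W2) + p$b2
  }
  expected <- 1 / (1 + exp(-2 * mlp(c(1.5, -0.5, 2), r$params)))
  expect_equal(rc$weights, expected, tolerance = 1e-12)
})

test_that("channel attention matches a hand-computed bottleneck on fixed weights", {
  # 2 channels, 2x2x2 grid, hand-set parameters
  x <- array(0, c(2, 2, 2, 2))
  x[, , , 1] <- seq(0.1, 0.8, by = 0.1)
  x[, , , 2] <- seq(-0.4, 0.3, by = 0.1)
  params <- list(W1 = matrix(c(0.5, -0.25, 1, 0.75), 2, 2),
                 b1 = c(0.1, -0.2),
                 W2 = matrix(c(0.3, -0.6, 0.8, 0.2), 2, 2),
                 b2 = c(0.05, -0.05))
  r <- channel_attention(x, params = params)
  # independent arithmetic: descriptors -> shared MLP -> summed -> sigmoid
  vmax <- c(max(x[, , , 1]), max(x[, , , 2]))
  vavg <- c(mean(x[, , , 1]), mean(x[, , , 2]))
  mlp <- function(v) {
    z1 <- pmax(c(v %*% params$W1) + params$b1, 0)
    c(z1 %*% params$W2) + params$b2
  }
  s <- 1 / (1 + exp(-(mlp(vmax) + mlp(vavg))))
  expect_equal(r$weights, s, tolerance = 1e-12)
  expect_equal(r$output[, , , 1], x[, , , 1] * s[1], tolerance = 1e-12)
  expect_equal(r$output[, , , 2], x[, , , 2] * s[2], tolerance = 1e-12)
})

test_that("spatial attention yields a shape-preserving (0,1) weight map", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 4 * 3), c(6, 6, 4, 3))
  r <- spatial_attention(x, kernel = 3L)
  expect_equal(dim(r$weights), dim(x)[1:3])
  expect_true(all(r$weights > 0 & r$weights < 1))
  expect_equal(r$output, x * as.numeric(r$weights), tolerance = 1e-12)
  expect_error(spatial_attention(x, kernel = 4L), "odd")
})

test_that("spatial attention matches hand arithmetic on a constant input", {
  xc <- array(2, c(5, 5, 3, 1))
  params <- list(W = matrix(seq(-0.2, by = 0.01, length.out = 54), 54, 1),
                 b = 0.1, k = 3L)
  r <- spatial_attention(xc, kernel = 3L, params = params)
  # interior voxel: channel max and mean maps are both constant 2, so the
  # pre-activation is 2 * sum(all kernel weights) + bias
  pre <- 2 * sum(params$W) + params$b
  expect_equal(r$weights[3, 3, 2], 1 / (1 + exp(-pre)), tolerance = 1e-12)
})

test_that("CBAM applies channel attention strictly before spatial attention", {
  set.seed(6)
  spec <- tiny_network_spec(use_residual = TRUE, use_cbam = TRUE)
  net <- build_network(spec)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  p <- net$params$enc[[1]]
  b <- uamt3d:::block_fwd(x_to_4d <- array(x, c(8, 8, 4, 1)), p, spec)
  # recompute by hand: conv branch, then CAM, then SAM, then residual add
  h <- uamt3d:::lrelu_fwd(uamt3d:::instnorm_fwd(
    uamt3d:::conv3d_fwd(x_to_4d, p$conv1)$y, p$in1)$y)$y
  h <- uamt3d:::lrelu_fwd(uamt3d:::instnorm_fwd(
    uamt3d:::conv3d_fwd(h, p$conv2)$y, p$in2)$y)$y
  skip <- uamt3d:::conv3d_fwd(x_to_4d, p$proj)$y
  cam_then_sam <- uamt3d:::sam_fwd(uamt3d:::cam_fwd(h, p$cam)$y, p$sam)$y +
    skip
  sam_then_cam <- uamt3d:::cam_fwd(uamt3d:::sam_fwd(h, p$sam)$y, p$cam)$y +
    skip
  expect_equal(b$y, cam_then_sam, tolerance = 1e-12)
  expect_gt(max(abs(b$y - sam_then_cam)), 1e-8)
})

test_that("raw scores stay finite over many random inputs", {
  set.seed(7)
  net <- build_network(tiny_network_spec(levels = 1L))
  ok <- TRUE
  for (i in seq_len(1000)) {
    y <- net_forward(net, array(rnorm(6 * 6 * 4, sd = 3), c(6, 6, 4)))
    ok <- ok && all(is.finite(y))
  }
  expect_true(ok)
})

test_that("direct convolution kernels agree with the im2col + GEMM oracle", {
  set.seed(8)
  for (k in c(1L, 3L)) {
    d <- c(6L, 5L, 4L); cin <- 3L; cout <- 2L
    x <- array(rnorm(prod(d) * cin), c(d, cin))
    p <- uamt3d:::conv3d_init(cin, cout, k)
    fwd <- uamt3d:::conv3d_fwd(x, p)
    cols <- uamt3d:::im2col3d(as.numeric(x), d[1], d[2], d[3], cin, k)
    ref <- sweep(cols %*% p$W, 2, p$b, `+`)
    expect_equal(as.numeric(fwd$y), as.numeric(ref), tolerance = 1e-12)
    dy <- array(rnorm(prod(d) * cout), c(d, cout))
    bwd <- uamt3d:::conv3d_bwd(p, fwd$cache, dy)
    dym <- matrix(dy, prod(d), cout)
    expect_equal(bwd$grads$W, crossprod(cols, dym), tolerance = 1e-12,
                 ignore_attr = TRUE)
    dx_ref <- uamt3d:::col2im3d(tcrossprod(dym, p$W), d[1], d[2], d[3], cin, k)
    expect_equal(as.numeric(bwd$dx), as.numeric(dx_ref), tolerance = 1e-12)
  }
})

test_that("backpropagated parameter gradients match finite differences", {
  set.seed(42)
  spec <- tiny_network_spec(use_residual = TRUE, use_cbam = TRUE)
  net <- build_network(spec)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  fwd <- net_forward(net, x, with_cache = TRUE)
  g <- net_backward(net, fwd$cache, r)
  lossfn <- function(params) sum(net_forward(net, x, params = params) * r)
  probes <- list(
    list("enc", 1L, "conv1", "W"), list("enc", 1L, "in1", "gamma"),
    list("enc", 1L, "cam", "W1"), list("enc", 1L, "sam", "W"),
    list("enc", 1L, "proj", "W"), list("enc", 2L, "conv2", "b"),
    list("dec", 1L, "conv1", "W"), list("final", "W"))
  get_path <- function(x, pr) Reduce(`[[`, pr, x)
  set_path <- function(x, pr, v) {
    if (length(pr) == 1L) x[[pr[[1]]]] <- v
    else x[[pr[[1]]]] <- set_path(x[[pr[[1]]]], pr[-1], v)
    x
  }
  eps <- 1e-6
  for (pr in probes) {
    gv <- get_path(g, pr)
    idx <- sample(length(gv), 1)
    perturb <- function(delta) {
      v <- get_path(net$params, pr)
      v[idx] <- v[idx] + delta
      lossfn(set_path(net$params, pr, v))
    }
    fd <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    expect_equal(gv[idx], fd, tolerance = 1e-4)
  }
})
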