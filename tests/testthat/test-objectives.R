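test_that("supervised loss vanishes for confident correct predictions", {
  set.seed(1)
  lab <- random_mask(c(6, 6, 4), 0.3)
  logits <- array(0, c(6, 6, 4, 2))
  logits[, , , 1] <- ifelse(lab == 0, 20, -20)
  logits[, , , 2] <- ifelse(lab == 1, 20, -20)
  out <- supervised_loss(logits, lab)
  expect_lte(out$loss, 1e-2)
})

test_that("a uniform predictor pays exactly ln 2 cross-entropy", {
  lab <- random_mask(c(4, 4, 2), 0.5)
  logits <- array(0, c(4, 4, 2, 2))
  out <- supervised_loss(logits, lab)
  expect_equal(out$ce, log(2), tolerance = 1e-12)
})

test_that("labels outside the class range are rejected", {
  logits <- array(0, c(2, 2, 2, 2))
  expect_error(supervised_loss(logits, array(2L, c(2, 2, 2))), "labels")
  expect_error(supervised_loss(logits, array(0L, c(2, 2, 1))), "shape")
})

test_that("supervised loss equals a per-voxel brute-force computation", {
  set.seed(2)
  for (trial in 1:5) {
    d <- c(4, 4, 4)
    logits <- array(rnorm(prod(d) * 2), c(d, 2))
    lab <- random_mask(d, 0.4)
    smooth <- 1e-5
    out <- supervised_loss(logits, lab, smooth = smooth)
    # brute force: scalar loops over voxels
    ce_acc <- 0; num <- 0; den_p <- 0; den_y <- 0
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      z <- logits[i, j, k, ]
      p <- exp(z - max(z)); p <- p / sum(p)
      y <- lab[i, j, k]
      ce_acc <- ce_acc - log(p[y + 1])
      num <- num + p[2] * y
      den_p <- den_p + p[2]; den_y <- den_y + y
    }
    ce_ref <- ce_acc / prod(d)
    dice_ref <- 1 - (2 * num + smooth) / (den_p + den_y + smooth)
    expect_equal(out$ce, ce_ref, tolerance = 1e-10)
    expect_equal(out$dice_loss, dice_ref, tolerance = 1e-10)
    expect_equal(out$loss, 0.5 * (dice_ref + ce_ref), tolerance = 1e-10)
  }
})

test_that("supervised loss gradient matches finite differences", {
  set.seed(3)
  d <- c(3, 3, 2)
  logits <- array(rnorm(prod(d) * 2), c(d, 2))
  lab <- random_mask(d, 0.4)
  g <- supervised_loss(logits, lab, with_grad = TRUE)$dlogits
  eps <- 1e-6
  for (probe in sample(length(logits), 5)) {
    lp <- logits; lp[probe] <- lp[probe] + eps
    lm <- logits; lm[probe] <- lm[probe] - eps
    fd <- (supervised_loss(lp, lab)$loss - supervised_loss(lm, lab)$loss) /
      (2 * eps)
    expect_equal(g[probe], fd, tolerance = 1e-5)
  }
})

test_that("consistency loss is zero for identical predictions or empty masks", {
  set.seed(4)
  f <- random_prob_map(c(4, 4, 2))
  u <- array(runif(32, 0, log(2)), c(4, 4, 2))
  expect_equal(consistency_loss(f, f, u, 0.5)$loss, 0)
  g <- random_prob_map(c(4, 4, 2))
  expect_equal(consistency_loss(f, g, u, 0)$loss, 0)  # I = 0: guarded
})

test_that("consistency loss matches hand arithmetic on a 2x2x1 toy", {
  f <- array(c(0.9, 0.6, 0.3, 0.2,
               0.1, 0.4, 0.7, 0.8), c(2, 2, 1, 2))
  fp <- array(c(0.8, 0.5, 0.5, 0.1,
                0.2, 0.5, 0.5, 0.9), c(2, 2, 1, 2))
  u <- array(c(0.1, 0.7, 0.4, 0.6), c(2, 2, 1))
  # reliable voxels: u < 0.5 -> voxels 1 and 3
  # per-voxel squared error averaged over the two classes
  e1 <- ((0.9 - 0.8)^2 + (0.1 - 0.2)^2) / 2
  e3 <- ((0.3 - 0.5)^2 + (0.7 - 0.5)^2) / 2
  out <- consistency_loss(f, fp, u, 0.5)
  expect_equal(out$n_reliable, 2)
  expect_equal(out$loss, (e1 + e3) / 2, tolerance = 1e-12)
})

test_that("consistency loss is symmetric, bounded, and equals a brute-force masked mean", {
  set.seed(5)
  for (trial in 1:100) {
    d <- c(3, 2, 2)
    f <- random_prob_map(d); g <- random_prob_map(d)
    u <- array(runif(prod(d), 0, log(2)), d)
    th <- runif(1, 0, log(2))
    out <- consistency_loss(f, g, u, th)$loss
    expect_equal(out, consistency_loss(g, f, u, th)$loss, tolerance = 1e-12)
    expect_gte(out, 0); expect_lte(out, 1)
    H <- u < th
    if (sum(H) == 0) { expect_equal(out, 0); next }
    acc <- 0
    for (i in 1:3) for (j in 1:2) for (k in 1:2) {
      if (!H[i, j, k]) next
      acc <- acc + mean((f[i, j, k, ] - g[i, j, k, ])^2)
    }
    expect_equal(out, acc / sum(H), tolerance = 1e-12)
  }
})

test_that("consistency gradient matches finite differences", {
  set.seed(6)
  d <- c(3, 2, 2)
  f <- random_prob_map(d); g <- random_prob_map(d)
  u <- array(runif(prod(d), 0, log(2)), d)
  gr <- consistency_loss(f, g, u, 0.5, with_grad = TRUE)$dprobs
  eps <- 1e-7
  for (probe in sample(length(f), 5)) {
    fp <- f; fp[probe] <- fp[probe] + eps
    fm <- f; fm[probe] <- fm[probe] - eps
    fd <- (consistency_loss(fp, g, u, 0.5)$loss -
             consistency_loss(fm, g, u, 0.5)$loss) / (2 * eps)
    expect_equal(gr[probe], fd, tolerance = 1e-5)
  }
})

test_that("the consistency weight follows the Gaussian ramp", {
  cfg <- loss_config(lambda_max = 0.1, rampup_length = 100L)
  expect_equal(lambda_schedule(100, cfg), 0.1)
  expect_equal(lambda_schedule(1000, cfg), 0.1)            # plateau
  expect_equal(lambda_schedule(50, cfg), 0.1 * exp(-1.25)) # half-ramp
  expect_equal(lambda_schedule(0, cfg), 0.1 * exp(-5))
  cfg0 <- loss_config(lambda_max = 0, rampup_length = 10L)
  expect_equal(lambda_schedule(5, cfg0), 0)
})

test_that("the joint objective is monotone in the consistency term", {
  cfg <- loss_config(lambda_max = 0.2, rampup_length = 10L)
  expect_equal(joint_loss(1.5, 0.3, 20, cfg), 1.5 + 0.2 * 0.3)
  expect_equal(joint_loss(1.5, 0.3, 20, loss_config(lambda_max = 0)), 1.5)
  cons <- sort(runif(5))
  vals <- vapply(cons, function(co) joint_loss(1, co, 5, cfg), numeric(1))
  expect_true(all(diff(vals) >= 0))
})
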