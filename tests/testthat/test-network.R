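# naive nested-loop references for the compiled convolution kernels
naive_conv2d <- function(x, w, b, n) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(x)[3] / n; cout <- nrow(w)
  y <- array(0, c(H, W, cout * n))
  for (s in 1:n) for (oc in 1:cout) {
    out <- matrix(b[oc], H, W)
    for (cc in 1:cin) {
      xc <- x[, , (s - 1) * cin + cc]
      for (dy in -1:1) for (dx in -1:1) {
        wgt <- w[oc, (cc - 1) * 9 + (dy + 1) * 3 + dx + 2]
        for (j in 1:W) for (i in 1:H) {
          is <- i + dy; js <- j + dx
          if (is >= 1 && is <= H && js >= 1 && js <= W)
            out[i, j] <- out[i, j] + wgt * xc[is, js]
        }
      }
    }
    y[, , (s - 1) * cout + oc] <- out
  }
  y
}

naive_conv1d <- function(x, w, b, n) {
  L <- nrow(x); cin <- ncol(x) / n; cout <- nrow(w)
  y <- matrix(0, L, cout * n)
  for (s in 1:n) for (oc in 1:cout) {
    out <- rep(b[oc], L)
    for (cc in 1:cin) for (d in -1:1) {
      wgt <- w[oc, (cc - 1) * 3 + d + 2]
      for (p in 1:L) {
        ps <- p + d
        if (ps >= 1 && ps <= L)
          out[p] <- out[p] + wgt * x[ps, (s - 1) * cin + cc]
      }
    }
    y[, (s - 1) * cout + oc] <- out
  }
  y
}

tiny_cfg <- function() {
  network_config(image_side = 16L, ibranch_channels = c(2L, 3L, 2L, 2L),
                 obranch_channels = c(2L, 2L, 3L), dropout_zero_prob = 0)
}

test_that("compiled 2-D convolution matches the nested-loop reference", {
  set.seed(101)
  n <- 2L; cin <- 2L; cout <- 3L
  x <- array(rnorm(6 * 6 * cin * n), c(6, 6, cin * n))
  w <- matrix(rnorm(cout * cin * 9), cout)
  b <- rnorm(cout)
  expect_equal(retinafocus:::conv2d_fw(x, w, b, n),
               naive_conv2d(x, w, b, n), tolerance = 1e-12)
})

test_that("compiled 1-D convolution matches the nested-loop reference", {
  set.seed(102)
  n <- 3L; cin <- 2L; cout <- 4L
  x <- matrix(rnorm(10 * cin * n), 10)
  w <- matrix(rnorm(cout * cin * 3), cout)
  b <- rnorm(cout)
  expect_equal(retinafocus:::conv1d_fw(x, w, b, n),
               naive_conv1d(x, w, b, n), tolerance = 1e-12)
})

test_that("max pooling matches blockwise max and routes gradients to argmax", {
  set.seed(103)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  pl <- retinafocus:::maxpool2_fw(x)
  for (s in 1:2) for (i in 1:3) for (j in 1:3) {
    expect_equal(pl$y[i, j, s],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), s]))
  }
  g <- array(1, c(3, 3, 2))
  dx <- retinafocus:::maxpool2_bw(g, pl$idx, 6L, 6L)
  expect_equal(sum(dx), sum(g))               # gradient mass conserved
  for (s in 1:2) for (i in 1:3) for (j in 1:3) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), s]
    dbk <- dx[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), s]
    expect_equal(dbk[which.max(blk)], 1)
    expect_equal(sum(dbk), 1)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(fc_in = 179L), "invariant")
  expect_error(network_config(image_side = 100L), "divisible by 16")
  expect_error(network_config(dropout_zero_prob = 1), "dropout")
  expect_silent(check_config(network_config()))
  expect_error(check_config(tiny_cfg()), "expected 180")
})

test_that("probe shapes follow the halving schedule at any input side", {
  m <- build_model(network_config(), seed = 1)
  p64 <- probe_shapes(m, 64L)
  expect_equal(p64$height[1:4], c(32L, 16L, 8L, 4L))
  expect_equal(p64$channels[1:4], c(15L, 30L, 60L, 120L))
  expect_equal(p64$width[5:7], rep(50L, 3))
  expect_equal(p64$channels[p64$layer == "concat"], 180L)
  expect_equal(p64$channels[p64$layer == "output"], 5L)
})

test_that("concatenated feature length is independent of the image side", {
  m <- build_model(network_config(dropout_zero_prob = 0), seed = 2)
  det <- matrix(runif(50), 50, 1)
  for (side in c(32L, 64L)) {
    p <- nn_forward(m, array(runif(side * side), c(side, side, 1)), det)
    expect_equal(dim(p), c(5L, 1L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("forward pass validates its inputs", {
  m <- build_model(tiny_cfg(), seed = 3)
  img <- array(runif(16 * 16 * 2), c(16, 16, 2))
  det <- matrix(runif(100), 50, 2)
  expect_error(nn_forward(m, array(0, c(16, 24, 1)), det[, 1, drop = FALSE]),
               "differ")
  expect_error(nn_forward(m, array(0, c(24, 24, 1)), det[, 1, drop = FALSE]),
               "divisible by 16")
  expect_error(nn_forward(m, img, det[1:40, ]), "50 rows")
  expect_error(nn_forward(m, img, det[, 1, drop = FALSE]), "batch size")
})

test_that("all-zero parameters yield exactly 0.5 everywhere", {
  m <- build_model(tiny_cfg(), seed = 4)
  m$params <- lapply(m$params, function(l) list(w = l$w * 0, b = l$b * 0))
  p <- nn_forward(m, array(runif(16 * 16), c(16, 16, 1)), matrix(runif(50)))
  expect_equal(as.numeric(p), rep(0.5, 5))
})

test_that("initialization and inference are deterministic", {
  a <- build_model(tiny_cfg(), seed = 9)
  b <- build_model(tiny_cfg(), seed = 9)
  expect_identical(a$params, b$params)
  img <- array(runif(16 * 16), c(16, 16, 1))
  det <- matrix(runif(50))
  expect_identical(nn_forward(a, img, det), nn_forward(b, img, det))
  expect_false(identical(a$params, build_model(tiny_cfg(), seed = 10)$params))
})

test_that("backpropagation matches central finite differences", {
  set.seed(105)
  m <- build_model(tiny_cfg(), seed = 5)
  # move biases off zero: with all-zero biases, positions whose whole
  # receptive field is ReLU-dead sit exactly on the ReLU kink, where the
  # one-sided finite difference and the conventional subgradient disagree
  m$params <- lapply(m$params, function(l) {
    l$b <- rnorm(length(l$b), sd = 0.05)
    l
  })
  n <- 2L
  img <- array(runif(16 * 16 * n), c(16, 16, n))
  det <- matrix(runif(50 * n), 50, n)
  tgt <- matrix(rbinom(5 * n, 1, 0.5), 5, n)
  fw <- nn_forward(m, img, det, training = FALSE, keep_cache = TRUE)
  gr <- retinafocus:::nn_backward(m, fw$cache, tgt)
  loss_at <- function(mod) bce_loss(nn_forward(mod, img, det), tgt)
  h <- 1e-5
  for (nm in names(m$params)) {
    for (fld in c("w", "b")) {
      len <- length(m$params[[nm]][[fld]])
      for (k in sample(len, min(4L, len))) {
        mp <- m; mp$params[[nm]][[fld]][k] <- mp$params[[nm]][[fld]][k] + h
        mm <- m; mm$params[[nm]][[fld]][k] <- mm$params[[nm]][[fld]][k] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        expect_equal(gr[[nm]][[fld]][k], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("checkpoints round-trip through JSON near machine precision", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_cfg(), seed = 6)
  path <- file.path(dir, "ckpt.json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params, tolerance = 1e-14)
  img <- array(runif(16 * 16), c(16, 16, 1))
  det <- matrix(runif(50))
  expect_equal(nn_forward(m, img, det), nn_forward(m2, img, det),
               tolerance = 1e-12)
})
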