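#' Dual-branch network configuration
#'
#' The classifier has an image branch (i-branch) of four 3x3 / stride-1 /
#' padding-1 convolution blocks, each followed by a ReLU and a 2x2
#' stride-2 max pool, and an object branch (o-branch) of three kernel-3 /
#' stride-1 / padding-1 1-D convolution blocks with ReLU (their nominal
#' size-1 / stride-1 pools are identities and are implemented as
#' no-ops). Global average pooling reduces each branch to
#' one value per channel; the pooled vectors are concatenated (120 + 60 =
#' 180), passed through dropout and one fully connected layer, and squashed
#' by a logistic sigmoid into five per-slot primariness probabilities.
#'
#' Thanks to global average pooling the concatenated feature length is
#' independent of the input image's spatial size.
#'
#' @param image_side Nominal input side (default 256); the forward pass
#'   accepts any side with at least four pooling stages of headroom.
#' @param ibranch_channels Image-branch channel progression.
#' @param obranch_channels Object-branch channel progression.
#' @param dropout_zero_prob Dropout zero probability before the linear
#'   layer.
#' @param o_max Output slots (default 5).
#' @param n_details Descriptors per object slot (default 10).
#' @param fc_in Declared linear-layer fan-in; must equal the sum of the
#'   two branches' final channel counts (120 + 60 = 180 in the reference
#'   configuration).
#' @return Object of class `network_config`.
#' @export
network_config <- function(image_side = 256L,
                           ibranch_channels = c(15L, 30L, 60L, 120L),
                           obranch_channels = c(15L, 30L, 60L),
                           dropout_zero_prob = 0.5, o_max = O_MAX,
                           n_details = N_DETAILS,
                           fc_in = ibranch_channels[length(ibranch_channels)] +
                             obranch_channels[length(obranch_channels)]) {
  .stop_if(fc_in != ibranch_channels[length(ibranch_channels)] +
             obranch_channels[length(obranch_channels)],
           "fc_in invariant violated: declared fc_in = ", fc_in,
           " but branch outputs sum to ",
           ibranch_channels[length(ibranch_channels)] +
             obranch_channels[length(obranch_channels)])
  .stop_if(dropout_zero_prob < 0 || dropout_zero_prob >= 1,
           "dropout_zero_prob must lie in [0, 1)")
  .stop_if(image_side %% 16 != 0, "image_side must be divisible by 16")
  cfg <- structure(list(image_side = as.integer(image_side),
                        ibranch_channels = as.integer(ibranch_channels),
                        obranch_channels = as.integer(obranch_channels),
                        dropout_zero_prob = dropout_zero_prob,
                        fc_in = as.integer(fc_in), fc_out = as.integer(o_max),
                        o_max = as.integer(o_max),
                        n_details = as.integer(n_details)),
                   class = "network_config")
  cfg
}

#' Validate that a configuration matches the expected linear-layer fan-in
#'
#' @param config A [network_config()].
#' @param expected_fc_in Required concatenated feature length (default 180).
#' @return Invisibly `TRUE`; error if the invariant is violated.
#' @export
check_config <- function(config, expected_fc_in = 180L) {
  .stop_if(config$fc_in != expected_fc_in,
           "fc_in invariant violated: last i-branch channel + last ",
           "o-branch channel = ", config$fc_in, ", expected ", expected_fc_in)
  invisible(TRUE)
}

.init_mat <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

#' Build and initialize the model
#'
#' Weights use fan-in-scaled normal initialization; biases start at zero.
#' Deterministic under `seed`.
#'
#' @param config A [network_config()].
#' @param seed RNG seed stored with the model.
#' @return Object of class `retina_model`: the configuration plus all
#'   convolution and linear parameters.
#' @export
build_model <- function(config = network_config(), seed = 1L) {
  .stop_if(!inherits(config, "network_config"), "config must be a network_config")
  set.seed(seed)
  ich <- c(1L, config$ibranch_channels)
  och <- c(1L, config$obranch_channels)
  params <- list()
  for (l in seq_along(config$ibranch_channels)) {
    params[[paste0("ci", l)]] <- list(w = .init_mat(ich[l + 1], ich[l] * 9),
                                      b = numeric(ich[l + 1]))
  }
  for (l in seq_along(config$obranch_channels)) {
    params[[paste0("co", l)]] <- list(w = .init_mat(och[l + 1], och[l] * 3),
                                      b = numeric(och[l + 1]))
  }
  params$fc <- list(w = .init_mat(config$fc_out, config$fc_in),
                    b = numeric(config$fc_out))
  structure(list(config = config, params = params, seed = seed),
            class = "retina_model")
}

#' Per-layer output shapes for a probe input
#'
#' @param model A `retina_model`.
#' @param image_side Probe image side (default: the configured side).
#' @return Data frame with columns `layer`, `channels`, `height`, `width`
#'   for the image branch, the object branch (width = sequence length),
#'   and the concatenated feature vector.
#' @export
probe_shapes <- function(model, image_side = model$config$image_side) {
  cfg <- model$config
  side <- image_side
  rows <- list()
  for (l in seq_along(cfg$ibranch_channels)) {
    side <- side %/% 2L
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("iblock%d", l),
                 channels = cfg$ibranch_channels[l],
                 height = side, width = side)
  }
  L <- cfg$o_max * cfg$n_details
  for (l in seq_along(cfg$obranch_channels)) {
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("oblock%d", l),
                 channels = cfg$obranch_channels[l], height = 1L, width = L)
  }
  rows[[length(rows) + 1L]] <- data.frame(layer = "concat",
                                          channels = cfg$fc_in,
                                          height = 1L, width = 1L)
  rows[[length(rows) + 1L]] <- data.frame(layer = "output",
                                          channels = cfg$fc_out,
                                          height = 1L, width = 1L)
  do.call(rbind, rows)
}

.gap2d <- function(x, channels, n) {
  # x: cube (H, W, channels*n) -> channels x n matrix of spatial means
  matrix(colMeans(matrix(x, nrow = dim(x)[1] * dim(x)[2])), channels, n)
}

.gap1d <- function(x, channels, n) {
  matrix(colMeans(x), channels, n)
}

#' Forward pass of the dual-branch classifier
#'
#' @param model A `retina_model`.
#' @param images `H x W x N` array (grayscale in `[0, 1]`); a single
#'   matrix is treated as one sample. `H = W` and divisible by 16.
#' @param details `50 x N` matrix of flattened object detail matrices
#'   (row-major slot-contiguous layout), or one `object_detail_matrix`, or
#'   a `5 x 10 x N` array.
#' @param training Logical; when `TRUE` dropout is active (uses the
#'   ambient RNG) and, with `keep_cache = TRUE`, intermediate activations
#'   are retained for backpropagation. Inference (`FALSE`) is
#'   deterministic.
#' @param keep_cache Keep activations for [nn_backward()].
#' @return `o_max x N` matrix of probabilities in (0, 1); with
#'   `keep_cache = TRUE`, a list `(probs, cache)`.
#' @export
nn_forward <- function(model, images, details, training = FALSE,
                       keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  .stop_if(dim(images)[1] != dim(images)[2],
           "image height and width differ: ", dim(images)[1], " vs ",
           dim(images)[2])
  .stop_if(dim(images)[1] %% 16 != 0,
           "image side must be divisible by 16, got ", dim(images)[1])
  n <- dim(images)[3]
  if (inherits(details, "object_detail_matrix")) {
    details <- matrix(as.numeric(t(details$values)), ncol = 1)
  }
  if (length(dim(details)) == 3L) {
    details <- vapply(seq_len(dim(details)[3]),
                      function(i) as.numeric(t(details[, , i])),
                      numeric(cfg$o_max * cfg$n_details))
    details <- matrix(details, ncol = n)
  }
  .stop_if(nrow(details) != cfg$o_max * cfg$n_details,
           "details must have ", cfg$o_max * cfg$n_details, " rows, got ",
           nrow(details))
  .stop_if(ncol(details) != n, "details batch size ", ncol(details),
           " does not match image batch size ", n)

  cache <- list(n = n)
  # image branch
  x <- array(images, c(dim(images)[1], dim(images)[2], n))  # 1 channel
  for (l in seq_along(cfg$ibranch_channels)) {
    xin <- x
    z <- conv2d_fw(xin, p[[paste0("ci", l)]]$w, p[[paste0("ci", l)]]$b, n)
    a <- z * (z > 0)
    pl <- maxpool2_fw(a)
    x <- pl$y
    if (keep_cache) {
      cache[[paste0("i_in", l)]] <- xin
      cache[[paste0("i_act", l)]] <- a
      cache[[paste0("i_idx", l)]] <- pl$idx
    }
  }
  fi <- .gap2d(x, cfg$ibranch_channels[length(cfg$ibranch_channels)], n)
  if (keep_cache) cache$i_pooled_dim <- dim(x)
  # object branch
  s <- details
  for (l in seq_along(cfg$obranch_channels)) {
    sin <- s
    z <- conv1d_fw(sin, p[[paste0("co", l)]]$w, p[[paste0("co", l)]]$b, n)
    s <- z * (z > 0)
    if (keep_cache) {
      cache[[paste0("o_in", l)]] <- sin
      cache[[paste0("o_act", l)]] <- s
    }
  }
  fo <- .gap1d(s, cfg$obranch_channels[length(cfg$obranch_channels)], n)
  if (keep_cache) cache$o_len <- nrow(s)
  feat <- rbind(fi, fo)                    # fc_in x n
  if (training && cfg$dropout_zero_prob > 0) {
    keep <- 1 - cfg$dropout_zero_prob
    mask <- matrix(runif(length(feat)) < keep, nrow(feat)) / keep
    feat_d <- feat * mask
    if (keep_cache) cache$drop_mask <- mask
  } else {
    feat_d <- feat
  }
  logits <- p$fc$w %*% feat_d + p$fc$b
  probs <- 1 / (1 + exp(-logits))
  if (keep_cache) {
    cache$feat <- feat
    cache$feat_d <- feat_d
    cache$probs <- probs
    return(list(probs = probs, cache = cache))
  }
  probs
}

# Gradients of the mean binary cross-entropy loss w.r.t. all parameters.
# Returns a list mirroring model$params.
nn_backward <- function(model, cache, targets) {
  cfg <- model$config
  p <- model$params
  n <- cache$n
  grads <- list()
  dlogits <- (cache$probs - targets) / (cfg$fc_out * n)
  grads$fc <- list(w = dlogits %*% t(cache$feat_d),
                   b = rowSums(dlogits))
  dfeat <- t(p$fc$w) %*% dlogits
  if (!is.null(cache$drop_mask)) dfeat <- dfeat * cache$drop_mask
  ni <- cfg$ibranch_channels[length(cfg$ibranch_channels)]
  dfi <- dfeat[seq_len(ni), , drop = FALSE]
  dfo <- dfeat[(ni + 1):nrow(dfeat), , drop = FALSE]
  # image branch backward
  pd <- cache$i_pooled_dim
  hw <- pd[1] * pd[2]
  dx <- array(rep(as.numeric(dfi) / hw, each = hw), pd)
  for (l in rev(seq_along(cfg$ibranch_channels))) {
    a <- cache[[paste0("i_act", l)]]
    da <- maxpool2_bw(dx, cache[[paste0("i_idx", l)]], dim(a)[1], dim(a)[2])
    dz <- da * (a > 0)
    bw <- conv2d_bw(cache[[paste0("i_in", l)]], p[[paste0("ci", l)]]$w, dz, n)
    grads[[paste0("ci", l)]] <- list(w = bw$dw, b = as.numeric(bw$db))
    dx <- bw$dx
  }
  # object branch backward
  L <- cache$o_len
  no <- cfg$obranch_channels[length(cfg$obranch_channels)]
  ds <- matrix(rep(as.numeric(dfo) / L, each = L), L)
  for (l in rev(seq_along(cfg$obranch_channels))) {
    a <- cache[[paste0("o_act", l)]]
    dz <- ds * (a > 0)
    bw <- conv1d_bw(cache[[paste0("o_in", l)]], p[[paste0("co", l)]]$w, dz, n)
    grads[[paste0("co", l)]] <- list(w = bw$dw, b = as.numeric(bw$db))
    ds <- bw$dx
  }
  grads
}

#' Save / load a model checkpoint
#'
#' Plain-text checkpoint: a JSON file holding the configuration, the
#' initialization seed and all parameters at maximum decimal precision
#' (round-trips are exact to within one unit in the last place).
#'
#' @param model A `retina_model`.
#' @param path Output path (`.json`).
#' @return Invisibly `path`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config), seed = model$seed,
              params = lapply(model$params, function(l) {
                list(w = list(dim = dim(l$w), data = as.numeric(l$w)),
                     b = as.numeric(l$b))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config,
                 obj$config[c("image_side", "ibranch_channels",
                              "obranch_channels", "dropout_zero_prob")])
  params <- lapply(obj$params, function(l) {
    list(w = matrix(l$w$data, l$w$dim[1], l$w$dim[2]), b = as.numeric(l$b))
  })
  structure(list(config = cfg, params = params, seed = obj$seed),
            class = "retina_model")
}

#' @export
print.retina_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$w) + length(l$b),
                   numeric(1)))
  cat("retina_model:", length(x$config$ibranch_channels),
      "i-branch blocks +", length(x$config$obranch_channels),
      "o-branch blocks, fc", x$config$fc_in, "->", x$config$fc_out,
      sprintf("(%d parameters)\n", as.integer(np)))
  invisible(x)
}
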