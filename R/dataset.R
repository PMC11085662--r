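#' Normalize one object record to ten features in [0, 1]
#'
#' Column order is fixed: `x1, y1, x2, y2, xc, yc, c, a, d, score`.
#' Coordinates are divided by the image side, area by the squared side,
#' class id by the number of classes, depth by `d_max`; the detection
#' score is already in (0, 1]. Values are clipped to `[0, 1]`.
#'
#' @param record One-row data frame (or list) with fields `x1, y1, x2, y2,
#'   xc, yc, class_id, area_px, depth, score`.
#' @param image_side Image side in pixels (> 0).
#' @param n_classes Number of object classes (> 0).
#' @param d_max Maximum depth used for normalization (> 0).
#' @return Numeric vector of length 10.
#' @export
normalize_features <- function(record, image_side, n_classes, d_max) {
  .stop_if(image_side <= 0 || n_classes <= 0 || d_max <= 0,
           "normalizers must be positive")
  v <- c(record$x1 / image_side, record$y1 / image_side,
         record$x2 / image_side, record$y2 / image_side,
         record$xc / image_side, record$yc / image_side,
         record$class_id / n_classes, record$area_px / image_side^2,
         record$depth / d_max, record$score)
  pmin(pmax(as.numeric(v), 0), 1)
}

.detail_cols <- c("x1", "y1", "x2", "y2", "xc", "yc", "c", "a", "d", "score")

#' Build the per-image object detail matrix
#'
#' Assembles the fixed `o_max x 10` feature block consumed by the
#' classifier's object branch: one row per object slot in descending
#' detection-score order, normalized with [normalize_features()], rows
#' beyond the number of real objects zero-padded. With more than `o_max`
#' records only the top `o_max` by score are kept.
#'
#' @param records Slot table of object records (may be empty).
#' @param image_side Image side in pixels.
#' @param n_classes Number of object classes.
#' @param d_max Depth normalizer.
#' @param o_max Number of slots (default 5).
#' @return List with `values` (`o_max x 10` matrix in `[0,1]`) and
#'   `pad_mask` (logical, `TRUE` for zero-padded slots); class
#'   `object_detail_matrix`.
#' @export
build_object_matrix <- function(records, image_side, n_classes = 3,
                                d_max, o_max = O_MAX) {
  values <- matrix(0, o_max, N_DETAILS, dimnames = list(NULL, .detail_cols))
  n <- if (is.null(records)) 0L else nrow(records)
  if (n > 0) {
    if (is.unsorted(rev(records$score))) {
      message("records not sorted by score; re-sorting")
      records <- records[order(-records$score), , drop = FALSE]
    }
    k <- min(n, o_max)
    for (i in seq_len(k)) {
      values[i, ] <- normalize_features(records[i, ], image_side, n_classes,
                                        d_max)
    }
  }
  structure(list(values = values,
                 pad_mask = seq_len(o_max) > min(n, o_max)),
            class = "object_detail_matrix")
}

#' Split indices into train / validation / test sets
#'
#' Random permutation under `seed`, cut into contiguous slices whose sizes
#' are the rounded cumulative fractions (so the three sets always
#' partition `1..n`).
#'
#' @param n Number of samples.
#' @param fractions Length-3 nonnegative fractions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed.
#' @return List with integer index vectors `train`, `validation`, `test`;
#'   class `dataset_split`.
#' @export
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  .stop_if(abs(sum(fractions) - 1) > 1e-9, "fractions must sum to 1")
  .stop_if(n < 1, "n must be positive")
  set.seed(seed)
  perm <- sample.int(n)
  cuts <- round(cumsum(fractions) * n)
  cuts[3] <- n
  structure(list(train = sort(perm[seq_len(cuts[1])]),
                 validation = sort(perm[seq(cuts[1] + 1, length.out = cuts[2] - cuts[1])]),
                 test = sort(perm[seq(cuts[2] + 1, length.out = n - cuts[2])])),
            class = "dataset_split")
}

.annotation_cols <- c("image", "slot", "x1", "y1", "x2", "y2", "xc", "yc",
                      "c", "a", "d", "score", "actual_size", "primary")

#' Write scene annotations to CSV
#'
#' One row per object slot (padded slots included as all-zero rows so the
#' 5-slot structure round-trips exactly). Schema:
#' `image, slot, x1, y1, x2, y2, xc, yc, c, a, d, score, actual_size,
#' primary`.
#'
#' @param samples List of `scene_sample` objects.
#' @param path Output CSV path (a `.json` extension writes the JSON
#'   mirror instead).
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(samples, path) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    rec <- s$objects
    n <- nrow(rec)
    out <- data.frame(image = sprintf("scene_%04d.png", i),
                      slot = seq_len(O_MAX), x1 = 0, y1 = 0, x2 = 0, y2 = 0,
                      xc = 0, yc = 0, c = 0L, a = 0, d = 0, score = 0,
                      actual_size = 0, primary = as.integer(s$truth_labels))
    if (n > 0) {
      k <- min(n, O_MAX)
      idx <- seq_len(k)
      out$x1[idx] <- rec$x1[idx]; out$y1[idx] <- rec$y1[idx]
      out$x2[idx] <- rec$x2[idx]; out$y2[idx] <- rec$y2[idx]
      out$xc[idx] <- rec$xc[idx]; out$yc[idx] <- rec$yc[idx]
      out$c[idx] <- rec$class_id[idx]; out$a[idx] <- rec$area_px[idx]
      out$d[idx] <- rec$depth[idx]; out$score[idx] <- rec$score[idx]
      out$actual_size[idx] <- rec$actual_size[idx]
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read scene annotations
#'
#' Inverse of [write_annotations()]: validates the schema (any missing or
#' unknown column is reported by name) and returns the slot table.
#'
#' @param path CSV (or JSON mirror) path.
#' @return Data frame in the annotation schema; zero rows for a
#'   header-only file.
#' @export
read_annotations <- function(path) {
  .stop_if(!file.exists(path), "no such file: ", path)
  tab <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    stop("annotation file has no header", call. = FALSE)
  }
  miss <- setdiff(.annotation_cols, names(tab))
  .stop_if(length(miss) > 0, "annotation schema missing column(s): ",
           paste(miss, collapse = ", "))
  extra <- setdiff(names(tab), .annotation_cols)
  .stop_if(length(extra) > 0, "unexpected annotation column(s): ",
           paste(extra, collapse = ", "))
  tab
}

#' Block-average downsampling of a square image
#'
#' @param img Numeric matrix with side divisible by `side_out`.
#' @param side_out Output side in pixels.
#' @return `side_out x side_out` matrix of block means.
#' @export
downsample_image <- function(img, side_out) {
  side <- nrow(img)
  if (side == side_out) return(img)
  .stop_if(side %% side_out != 0, "image side not divisible by side_out")
  f <- side %/% side_out
  g <- rep(seq_len(side_out), each = f)
  unname(t(rowsum(t(rowsum(img, g)), g))) / f^2
}

#' Assemble network-ready tensors from scenes
#'
#' Converts scene samples into the arrays the trainer consumes: images
#' scaled to `[0, 1]` and block-averaged to `input_side`, the flattened
#' 5 x 10 object detail matrices (row-major, one object's ten descriptors
#' contiguous), and the 5-slot target labels.
#'
#' @param samples List of `scene_sample` objects.
#' @param input_side Side of the image fed to the network (default 32).
#' @return List with `images` (`input_side x input_side x N` array),
#'   `details` (`50 x N` matrix), `targets` (`5 x N` 0/1 matrix) and
#'   `pad` (`5 x N` logical).
#' @export
prepare_training_data <- function(samples, input_side = 32L) {
  n <- length(samples)
  imgs <- array(0, c(input_side, input_side, n))
  det <- matrix(0, O_MAX * N_DETAILS, n)
  tgt <- matrix(0, O_MAX, n)
  pad <- matrix(TRUE, O_MAX, n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    imgs[, , i] <- downsample_image(s$image, input_side) / 255
    m <- build_object_matrix(s$objects, image_side = s$spec$image_side,
                             n_classes = length(s$spec$shapes),
                             d_max = s$spec$background_depth)
    det[, i] <- as.numeric(t(m$values))   # row-major: slot-contiguous
    tgt[, i] <- as.numeric(s$truth_labels)
    pad[, i] <- m$pad_mask
  }
  list(images = imgs, details = det, targets = tgt, pad = pad)
}

#' Generate network-ready data without retaining full scenes
#'
#' Streaming combination of [generate_dataset()] and
#' [prepare_training_data()]: each scene is generated, converted and
#' discarded, keeping memory proportional to the downsampled tensors.
#'
#' @inheritParams generate_dataset
#' @param input_side Side of the image fed to the network.
#' @return As [prepare_training_data()].
#' @export
generate_training_data <- function(spec_template, n_scenes, seed = 1L,
                                   input_side = 32L,
                                   n_objects_range = c(0L, O_MAX)) {
  .stop_if(n_scenes < 1, "n_scenes must be at least 1")
  set.seed(seed)
  counts <- sample(seq(n_objects_range[1], n_objects_range[2]),
                   n_scenes, replace = TRUE)
  imgs <- array(0, c(input_side, input_side, n_scenes))
  det <- matrix(0, O_MAX * N_DETAILS, n_scenes)
  tgt <- matrix(0, O_MAX, n_scenes)
  pad <- matrix(TRUE, O_MAX, n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- spec_template
    sp$n_objects <- as.integer(counts[i])
    sp$seed <- NULL
    s <- generate_scene(sp)
    one <- prepare_training_data(list(s), input_side)
    imgs[, , i] <- one$images[, , 1]
    det[, i] <- one$details[, 1]
    tgt[, i] <- one$targets[, 1]
    pad[, i] <- one$pad[, 1]
  }
  list(images = imgs, details = det, targets = tgt, pad = pad)
}
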