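#' Keep only primary objects in an image
#'
#' Pixels inside the union of the primary objects' regions are preserved;
#' everything else is set to 0. By default regions are bounding boxes; a
#' list of silhouette masks (logical matrices) may be supplied instead
#' when an external segmentation source is available.
#'
#' @param image Grayscale matrix (0-255).
#' @param records Slot table with `x1, y1, x2, y2` (0-based half-open).
#' @param primariness Logical vector aligned with the records (extra
#'   entries, e.g. for padded slots, are ignored).
#' @param masks Optional list of logical matrices, one per record,
#'   overriding the bounding boxes.
#' @return Object of class `enhanced_image`: list with `pixels` and
#'   `kept_slots`.
#' @export
filter_primary <- function(image, records, primariness, masks = NULL) {
  n <- if (is.null(records)) 0L else nrow(records)
  keep <- which(as.logical(primariness[seq_len(n)]))
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (k in keep) {
    if (!is.null(masks)) {
      mask <- mask | masks[[k]]
    } else {
      x1 <- max(0, floor(records$x1[k])); y1 <- max(0, floor(records$y1[k]))
      x2 <- min(ncol(image), ceiling(records$x2[k]))
      y2 <- min(nrow(image), ceiling(records$y2[k]))
      if (x2 > x1 && y2 > y1) mask[(y1 + 1):y2, (x1 + 1):x2] <- TRUE
    }
  }
  structure(list(pixels = image * mask, kept_slots = keep),
            class = "enhanced_image")
}

#' Canny-style edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, and hysteresis linking: weak edge pixels (between
#' the two thresholds) survive only when 8-connected to a strong pixel.
#'
#' @param image Grayscale matrix (0-255).
#' @param low_thr,high_thr Hysteresis thresholds on the gradient
#'   magnitude, `0 <= low_thr < high_thr` (defaults 50 / 150 on 8-bit).
#' @param sigma Gaussian smoothing scale in pixels (default 1.4).
#' @return Binary (0/1) matrix of edge pixels.
#' @export
edge_map <- function(image, low_thr = 50, high_thr = 150, sigma = 1.4) {
  .stop_if(low_thr < 0 || low_thr >= high_thr,
           "require 0 <= low_thr < high_thr")
  canny_edges(image, sigma, low_thr, high_thr)
}

#' Simulated phosphene rendering
#'
#' Emulates what a retinal-implant wearer perceives: the image is reduced
#' to a `G x G` grid of luminous dots. Each block's mean intensity is
#' quantized to `levels` gray levels and rendered as a radially symmetric
#' Gaussian bump on black (when the image side is not divisible by `G`
#' the pixels are apportioned so that every block is non-empty).
#'
#' @param image Grayscale matrix (0-255).
#' @param grid_dims Dots per side, `G >= 2` and at most the image side.
#' @param dot_sigma Dot radius parameter in pixels (default: a third of
#'   the block size).
#' @param levels Number of gray levels (default 8).
#' @return Object of class `phosphene_image`: `grid` (`G x G` quantized
#'   dot intensities), `rendered` (matrix like `image`), `grid_dims`,
#'   `levels`.
#' @export
phosphene_render <- function(image, grid_dims = 32L, dot_sigma = NULL,
                             levels = 8L) {
  side_y <- nrow(image); side_x <- ncol(image)
  .stop_if(grid_dims < 2, "grid_dims must be at least 2")
  .stop_if(grid_dims > min(side_y, side_x),
           "grid_dims larger than the image side")
  G <- as.integer(grid_dims)
  # proportional block assignment: every one of the G groups is non-empty
  # even when the side is not divisible by G
  gy <- ceiling(seq_len(side_y) * G / side_y)
  gx <- ceiling(seq_len(side_x) * G / side_x)
  bs_y <- side_y / G; bs_x <- side_x / G
  sums <- rowsum(t(rowsum(image, gy)), gx)          # G x G (x by y)
  cnt <- rowsum(t(rowsum(matrix(1, side_y, side_x), gy)), gx)
  means <- t(sums / cnt)                            # y by x
  q <- 255 / (levels - 1)
  grid <- round(means / q) * q
  if (is.null(dot_sigma)) dot_sigma <- min(bs_y, bs_x) / 3
  rendered <- matrix(0, side_y, side_x)
  cy <- (tapply(seq_len(side_y), gy, mean))
  cx <- (tapply(seq_len(side_x), gx, mean))
  yy <- matrix(seq_len(side_y), side_y, side_x)
  xx <- matrix(seq_len(side_x), side_y, side_x, byrow = TRUE)
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (grid[i, j] <= 0) next
      d2 <- (yy - cy[i])^2 + (xx - cx[j])^2
      rendered <- rendered + grid[i, j] * exp(-d2 / (2 * dot_sigma^2))
    }
  }
  structure(list(grid = grid, rendered = pmin(rendered, 255),
                 grid_dims = G, levels = as.integer(levels)),
            class = "phosphene_image")
}

# count local maxima with topographic prominence >= prom
.count_peaks <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(0L)
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  cnt <- 0L
  for (p in peaks) {
    left <- x[seq_len(p - 1)]
    right <- x[seq(p + 1, n)]
    # descend to the higher of the two key saddles
    lmin <- if (any(left >= x[p])) {
      k <- max(which(left >= x[p])); min(x[k:(p - 1)])
    } else min(left)
    rmin <- if (any(right >= x[p])) {
      k <- min(which(right >= x[p])); min(x[(p + 1):(p + k)])
    } else min(right)
    if (x[p] - max(lmin, rmin) >= prom) cnt <- cnt + 1L
  }
  cnt
}

#' Intensity profile along an image row
#'
#' @param image Grayscale matrix.
#' @param row 1-based row index (default: center row).
#' @param prominence Minimum peak prominence in gray levels (default 10).
#' @return Object of class `intensity_profile`: `row`, `intensity`
#'   (length = image width), `contrast` (max - min) and `peak_count`.
#' @export
intensity_profile <- function(image, row = nrow(image) %/% 2L,
                              prominence = 10) {
  .stop_if(row < 1 || row > nrow(image), "row out of bounds: ", row)
  v <- as.numeric(image[row, ])
  structure(list(row = row, intensity = v, contrast = max(v) - min(v),
                 peak_count = .count_peaks(v, prominence),
                 prominence = prominence),
            class = "intensity_profile")
}

#' Run the enhancement stage on one scene
#'
#' Applies [filter_primary()] with the given (or ground-truth) slot
#' primariness, then derives edge maps and phosphene renderings of both
#' the original and the enhanced image, mirroring the panel comparison
#' original | edges | phosphene | enhanced | enhanced edges | enhanced
#' phosphene.
#'
#' @param sample A `scene_sample`.
#' @param primariness Logical slot labels (default: the sample's truth).
#' @param grid_dims Phosphene grid side.
#' @return Named list of the six panels (`enhanced` is the
#'   `enhanced_image`; edge maps binary; phosphenes `phosphene_image`).
#' @export
enhance_scene <- function(sample, primariness = sample$truth_labels,
                          grid_dims = 32L) {
  enh <- filter_primary(sample$image, sample$objects, primariness)
  list(original = sample$image,
       edges = edge_map(sample$image),
       phosphene = phosphene_render(sample$image, grid_dims),
       enhanced = enh,
       enhanced_edges = edge_map(enh$pixels),
       enhanced_phosphene = phosphene_render(enh$pixels, grid_dims))
}

#' Write a side-by-side comparison panel as PNG
#'
#' @param panels Result of [enhance_scene()].
#' @param path Output PNG path.
#' @return Invisibly `path`.
#' @export
write_comparison <- function(panels, path) {
  to_mat <- function(x) {
    if (inherits(x, "enhanced_image")) x <- x$pixels
    if (inherits(x, "phosphene_image")) x <- x$rendered
    if (max(x) <= 1) x <- x * 255
    x / 255
  }
  mats <- lapply(panels, to_mat)
  h <- max(vapply(mats, nrow, 0L))
  sep <- matrix(1, h, 2)
  padded <- lapply(mats, function(m) {
    if (nrow(m) < h) m <- rbind(m, matrix(0, h - nrow(m), ncol(m)))
    m
  })
  strip <- padded[[1]]
  for (m in padded[-1]) strip <- cbind(strip, sep, m)
  png::writePNG(pmin(pmax(strip, 0), 1), path)
  invisible(path)
}
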