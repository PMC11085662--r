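#' Labeling parameters for primary/non-primary assignment
#'
#' An object is labeled *primary* when its depth-transferred actual size is
#' at least `alpha` times the largest actual size among the real objects in
#' the image, and its depth does not exceed `beta` times the maximum depth
#' present in the depth map. `d_ref` is the common reference depth to which
#' all object sizes are virtually transferred before comparison.
#'
#' @param d_ref Reference depth (depth units, > 0) for the size transfer.
#' @param alpha Size fraction in (0, 1]: minimum actual size relative to the
#'   image's largest actual size.
#' @param beta Depth fraction in (0, 1]: objects deeper than
#'   `beta * max(depth map)` are never primary.
#' @return An object of class `labeling_params`.
#' @export
labeling_params <- function(d_ref = 1, alpha = 0.5, beta = 0.75) {
  .stop_if(!is.numeric(d_ref) || length(d_ref) != 1L || d_ref <= 0,
           "d_ref must be a positive scalar")
  .stop_if(!is.numeric(alpha) || alpha <= 0 || alpha > 1,
           "alpha must lie in (0, 1]")
  .stop_if(!is.numeric(beta) || beta <= 0 || beta > 1,
           "beta must lie in (0, 1]")
  structure(list(d_ref = d_ref, alpha = alpha, beta = beta),
            class = "labeling_params")
}

.check_bbox <- function(bbox, allow_degenerate = TRUE) {
  .stop_if(length(bbox) != 4L || anyNA(bbox), "bbox must be (x1, y1, x2, y2)")
  .stop_if(bbox[1] > bbox[3] || bbox[2] > bbox[4],
           "inverted bbox corners: require x1 <= x2 and y1 <= y2")
  .stop_if(!allow_degenerate && (bbox[1] == bbox[3] || bbox[2] == bbox[4]),
           "degenerate bbox")
  invisible(bbox)
}

#' Bounding-box area
#'
#' Boxes are 0-based, half-open `(x1, y1, x2, y2)`, so the area is exactly
#' `(x2 - x1) * (y2 - y1)` pixels squared. Zero-padded slots `(0,0,0,0)`
#' have area 0.
#'
#' @param bbox Numeric length-4 vector `(x1, y1, x2, y2)`.
#' @return Area in pixels squared.
#' @export
bbox_area <- function(bbox) {
  .check_bbox(bbox)
  (bbox[3] - bbox[1]) * (bbox[4] - bbox[2])
}

#' Bounding-box center
#'
#' @inheritParams bbox_area
#' @return Numeric `(xc, yc)`, the arithmetic midpoint of the two corners.
#' @export
bbox_center <- function(bbox) {
  .check_bbox(bbox)
  c(xc = (bbox[1] + bbox[3]) / 2, yc = (bbox[2] + bbox[4]) / 2)
}

#' Robust object depth from a depth map
#'
#' The mean depth inside a bounding box is biased by background pixels that
#' the box inevitably contains. Instead the depth values inside the box are
#' split into two groups at the threshold maximizing the between-group
#' variance (Otsu's criterion applied to the raw values), and the median of
#' the *nearer* group is returned. When the two group medians differ by
#' less than 5% of the depth map's full range the split is considered
#' spurious and the median of all values in the box is returned.
#'
#' @param depth_map Numeric matrix of per-pixel depths (rows = y, cols = x).
#' @param bbox 0-based half-open box `(x1, y1, x2, y2)`, non-degenerate.
#' @return Estimated object depth (depth units).
#' @export
estimate_object_depth <- function(depth_map, bbox) {
  .check_bbox(bbox, allow_degenerate = FALSE)
  h <- nrow(depth_map); w <- ncol(depth_map)
  x1 <- max(0, floor(bbox[1])); y1 <- max(0, floor(bbox[2]))
  x2 <- min(w, ceiling(bbox[3])); y2 <- min(h, ceiling(bbox[4]))
  .stop_if(x1 >= x2 || y1 >= y2, "bbox does not intersect the depth map")
  vals <- as.numeric(depth_map[(y1 + 1):y2, (x1 + 1):x2])
  rng <- max(depth_map) - min(depth_map)
  u <- sort(unique(vals))
  if (length(u) == 1L) return(u)
  # exact Otsu split over all candidate thresholds (midpoints between
  # consecutive distinct values), via cumulative moments of sorted values
  s <- sort(vals)
  n <- length(s)
  cs <- cumsum(s)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  valid <- s[k] < s[k + 1L]              # splits between distinct values
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  between <- (k / n) * ((n - k) / n) * (m1 - m2)^2
  between[!valid] <- -Inf
  kstar <- which.max(between)            # first maximizer: lowest threshold
  near <- s[seq_len(kstar)]
  far <- s[(kstar + 1L):n]
  if (abs(median(far) - median(near)) < 0.05 * rng) return(median(s))
  median(near)
}

#' Depth-transferred actual size
#'
#' Virtually transfers an object to the common reference depth `d_ref` and
#' returns its area there. Under perspective projection on-image area
#' scales with `1 / depth^2`, so the corrected area is
#' `area_px * (depth / d_ref)^2`.
#'
#' @param area_px On-image area in pixels squared.
#' @param depth Object depth (> 0, depth units).
#' @param d_ref Reference depth (> 0, depth units).
#' @return Area in pixels squared at the reference depth.
#' @export
actual_size <- function(area_px, depth, d_ref = 1) {
  .stop_if(any(depth <= 0), "depth must be positive")
  .stop_if(any(d_ref <= 0), "d_ref must be positive")
  area_px * (depth / d_ref)^2
}

#' Assign primary/non-primary labels
#'
#' Applies the documented labeling rule to a slot table of object records:
#' a real object is primary iff its `actual_size` is at least
#' `params$alpha` times the maximum actual size among real objects in the
#' image *and* its depth is at most `params$beta * d_max`, where `d_max`
#' is the maximum depth present in the image's depth map. Zero-padded
#' slots (area 0) are always non-primary.
#'
#' @param records Data frame with columns `area_px`, `depth`,
#'   `actual_size` (one row per object slot; padded slots have
#'   `area_px == 0`). May have fewer than `o_max` rows.
#' @param params A [labeling_params()] object.
#' @param d_max Maximum depth present in the image's depth map.
#' @param o_max Number of label slots to return (default 5).
#' @return Logical vector of length `o_max`.
#' @export
label_primariness <- function(records, params = labeling_params(),
                              d_max, o_max = O_MAX) {
  .stop_if(!inherits(params, "labeling_params"), "params must be labeling_params")
  .stop_if(missing(d_max) || !is.numeric(d_max) || d_max <= 0,
           "d_max (maximum depth in the depth map) must be a positive scalar")
  out <- logical(o_max)
  if (is.null(records) || nrow(records) == 0L) return(out)
  n <- min(nrow(records), o_max)
  rec <- records[seq_len(n), , drop = FALSE]
  real <- rec$area_px > 0
  if (!any(real)) return(out)
  amax <- max(rec$actual_size[real])
  pr <- real & rec$actual_size >= params$alpha * amax &
    rec$depth <= params$beta * d_max
  out[seq_len(n)] <- pr
  out
}

#' Annotate detection records against a depth map
#'
#' The adapter seam for externally produced detections: given raw records
#' (class, bounding box, score) and the image's depth map, derives center,
#' area, robust object depth, depth-transferred actual size, and the
#' primariness labels. This is the same derivation the synthetic scene
#' generator uses for its ground truth, but run on estimated rather than
#' exact depths.
#'
#' @param records Data frame with at least `class_id`, `x1`, `y1`, `x2`,
#'   `y2`, `score` columns (one row per detected object).
#' @param depth_map Numeric depth matrix aligned with the image.
#' @param params A [labeling_params()] object.
#' @return The records with `xc`, `yc`, `area_px`, `depth`, `actual_size`
#'   and `primary` columns filled in, sorted by descending score.
#' @export
annotate_records <- function(records, depth_map, params = labeling_params()) {
  need <- c("class_id", "x1", "y1", "x2", "y2", "score")
  miss <- setdiff(need, names(records))
  .stop_if(length(miss) > 0, "records missing column(s): ",
           paste(miss, collapse = ", "))
  records <- records[order(-records$score), , drop = FALSE]
  n <- nrow(records)
  records$xc <- (records$x1 + records$x2) / 2
  records$yc <- (records$y1 + records$y2) / 2
  records$area_px <- (records$x2 - records$x1) * (records$y2 - records$y1)
  records$depth <- vapply(seq_len(n), function(i) {
    estimate_object_depth(depth_map,
                          c(records$x1[i], records$y1[i],
                            records$x2[i], records$y2[i]))
  }, numeric(1))
  records$actual_size <- actual_size(records$area_px, records$depth,
                                     params$d_ref)
  pr <- label_primariness(records, params, d_max = max(depth_map),
                          o_max = max(O_MAX, n))
  records$primary <- pr[seq_len(n)]
  rownames(records) <- NULL
  records
}
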