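#' Scene specification for the synthetic generator
#'
#' Describes one synthetic multi-object scene: geometric objects (standing
#' in for detector classes) placed at known depths in front of a flat
#' background. Perspective is modeled by scaling each object's on-image
#' linear extent with `1 / depth`; the depth map carries each object's
#' depth inside its silhouette and `background_depth` elsewhere.
#'
#' Depth units are abstract. The generator's near plane `depth_range[1]`
#' doubles as the default reference depth for size transfer.
#'
#' @param image_side Image side in pixels (square images).
#' @param n_objects Number of objects, between 0 and `o_max` (5).
#' @param shapes Character vector of renderable shapes; class ids are the
#'   positions in this palette.
#' @param depth_range `(d_near, d_far)` object depth interval, `0 < d_near
#'   < d_far < background_depth`.
#' @param physical_size_range Object linear size (pixels) when standing at
#'   the near/reference depth.
#' @param background_depth Depth assigned to background pixels.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (8-bit gray levels).
#' @param seed Optional RNG seed; `NULL` uses the ambient RNG stream.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_side = 256L, n_objects = 3L,
                       shapes = c("rectangle", "ellipse", "triangle"),
                       depth_range = c(1, 7), physical_size_range = c(40, 120),
                       background_depth = 8, noise_sd = 2, seed = NULL) {
  .stop_if(image_side < 16, "image_side must be at least 16")
  .stop_if(n_objects < 0 || n_objects > O_MAX,
           "n_objects must lie in [0, ", O_MAX, "]")
  .stop_if(depth_range[1] <= 0, "d_near must be positive")
  .stop_if(depth_range[1] >= depth_range[2],
           "depth_range must satisfy d_near < d_far")
  .stop_if(depth_range[2] >= background_depth,
           "d_far must be smaller than background_depth")
  .stop_if(physical_size_range[1] <= 0 ||
             physical_size_range[1] > physical_size_range[2],
           "invalid physical_size_range")
  .stop_if(noise_sd < 0, "noise_sd must be nonnegative")
  structure(list(image_side = as.integer(image_side),
                 n_objects = as.integer(n_objects), shapes = shapes,
                 depth_range = as.numeric(depth_range),
                 physical_size_range = as.numeric(physical_size_range),
                 background_depth = as.numeric(background_depth),
                 noise_sd = as.numeric(noise_sd), seed = seed),
            class = "scene_spec")
}

# silhouette mask of one shape on the pixel grid; dx, dy are offsets of
# pixel centers from the object center, wx, wy the half-extents
.shape_mask <- function(shape, dx, dy, wx, wy) {
  switch(shape,
    rectangle = abs(dx) <= wx & abs(dy) <= wy,
    ellipse = (dx / wx)^2 + (dy / wy)^2 <= 1,
    triangle = dy >= -wy & dy <= wy & abs(dx) <= wx * (dy + wy) / (2 * wy),
    stop("unknown shape: ", shape, call. = FALSE))
}

#' Render a fixed object table into a scene
#'
#' Lower-level deterministic renderer behind [generate_scene()]: takes an
#' explicit object table instead of sampling one, so geometry (exact
#' depths, sizes, positions) can be controlled directly.
#'
#' Occlusion follows the painter's algorithm (far to near). Bounding boxes
#' tightly enclose each object's own rendered silhouette (0-based,
#' half-open). Ground-truth labels are computed by applying
#' [label_primariness()] to the exact generated geometry before noise.
#'
#' @param spec A [scene_spec()].
#' @param objects Data frame with columns `shape`, `depth`, `phys_size`,
#'   `aspect`, `intensity`, `xc`, `yc`, `score` (one row per object).
#'   May have zero rows.
#' @param params [labeling_params()] used for the ground-truth labels;
#'   defaults to the generator's near plane as reference depth.
#' @return A `scene_sample`: list with `image` (matrix, 0-255),
#'   `depth_map` (matrix), `objects` (slot table sorted by descending
#'   score), `truth_labels` (logical, length 5) and `spec`.
#' @export
render_objects <- function(spec, objects,
                           params = labeling_params(d_ref = spec$depth_range[1])) {
  side <- spec$image_side
  img <- matrix(60, side, side)          # background gray level
  dmap <- matrix(spec$background_depth, side, side)
  idmap <- matrix(0L, side, side)
  n <- nrow(objects)
  px <- matrix(rep(seq_len(side) - 0.5, each = side), side)  # x of centers
  py <- matrix(rep(seq_len(side) - 0.5, times = side), side) # y of centers
  masks <- vector("list", n)
  if (n > 0) {
    for (k in order(objects$depth, decreasing = TRUE)) {  # painter: far first
      o <- objects[k, ]
      ext <- o$phys_size * spec$depth_range[1] / o$depth
      wx <- ext / 2 * min(1, o$aspect)
      wy <- ext / 2 * min(1, 1 / o$aspect)
      m <- .shape_mask(o$shape, px - o$xc, py - o$yc, wx, wy)
      masks[[k]] <- m
      img[m] <- o$intensity
      dmap[m] <- o$depth
      idmap[m] <- k
    }
  }
  recs <- .records_from_masks(spec, objects, masks, idmap, params, dmap)
  truth <- label_primariness(recs, params, d_max = max(dmap), o_max = O_MAX)
  if (spec$noise_sd > 0) {
    img <- img + rnorm(side * side, sd = spec$noise_sd)
    img <- pmin(pmax(img, 0), 255)
  }
  structure(list(image = img, depth_map = dmap, objects = recs,
                 truth_labels = truth, spec = spec),
            class = "scene_sample")
}

.records_from_masks <- function(spec, objects, masks, idmap, params, dmap) {
  n <- nrow(objects)
  empty <- data.frame(slot = integer(), instance_idx = integer(),
                      class_id = integer(), x1 = integer(), y1 = integer(),
                      x2 = integer(), y2 = integer(), xc = numeric(),
                      yc = numeric(), area_px = numeric(), depth = numeric(),
                      actual_size = numeric(), score = numeric(),
                      primary = logical())
  if (n == 0) return(empty)
  rows <- lapply(seq_len(n), function(k) {
    m <- masks[[k]]
    if (!any(m)) return(NULL)            # degenerate: nothing rendered
    ys <- range(which(rowSums(m) > 0))   # matrix rows are y
    xs <- range(which(colSums(m) > 0))
    bbox <- c(xs[1] - 1, ys[1] - 1, xs[2], ys[2])  # 0-based half-open
    data.frame(class_id = match(objects$shape[k], spec$shapes),
               x1 = bbox[1], y1 = bbox[2], x2 = bbox[3], y2 = bbox[4],
               xc = (bbox[1] + bbox[3]) / 2, yc = (bbox[2] + bbox[4]) / 2,
               area_px = bbox_area(bbox), depth = objects$depth[k],
               score = objects$score[k], visible_px = sum(idmap == k))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  recs <- do.call(rbind, rows)
  recs$actual_size <- actual_size(recs$area_px, recs$depth, params$d_ref)
  recs <- recs[order(-recs$score), , drop = FALSE]
  recs$slot <- seq_len(nrow(recs))
  recs$instance_idx <- stats::ave(recs$class_id, recs$class_id,
                                  FUN = seq_along)
  recs$primary <- label_primariness(recs, params, d_max = max(dmap),
                                    o_max = nrow(recs))[seq_len(nrow(recs))]
  recs$visible_px <- NULL
  rownames(recs) <- NULL
  recs[, names(empty)]
}

#' Generate one synthetic scene
#'
#' Samples object geometry from the spec and renders it: shapes, depths
#' and physical sizes are drawn uniformly from the spec's ranges, objects
#' are placed fully inside the frame, nearer objects occlude farther ones,
#' and detection scores in (0.5, 1] are drawn so that visually prominent
#' (large on-image) objects tend to score higher, emulating detector
#' confidence. Records are ordered by descending score.
#'
#' @param spec A [scene_spec()].
#' @param params [labeling_params()] for the ground-truth labels.
#' @return A `scene_sample`; see [render_objects()].
#' @export
generate_scene <- function(spec,
                           params = labeling_params(d_ref = spec$depth_range[1])) {
  .stop_if(!inherits(spec, "scene_spec"), "spec must be a scene_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_objects
  side <- spec$image_side
  if (n == 0) {
    objects <- data.frame(shape = character(), depth = numeric(),
                          phys_size = numeric(), aspect = numeric(),
                          intensity = numeric(), xc = numeric(),
                          yc = numeric(), score = numeric())
    return(render_objects(spec, objects, params))
  }
  shape <- sample(spec$shapes, n, replace = TRUE)
  depth <- runif(n, spec$depth_range[1], spec$depth_range[2])
  phys <- runif(n, spec$physical_size_range[1], spec$physical_size_range[2])
  aspect <- runif(n, 0.7, 1.4)
  intensity <- runif(n, 120, 250)
  ext <- phys * spec$depth_range[1] / depth
  half <- pmin(ext / 2, (side - 4) / 2)
  xc <- runif(n, half + 1, side - half - 1)
  yc <- runif(n, half + 1, side - half - 1)
  objects <- data.frame(shape = shape, depth = depth, phys_size = phys,
                        aspect = aspect, intensity = intensity,
                        xc = xc, yc = yc)
  # on-image footprint (continuous, pre-occlusion) drives the score
  foot <- ext^2
  rel <- sqrt(foot) / max(sqrt(foot))
  u <- 0.65 * (1 - rel) + 0.35 * runif(n)
  objects$score <- 1 - 0.5 * u
  render_objects(spec, objects, params)
}

#' Generate a collection of synthetic scenes
#'
#' Object counts are drawn independently and uniformly from
#' `n_objects_range` for each scene; all other settings come from the
#' template spec. Reproducible under `seed`.
#'
#' @param spec_template A [scene_spec()] providing the shared settings.
#' @param n_scenes Number of scenes (>= 1).
#' @param seed RNG seed for the whole collection.
#' @param n_objects_range Integer `(min, max)` object count per scene.
#' @return List of `scene_sample` objects.
#' @export
generate_dataset <- function(spec_template, n_scenes, seed = 1L,
                             n_objects_range = c(0L, O_MAX)) {
  .stop_if(n_scenes < 1, "n_scenes must be at least 1")
  set.seed(seed)
  counts <- sample(seq(n_objects_range[1], n_objects_range[2]),
                   n_scenes, replace = TRUE)
  lapply(counts, function(n) {
    sp <- spec_template
    sp$n_objects <- as.integer(n)
    sp$seed <- NULL
    generate_scene(sp)
  })
}

#' @export
print.scene_sample <- function(x, ...) {
  cat("scene_sample:", nrow(x$objects), "objects,",
      paste(dim(x$image), collapse = "x"), "px, primaries:",
      sum(x$truth_labels), "\n")
  invisible(x)
}

#' Write scenes to a directory
#'
#' Each scene `i` becomes `scene_%04d.png` (8-bit grayscale image),
#' `scene_%04d_depth.tsv` (plain-text depth matrix) and one shared
#' annotation table `annotations.csv` in the dataset-module schema.
#'
#' @param samples List of `scene_sample` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the annotation file path.
#' @export
write_scenes <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image / 255, file.path(dir, sprintf("scene_%04d.png", i)))
    utils::write.table(s$depth_map,
                       file.path(dir, sprintf("scene_%04d_depth.tsv", i)),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  path <- file.path(dir, "annotations.csv")
  write_annotations(samples, path)
  invisible(path)
}
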