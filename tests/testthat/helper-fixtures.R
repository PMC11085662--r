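# Shared fixtures: small specs and a one-object scene table for the
# deterministic renderer.

tiny_spec <- function(image_side = 64L, ...) {
  scene_spec(image_side = image_side, noise_sd = 0, ...)
}

# explicit object table for render_objects()
obj_row <- function(shape = "rectangle", depth = 2, phys_size = 40,
                    aspect = 1, intensity = 200, xc = 32, yc = 32,
                    score = 0.9) {
  data.frame(shape = shape, depth = depth, phys_size = phys_size,
             aspect = aspect, intensity = intensity, xc = xc, yc = yc,
             score = score)
}

# random prediction/target fixture on the image x slot grid
random_fixture <- function(n_images, seed = 1) {
  set.seed(seed)
  list(pred = matrix(runif(n_images * 5), n_images, 5),
       targ = matrix(rbinom(n_images * 5, 1, 0.4), n_images, 5))
}
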