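# shared fixtures, all generated in code

# a bare od_image built directly from a 3 x d matrix (no source raster)
make_od <- function(od, shape, I0 = 255) {
  structure(list(od = od, shape = shape,
                 background_mask = rep(FALSE, ncol(od)),
                 I0 = I0, source_pixels = NULL),
            class = "od_image")
}

# random valid 8-bit image with channel values in [lo, 255]
random_rgb_image <- function(h = 16, w = 16, seed = 1, lo = 1) {
  withr::with_seed(seed, {
    px <- array(sample(lo:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
    rgb_image(px)
  })
}

# unit-column reference stain matrix (packaged mean, exactly normalized)
unit_reference <- function() {
  W <- cbcs_stain_distribution()$W0
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# small, fast phantom spec for unit tests
small_spec <- function(n_images = 4, image_size = c(64, 64), ...) {
  phantom_spec(n_images = n_images, image_size = image_size, ...)
}
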