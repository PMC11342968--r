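test_that("intensity perturbation uses one uniform alpha per image", {
  H <- matrix(runif(2 * 50), 2)
  expect_identical(perturb_intensity(H, 0)[, ], H[, ])
  out <- perturb_intensity(H, 0.2, rng_seed = 5)
  ratio <- out / H
  a <- attr(out, "alpha")
  expect_equal(max(abs(ratio - a)), 0, tolerance = 1e-12)
  expect_true(a >= 0.8 && a <= 1.2)
  expect_identical(perturb_intensity(H, 0.2, rng_seed = 5)[, ], out[, ])
  expect_error(perturb_intensity(H, 1), "alpha must stay positive")
})

test_that("san at test time equals normalization onto the target mean", {
  ph <- generate_phantom(small_spec(), 0, 1)
  dc <- decompose_stains(ph$image)
  dist <- stain_distribution(unit_reference(), sigma = 0.31)  # sigma irrelevant
  cfg_t <- adaptation_config("san", role = "test")
  cfg_n <- adaptation_config("normalize", percentile_rescale = NULL)
  out_san <- adapt_stain_san(dc, dist, cfg_t)
  out_norm <- adapt_normalize(dc, dist$W0, cfg_n)
  expect_identical(out_san$pixels, out_norm$pixels)
})

test_that("san with zero variance and zero epsilon reduces to normalization", {
  dist0 <- stain_distribution(unit_reference(), sigma = 0)
  cfg <- adaptation_config("san", role = "train", epsilon = 0, rng_seed = 9)
  cfg_n <- adaptation_config("normalize", percentile_rescale = NULL)
  for (idx in 1:3) {
    dc <- decompose_stains(generate_phantom(small_spec(), 0, idx)$image)
    expect_identical(adapt_stain_san(dc, dist0, cfg)$pixels,
                     adapt_normalize(dc, dist0$W0, cfg_n)$pixels)
  }
})

test_that("background pixels are restored verbatim and geometry is preserved", {
  ph <- generate_phantom(small_spec(background_fraction = 0.3), 0, 2)
  dc <- decompose_stains(ph$image)
  dist <- cbcs_stain_distribution()
  out <- adapt_stain_san(dc, dist, adaptation_config("san", rng_seed = 4))
  expect_identical(dim(out$pixels), dim(ph$image$pixels))
  for (ch in 1:3) {
    src <- as.vector(t(ph$image$pixels[, , ch]))
    new <- as.vector(t(out$pixels[, , ch]))
    expect_identical(new[dc$mask], src[dc$mask])
  }
  # adapted image is a valid 8-bit raster
  expect_true(all(out$pixels >= 0L & out$pixels <= 255L))
})

test_that("san draws change the stain basis but respect the distribution", {
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 1)$image)
  dist <- stain_distribution(unit_reference(), sigma = 0.05)
  cfg <- adaptation_config("san", rng_seed = 10)
  out <- adapt_stain_san(dc, dist, cfg)
  ad <- attr(out, "adaptation")
  expect_identical(adapt_stain_san(dc, dist, cfg)$pixels, out$pixels)
  expect_true(all(abs(ad$W_prime - dist$W0) < 5 * dist$sigma))
  expect_true(ad$alpha >= 0.8 && ad$alpha <= 1.2)
})

test_that("normalization replaces the effective basis with the reference", {
  ref <- unit_reference()
  cfg <- adaptation_config("normalize", percentile_rescale = NULL)
  for (idx in 1:2) {
    ph <- generate_phantom(small_spec(domain_spread = 0.05), 1, idx)
    dc <- decompose_stains(ph$image)
    out <- adapt_normalize(dc, ref, cfg)
    re <- decompose_stains(out)
    expect_lt(max(stain_angles(re$W, ref)), 1.5)  # extraction tolerance
  }

  # reference = own W, rescale off: identity adaptation
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 3)$image)
  out <- adapt_normalize(dc, dc$W, cfg)
  expect_identical(out$pixels, reconstruct_adapted(dc)$pixels)
})

test_that("percentile rescale aligns intensity rows with the reference", {
  spec <- small_spec(domain_spread = 0.04)
  ref_dc <- decompose_stains(generate_phantom(spec, 0, 1)$image)
  ref_p <- intensity_percentiles(ref_dc, 99)
  dc <- decompose_stains(generate_phantom(spec, 1, 2)$image)
  cfg <- adaptation_config("normalize", percentile_rescale = 99)
  out <- adapt_normalize(dc, ref_dc$W, cfg, reference_percentiles = ref_p)
  re <- decompose_stains(out)
  expect_equal(intensity_percentiles(re, 99), ref_p, tolerance = 0.05)
  expect_warning(
    adapt_normalize(dc, ref_dc$W, cfg, reference_percentiles = c(0, 1)),
    "rescale skipped")
})

test_that("augmentation stays in its support box and degenerates to identity", {
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 1)$image)
  cfg0 <- adaptation_config("augment", epsilon1 = 0, epsilon2 = 0)
  expect_identical(adapt_augment(dc, cfg0)$pixels,
                   reconstruct_adapted(dc)$pixels)

  for (seed in 1:10) {
    cfg <- adaptation_config("augment", rng_seed = seed)  # eps1 = eps2 = 0.2
    ad <- attr(adapt_augment(dc, cfg), "adaptation")
    lo <- pmax(0.8 * dc$W - 0.2, 0)
    hi <- 1.2 * dc$W + 0.2
    expect_true(all(ad$W_prime >= lo - 1e-12 & ad$W_prime <= hi + 1e-12))
    expect_true(all(ad$alpha_i >= 0.8 & ad$alpha_i <= 1.2))
    expect_true(all(abs(ad$beta_i) <= 0.2))
  }
})

test_that("the printed-beta convention shifts columns by alpha_i W + 1", {
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 1)$image)
  cfg <- adaptation_config("augment", epsilon2 = 0,
                           augment_beta_as_printed = TRUE, rng_seed = 2)
  ad <- attr(adapt_augment(dc, cfg), "adaptation")
  expect_equal(ad$W_prime,
               sweep(sweep(dc$W, 2, ad$alpha_i, "*"), 2, rep(1, 2), "+"),
               tolerance = 1e-12)
})

test_that("augmentation is a no-op warning at test time", {
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 1)$image)
  cfg <- adaptation_config("augment", role = "test")
  expect_warning(out <- adapt_augment(dc, cfg), "test images")
  expect_identical(out$pixels, reconstruct_adapted(dc)$pixels)
})

test_that("mix-up interpolates between the two stain matrices", {
  dc <- decompose_stains(generate_phantom(small_spec(), 0, 1)$image)
  Wk <- unit_reference()
  cfg <- adaptation_config("mixup", epsilon = 0)
  out0 <- adapt_mixup(dc, Wk, cfg, u = 0)
  expect_identical(attr(out0, "adaptation")$W_prime, dc$W)
  expect_identical(out0$pixels, reconstruct_adapted(dc)$pixels)
  out1 <- adapt_mixup(dc, Wk, cfg, u = 1)
  expect_identical(attr(out1, "adaptation")$W_prime, Wk)
  expect_identical(out1$pixels, reconstruct_adapted(dc, Wk, dc$H)$pixels)

  cfg_r <- adaptation_config("mixup", rng_seed = 6)
  Wp <- attr(adapt_mixup(dc, Wk, cfg_r), "adaptation")$W_prime
  expect_true(all(Wp >= pmin(dc$W, Wk) - 1e-12 & Wp <= pmax(dc$W, Wk) + 1e-12))
  expect_error(adapt_mixup(dc, matrix(1, 3, 3), cfg_r), "m = 3")
})

test_that("batch adaptation is seeded, self-fitting, and validates inputs", {
  spec <- small_spec(n_images = 5, domain_spread = 0.04)
  imgs <- lapply(1:5, function(i) generate_phantom(spec, 0, i)$image)
  cfg <- adaptation_config("san", role = "train")
  b1 <- adapt_batch(imgs, cfg, rng_seed = 3)
  b2 <- adapt_batch(imgs, cfg, rng_seed = 3)
  for (i in 1:5) expect_identical(b1[[i]]$pixels, b2[[i]]$pixels)
  expect_length(attr(b1, "manifest"), 5)
  expect_s3_class(attr(b1, "dist"), "stain_distribution")

  expect_error(adapt_batch(imgs, adaptation_config("mixup")), "other_batch")
  expect_error(adapt_batch(imgs, adaptation_config("san", role = "test")),
               "fitted stain distribution")

  # san test batch: every image normalized onto the same W0
  dist <- cbcs_stain_distribution()
  bt <- adapt_batch(imgs[1:2], adaptation_config("san", role = "test"),
                    dist = dist)
  for (rec in attr(bt, "manifest")) expect_identical(rec$W_prime, dist$W0)

  # mixup with a partner batch runs end to end
  other <- lapply(1:2, function(i) generate_phantom(spec, 1, i)$image)
  bm <- adapt_batch(imgs[1:2], adaptation_config("mixup"),
                    other_batch = other, rng_seed = 8)
  expect_length(bm, 2)
  expect_true(all(vapply(bm, is_rgb_image, logical(1))))
})
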