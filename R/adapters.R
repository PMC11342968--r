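#' Adaptation configuration
#'
#' Bundles every tunable of the adaptation pipeline. The three perturbation
#' amplitudes default to 0.2, the setting used for all methods in the
#' original cross-dataset experiments; the OD background threshold defaults
#' to 0.3.
#'
#' @param method One of \code{"san"}, \code{"normalize"}, \code{"augment"},
#'   \code{"mixup"}.
#' @param role \code{"train"} (stochastic adaptation) or \code{"test"}
#'   (deterministic normalization onto the target mean).
#' @param epsilon Half-width of the uniform intensity perturbation
#'   \code{alpha ~ U(1 - epsilon, 1 + epsilon)} applied to H (san, mixup);
#'   must lie in \code{[0, 1)} so alpha stays positive.
#' @param epsilon1,epsilon2 Per-channel multiplicative / additive amplitudes
#'   for stain augmentation; in \code{[0, 1)}.
#' @param mask_threshold OD norm at or below which a pixel is background.
#' @param incident_intensity Beer-Lambert incident intensity I0.
#' @param angle_percentile Robust-extreme percentile for stain extraction.
#' @param percentile_rescale Percentile (in \code{(0, 100]}) used to rescale
#'   intensity rows during normalization, or \code{NULL} to disable.
#' @param rng_seed Optional integer seed making every random draw
#'   reproducible.
#' @param augment_beta_as_printed If \code{TRUE}, the additive augmentation
#'   offset is drawn as \code{U(1 - epsilon2, 1 + epsilon2)} (a shift near
#'   +1 OD); the default \code{FALSE} draws the zero-centered
#'   \code{U(-epsilon2, +epsilon2)}.
#' @param clip_floor RGB floor applied before the log (keeps OD finite).
#' @param min_foreground Minimum foreground pixels required for extraction.
#' @param intensity_solver \code{"pinv"} (least squares, negatives clipped)
#'   or \code{"nnls"} (exact two-stain non-negative least squares).
#' @return An object of class \code{"adaptation_config"}.
#' @export
adaptation_config <- function(method = c("san", "normalize", "augment", "mixup"),
                              role = c("train", "test"),
                              epsilon = 0.2, epsilon1 = 0.2, epsilon2 = 0.2,
                              mask_threshold = 0.3, incident_intensity = 255,
                              angle_percentile = 1, percentile_rescale = 99,
                              rng_seed = NULL,
                              augment_beta_as_printed = FALSE,
                              clip_floor = 1, min_foreground = 100,
                              intensity_solver = c("pinv", "nnls")) {
  method <- match.arg(method)
  role <- match.arg(role)
  for (nm in c("epsilon", "epsilon1", "epsilon2")) {
    e <- get(nm)
    if (!is.numeric(e) || length(e) != 1L || e < 0 || e >= 1) {
      stop("`", nm, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  if (!is.null(percentile_rescale) &&
      (percentile_rescale <= 0 || percentile_rescale > 100)) {
    stop("`percentile_rescale` must be in (0, 100] or NULL", call. = FALSE)
  }
  structure(list(method = method, role = role, epsilon = epsilon,
                 epsilon1 = epsilon1, epsilon2 = epsilon2,
                 mask_threshold = mask_threshold,
                 incident_intensity = incident_intensity,
                 angle_percentile = angle_percentile,
                 percentile_rescale = percentile_rescale,
                 rng_seed = rng_seed,
                 augment_beta_as_printed = augment_beta_as_printed,
                 clip_floor = clip_floor, min_foreground = min_foreground,
                 intensity_solver = match.arg(intensity_solver)),
            class = "adaptation_config")
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# deterministic per-item sub-stream, kept below 2^31 - 1
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) + 48271 * as.numeric(index)) %% 2147483647)
}

#' Reconstruct an adapted RGB image from new stain factors
#'
#' Forms \code{OD' = W' H'}, inverts the Beer-Lambert transform, and
#' restores every background-masked pixel verbatim from the source raster
#' (hidden pixels take no part in adaptation).
#'
#' @param decomp A \code{stain_decomposition}.
#' @param W New \code{3 x m} stain color matrix (defaults to the original).
#' @param H New \code{m x d} intensity matrix (defaults to the original).
#' @return An [rgb_image()].
#' @export
reconstruct_adapted <- function(decomp, W = decomp$W, H = decomp$H) {
  stopifnot(inherits(decomp, "stain_decomposition"))
  if (ncol(W) != nrow(H)) stop("W / H stain-count mismatch", call. = FALSE)
  od_new <- W %*% H
  od_new[od_new < 0] <- 0
  h <- decomp$shape[1]; w <- decomp$shape[2]
  bg <- decomp$mask
  px <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    v <- round(decomp$I0 * exp(-od_new[ch, ]))
    v <- pmin(pmax(v, 0), 255)
    src <- as.vector(t(decomp$source_pixels[, , ch]))
    v[bg] <- src[bg]
    px[, , ch] <- t(matrix(v, nrow = w, ncol = h))
  }
  rgb_image(px, I0 = decomp$I0)
}

#' Globally perturb a stain intensity matrix
#'
#' Multiplies every entry of H by a single scalar
#' \code{alpha ~ Uniform(1 - epsilon, 1 + epsilon)} drawn once per image
#' (one alpha shared across both stain channels).
#'
#' @param intensities \code{m x d} intensity matrix.
#' @param epsilon Amplitude in \code{[0, 1)}; 0 returns the input unchanged.
#' @param rng_seed Optional integer seed.
#' @return The perturbed matrix, with the drawn alpha attached as attribute
#'   \code{"alpha"}.
#' @export
perturb_intensity <- function(intensities, epsilon = 0.2, rng_seed = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 1) {
    stop("`epsilon` must lie in [0, 1): alpha must stay positive",
         call. = FALSE)
  }
  if (epsilon == 0) {
    attr(intensities, "alpha") <- 1
    return(intensities)
  }
  alpha <- with_optional_seed(rng_seed,
                              stats::runif(1, 1 - epsilon, 1 + epsilon))
  out <- alpha * intensities
  attr(out, "alpha") <- alpha
  out
}

#' Stain SAN adaptation of a single image
#'
#' Training images get a stain color matrix resampled from the target
#' Gaussian and a globally perturbed intensity matrix; test images are
#' normalized deterministically onto the distribution mean \code{W0} (a
#' zero-variance resample) with intensities untouched. Background pixels
#' are restored verbatim.
#'
#' @param decomp A \code{stain_decomposition}.
#' @param dist A [stain_distribution()].
#' @param config An [adaptation_config()] with \code{method = "san"}.
#' @return An [rgb_image()] with an \code{"adaptation"} attribute recording
#'   the drawn quantities.
#' @export
adapt_stain_san <- function(decomp, dist, config = adaptation_config("san")) {
  stopifnot(inherits(decomp, "stain_decomposition"),
            inherits(dist, "stain_distribution"))
  if (config$method != "san") stop("config$method must be 'san'", call. = FALSE)
  if (ncol(decomp$W) != dist$m) {
    stop("stain-count mismatch: decomposition has m = ", ncol(decomp$W),
         ", distribution has m = ", dist$m, call. = FALSE)
  }
  if (config$role == "train") {
    draws <- with_optional_seed(config$rng_seed, {
      Wp <- sample_color_matrix(dist)
      Hp <- perturb_intensity(decomp$H, config$epsilon)
      list(W = Wp, H = Hp, alpha = attr(Hp, "alpha"))
    })
    out <- reconstruct_adapted(decomp, draws$W, draws$H)
    attr(out, "adaptation") <- list(method = "san", role = "train",
                                    W_prime = draws$W, alpha = draws$alpha)
  } else {
    out <- reconstruct_adapted(decomp, dist$W0, decomp$H)
    attr(out, "adaptation") <- list(method = "san", role = "test",
                                    W_prime = dist$W0, alpha = 1)
  }
  out
}

#' Percentiles of stain intensity rows over foreground pixels
#'
#' @param decomp A \code{stain_decomposition}.
#' @param percentile Percentile in \code{(0, 100]}; default 99.
#' @return Numeric vector of length m (one value per stain row).
#' @export
intensity_percentiles <- function(decomp, percentile = 99) {
  fg <- !decomp$mask
  apply(decomp$H[, fg, drop = FALSE], 1L,
        stats::quantile, probs = percentile / 100, names = FALSE)
}

#' Stain normalization onto a fixed reference matrix
#'
#' Replaces the image's stain color matrix with a common reference; when
#' \code{config$percentile_rescale} is set and reference percentiles are
#' supplied, each intensity row is rescaled so its foreground percentile
#' matches the reference's.
#'
#' @param decomp A \code{stain_decomposition}.
#' @param reference A \code{3 x m} matrix or a [stain_distribution()] (its
#'   mean is used).
#' @param config An [adaptation_config()].
#' @param reference_percentiles Optional length-m vector of target row
#'   percentiles, typically [intensity_percentiles()] of a reference image
#'   or batch, stored at fit time.
#' @return An [rgb_image()].
#' @export
adapt_normalize <- function(decomp, reference,
                            config = adaptation_config("normalize"),
                            reference_percentiles = NULL) {
  stopifnot(inherits(decomp, "stain_decomposition"))
  W_ref <- if (inherits(reference, "stain_distribution")) reference$W0 else reference
  W_ref <- validate_stain_colors(as.matrix(W_ref), m = ncol(decomp$W))
  H <- decomp$H
  if (!is.null(config$percentile_rescale) && !is.null(reference_percentiles)) {
    own <- intensity_percentiles(decomp, config$percentile_rescale)
    for (i in seq_len(nrow(H))) {
      if (reference_percentiles[i] <= 0 || own[i] <= 0) {
        warning("row ", i, " percentile is zero; intensity rescale skipped",
                call. = FALSE)
        next
      }
      H[i, ] <- H[i, ] * reference_percentiles[i] / own[i]
    }
  }
  out <- reconstruct_adapted(decomp, W_ref, H)
  attr(out, "adaptation") <- list(method = "normalize", role = config$role,
                                  W_prime = W_ref, alpha = 1)
  out
}

#' Per-channel stain augmentation
#'
#' Training-time perturbation of the stain color matrix: column i becomes
#' \code{alpha_i * W[, i] + beta_i} with \code{alpha_i ~ U(1 - epsilon1,
#' 1 + epsilon1)} and, by default, \code{beta_i ~ U(-epsilon2, +epsilon2)}
#' (set \code{augment_beta_as_printed = TRUE} in the config for the
#' \code{U(1 - epsilon2, 1 + epsilon2)} convention). Entries are clipped at
#' zero; intensities are untouched. Test images are returned unchanged
#' (identity reconstruction) with a warning: augmentation is a
#' training-only device.
#'
#' @param decomp A \code{stain_decomposition}.
#' @param config An [adaptation_config()] with \code{method = "augment"}.
#' @return An [rgb_image()].
#' @export
adapt_augment <- function(decomp, config = adaptation_config("augment")) {
  stopifnot(inherits(decomp, "stain_decomposition"))
  if (config$method != "augment") stop("config$method must be 'augment'", call. = FALSE)
  if (config$role == "test") {
    warning("stain augmentation does not alter test images; ",
            "returning the identity reconstruction", call. = FALSE)
    out <- reconstruct_adapted(decomp)
    attr(out, "adaptation") <- list(method = "augment", role = "test",
                                    W_prime = decomp$W, alpha = 1)
    return(out)
  }
  m <- ncol(decomp$W)
  draws <- with_optional_seed(config$rng_seed, {
    a <- stats::runif(m, 1 - config$epsilon1, 1 + config$epsilon1)
    b <- if (config$augment_beta_as_printed) {
      stats::runif(m, 1 - config$epsilon2, 1 + config$epsilon2)
    } else {
      stats::runif(m, -config$epsilon2, config$epsilon2)
    }
    list(a = a, b = b)
  })
  Wp <- decomp$W
  for (i in seq_len(m)) Wp[, i] <- draws$a[i] * Wp[, i] + draws$b[i]
  Wp[Wp < 0] <- 0
  out <- reconstruct_adapted(decomp, Wp, decomp$H)
  attr(out, "adaptation") <- list(method = "augment", role = "train",
                                  W_prime = Wp, alpha_i = draws$a,
                                  beta_i = draws$b)
  out
}

#' Stain mix-up between a source image and a partner stain matrix
#'
#' Replaces W with the random convex combination
#' \code{W' = (1 - u) W_j + u W_k}, \code{u ~ Uniform(0, 1)} (one u per
#' image), and globally perturbs H.
#'
#' @param decomp Source \code{stain_decomposition} (provides \code{W_j},
#'   \code{H_j}).
#' @param other_colors \code{3 x m} stain matrix \code{W_k} extracted from a
#'   partner image in the opposite batch.
#' @param config An [adaptation_config()] with \code{method = "mixup"}.
#' @param u Optional forced interpolation weight in \code{[0, 1]} (bypasses
#'   the random draw; used for endpoint checks).
#' @return An [rgb_image()].
#' @export
adapt_mixup <- function(decomp, other_colors,
                        config = adaptation_config("mixup"), u = NULL) {
  stopifnot(inherits(decomp, "stain_decomposition"))
  Wk <- validate_stain_colors(as.matrix(other_colors), m = ncol(decomp$W))
  draws <- with_optional_seed(config$rng_seed, {
    uu <- if (is.null(u)) stats::runif(1) else u
    Hp <- perturb_intensity(decomp$H, config$epsilon)
    list(u = uu, H = Hp, alpha = attr(Hp, "alpha"))
  })
  Wp <- (1 - draws$u) * decomp$W + draws$u * Wk
  out <- reconstruct_adapted(decomp, Wp, draws$H)
  attr(out, "adaptation") <- list(method = "mixup", role = config$role,
                                  W_prime = Wp, u = draws$u,
                                  alpha = draws$alpha)
  out
}

#' Adapt a batch of images
#'
#' Orchestrates decomposition and adaptation over a list of images with
#' per-image independent randomness derived from one seed (sub-streams are
#' keyed by image index, so results are stable under batch growth). For
#' \code{method = "san"} with \code{role = "train"} and no distribution
#' given, the target distribution is first fitted on the batch itself; for
#' \code{"normalize"} with no reference, the element-wise median of the
#' batch's stain matrices is used; \code{"mixup"} pairs every image with a
#' uniformly chosen partner from \code{other_batch}.
#'
#' @param images List of [rgb_image()] objects.
#' @param config An [adaptation_config()].
#' @param dist Optional [stain_distribution()] (required for san at test
#'   time).
#' @param other_batch List of partner images (required for mixup).
#' @param reference Optional reference matrix for normalization.
#' @param rng_seed Base seed; defaults to \code{config$rng_seed}, else 1.
#' @return List of adapted [rgb_image()] objects; attribute
#'   \code{"manifest"} holds per-image records of the drawn quantities, and
#'   attribute \code{"dist"} the distribution used (san only).
#' @export
adapt_batch <- function(images, config, dist = NULL, other_batch = NULL,
                        reference = NULL, rng_seed = NULL) {
  stopifnot(is.list(images), length(images) > 0L,
            inherits(config, "adaptation_config"))
  if (is.null(rng_seed)) rng_seed <- if (is.null(config$rng_seed)) 1L else config$rng_seed
  decomps <- lapply(images, decompose_stains, config = config)

  partner_W <- NULL
  if (config$method == "san") {
    if (is.null(dist)) {
      if (config$role != "train") {
        stop("configuration error: method 'san' with role 'test' requires a ",
             "fitted stain distribution (`dist`)", call. = FALSE)
      }
      dist <- estimate_stain_distribution(lapply(decomps, `[[`, "W"))
    }
  } else if (config$method == "mixup") {
    if (is.null(other_batch)) {
      stop("configuration error: method 'mixup' requires `other_batch` ",
           "(images from the opposite dataset)", call. = FALSE)
    }
    partner_W <- lapply(other_batch, function(im) decompose_stains(im, config)$W)
  } else if (config$method == "normalize" && is.null(reference)) {
    reference <- if (!is.null(dist)) dist$W0 else {
      estimate_stain_distribution(lapply(decomps, `[[`, "W"))$W0
    }
  }

  out <- vector("list", length(images))
  manifest <- vector("list", length(images))
  for (i in seq_along(images)) {
    cfg_i <- config
    cfg_i$rng_seed <- derive_seed(rng_seed, i)
    img <- switch(config$method,
      san = adapt_stain_san(decomps[[i]], dist, cfg_i),
      normalize = adapt_normalize(decomps[[i]], reference, cfg_i),
      augment = adapt_augment(decomps[[i]], cfg_i),
      mixup = {
        k <- with_optional_seed(derive_seed(rng_seed, 1000000L + i),
                                sample.int(length(partner_W), 1L))
        adapt_mixup(decomps[[i]], partner_W[[k]], cfg_i)
      })
    manifest[[i]] <- c(list(index = i, seed = cfg_i$rng_seed),
                       attr(img, "adaptation"))
    out[[i]] <- img
  }
  attr(out, "manifest") <- manifest
  if (config$method == "san") attr(out, "dist") <- dist
  out
}
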