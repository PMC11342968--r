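#' Rotate stain vectors within the positive octant
#'
#' Rotates each unit column of \code{W} by \code{degrees} towards a target
#' direction (default the red axis, mimicking a batch with a more reddish
#' hue), staying in the plane spanned by the column and the target. Used to
#' construct a second stain domain at a known angular distance from a first.
#'
#' @param W \code{3 x m} matrix with unit columns.
#' @param degrees Rotation angle per column, in degrees.
#' @param toward Unit-ish 3-vector defining the rotation plane.
#' @return A \code{3 x m} matrix with unit columns; errors if any rotated
#'   column leaves the non-negative octant.
#' @export
rotate_stain_matrix <- function(W, degrees, toward = c(1, 0, 0)) {
  th <- degrees * pi / 180
  out <- W
  for (j in seq_len(ncol(W))) {
    wj <- W[, j] / sqrt(sum(W[, j]^2))
    t_orth <- toward - sum(toward * wj) * wj
    nrm <- sqrt(sum(t_orth^2))
    if (nrm < 1e-9) stop("rotation target is collinear with column ", j, call. = FALSE)
    t_orth <- t_orth / nrm
    v <- cos(th) * wj + sin(th) * t_orth
    if (any(v < -1e-12)) {
      stop("rotation by ", degrees, " degrees leaves the non-negative octant ",
           "for column ", j, call. = FALSE)
    }
    out[, j] <- pmax(v, 0)
  }
  out
}

#' Default two-domain stain centers
#'
#' Domain 0 is the packaged CBCS reference mean with columns normalized to
#' exact unit length; domain 1 rotates both columns by \code{gap_degrees}
#' towards red, emulating the purple-vs-reddish contrast seen between
#' H&E batches stained in different labs.
#'
#' @param gap_degrees Angular gap per column; default 12.
#' @return List of two \code{3 x 2} unit-column matrices.
#' @export
default_domain_centers <- function(gap_degrees = 12) {
  W0 <- cbcs_stain_distribution()$W0
  W0 <- sweep(W0, 2L, sqrt(colSums(W0^2)), "/")
  list(W0, rotate_stain_matrix(W0, gap_degrees))
}

#' Specification of a two-domain phantom study
#'
#' Defines synthetic H&E-like image batches with known ground truth: each
#' image's true stain color matrix is its domain center jittered entrywise
#' by a Gaussian of sd \code{domain_spread} and re-normalized to unit
#' columns; intensity fields combine flat-top disk "nuclei" (stain channel
#' 1, hematoxylin-like) with smooth low-frequency "stroma" texture (channel
#' 2, eosin-like) and a white background band of zero optical density. The
#' disk cores are purely channel 1 and the stroma-only areas purely channel
#' 2, so the OD point cloud densely covers the angular range between the
#' two stain rays — the geometry percentile-based extraction needs.
#'
#' @param n_images Images per domain; default 20.
#' @param image_size \code{c(height, width)} in pixels; default 128 x 128.
#' @param domain_centers List of two \code{3 x 2} unit-column, non-negative
#'   matrices; default [default_domain_centers()] (12 degree gap).
#' @param domain_spread Per-entry Gaussian jitter sd applied to each image's
#'   true W before column re-normalization; default 0.05, matching the
#'   scale of the packaged reference sigma.
#' @param nuclei_density Fraction of foreground area covered by nuclei
#'   disks, in \code{(0, 1)}; default 0.15.
#' @param background_fraction Fraction of image width devoted to the white
#'   background band, in \code{[0, 1]}; default 0.25.
#' @param intensity_scale Positive scale of the intensity fields; default 1
#'   keeps every foreground pixel's OD norm comfortably above the 0.3
#'   background threshold.
#' @param rng_seed Base seed; every phantom derives a sub-stream from it.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(n_images = 20, image_size = c(128, 128),
                         domain_centers = default_domain_centers(),
                         domain_spread = 0.05, nuclei_density = 0.15,
                         background_fraction = 0.25, intensity_scale = 1,
                         rng_seed = 1) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16))
  if (!is.list(domain_centers) || length(domain_centers) != 2L) {
    stop("`domain_centers` must be a list of two 3 x 2 matrices", call. = FALSE)
  }
  for (W in domain_centers) {
    validate_stain_colors(W)
    if (any(abs(colSums(W^2) - 1) > 1e-6)) {
      stop("domain center columns must have unit norm", call. = FALSE)
    }
  }
  if (nuclei_density <= 0 || nuclei_density >= 1) {
    stop("`nuclei_density` must lie in (0, 1)", call. = FALSE)
  }
  if (background_fraction < 0 || background_fraction > 1) {
    stop("`background_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (domain_spread < 0) stop("`domain_spread` must be >= 0", call. = FALSE)
  if (intensity_scale <= 0) stop("`intensity_scale` must be > 0", call. = FALSE)
  structure(list(n_images = n_images, image_size = as.integer(image_size),
                 domain_centers = domain_centers,
                 domain_spread = domain_spread,
                 nuclei_density = nuclei_density,
                 background_fraction = background_fraction,
                 intensity_scale = intensity_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

bilinear_resize <- function(m, h, w) {
  k1 <- nrow(m); k2 <- ncol(m)
  xr <- seq(1, k1, length.out = h)
  xc <- seq(1, k2, length.out = w)
  cols <- apply(m, 2L, function(col) stats::approx(seq_len(k1), col, xout = xr)$y)
  t(apply(matrix(cols, nrow = h), 1L, function(row)
    stats::approx(seq_len(k2), row, xout = xc)$y))
}

# flat-top radial profile: 1 inside 0.6 R, cosine taper to 0 at R
disk_profile <- function(r, R) {
  p <- numeric(length(r))
  p[r <= 0.6 * R] <- 1
  taper <- r > 0.6 * R & r < R
  p[taper] <- 0.5 * (1 + cos(pi * (r[taper] - 0.6 * R) / (0.4 * R)))
  p
}

#' Generate one phantom image with its ground truth
#'
#' @param spec A [phantom_spec()].
#' @param domain 0 (train-like) or 1 (test-like).
#' @param index Image index within the domain (1-based); together with
#'   \code{spec$rng_seed} and \code{domain} it fixes the sub-stream, so the
#'   same triple always yields a bit-identical phantom.
#' @return List with \code{image} (an [rgb_image()]), \code{W} (true
#'   \code{3 x 2} unit stain matrix) and \code{H} (true \code{2 x d}
#'   intensities, row-major pixel order).
#' @export
generate_phantom <- function(spec, domain, index) {
  stopifnot(inherits(spec, "phantom_spec"), domain %in% c(0, 1))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  seed_i <- derive_seed(spec$rng_seed, domain * 1000003 + index)
  withr::with_seed(seed_i, {
    center <- spec$domain_centers[[domain + 1L]]
    W <- center
    if (spec$domain_spread > 0) {
      W <- W + matrix(stats::rnorm(6, sd = spec$domain_spread), 3L, 2L)
      W[W < 0] <- 0
      W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    }

    n_bg_cols <- round(spec$background_fraction * w)
    fg_w <- w - n_bg_cols
    g <- matrix(0, h, w)     # nuclei field
    s <- matrix(0, h, w)     # stroma field
    if (fg_w > 0) {
      k <- max(3L, round(min(h, fg_w) / 16))
      coarse <- matrix(stats::runif(k * k), k, k)
      s[, seq_len(fg_w)] <- 0.55 + 0.45 * bilinear_resize(coarse, h, fg_w)

      R <- max(3, round(min(h, fg_w) / 16))
      if (fg_w > 2 * R + 2 && h > 2 * R + 2) {
        n_disks <- max(1L, round(spec$nuclei_density * h * fg_w / (pi * R^2)))
        ci <- stats::runif(n_disks, 1 + R, h - R)
        cj <- stats::runif(n_disks, 1 + R, fg_w - R)
        for (dsk in seq_len(n_disks)) {
          i0 <- max(1L, floor(ci[dsk] - R)); i1 <- min(h, ceiling(ci[dsk] + R))
          j0 <- max(1L, floor(cj[dsk] - R)); j1 <- min(w, ceiling(cj[dsk] + R))
          sub_r <- sqrt(outer((i0:i1) - ci[dsk], (j0:j1) - cj[dsk],
                              function(a, b) a^2 + b^2))
          g[i0:i1, j0:j1] <- pmax(g[i0:i1, j0:j1], disk_profile(sub_r, R))
        }
      }
    }
    H1 <- spec$intensity_scale * 1.2 * g
    H2 <- spec$intensity_scale * 0.9 * s * (1 - g)
    # true H in row-major pixel order, matching the OD flattening convention
    H <- rbind(as.vector(t(H1)), as.vector(t(H2)))
    od <- W %*% H
    px <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) {
      v <- pmin(pmax(round(255 * exp(-od[ch, ])), 0), 255)
      px[, , ch] <- t(matrix(v, nrow = w, ncol = h))
    }
    list(image = rgb_image(px), W = W, H = H)
  })
}

#' Generate a full two-domain phantom study
#'
#' Domain 0 is the training batch, domain 1 the test batch; every image
#' comes with its ground-truth stain factors, and the manifest echoes the
#' spec plus the configured per-column angular gap between the two domain
#' centers.
#'
#' @param spec A [phantom_spec()].
#' @return List with \code{train} and \code{test} (each a list of
#'   \code{generate_phantom} outputs) and \code{manifest} (spec echo,
#'   per-column \code{gap_degrees}).
#' @export
generate_two_domain_study <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  train <- lapply(seq_len(spec$n_images), function(i) generate_phantom(spec, 0, i))
  test <- lapply(seq_len(spec$n_images), function(i) generate_phantom(spec, 1, i))
  gap <- stain_angles(spec$domain_centers[[1]], spec$domain_centers[[2]])
  list(train = train, test = test,
       manifest = list(spec = spec, gap_degrees = gap))
}
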