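#' Extract the stain color matrix by the SVD plane-and-angle method
#'
#' Estimates the \code{3 x 2} matrix of unit H&E stain vectors from the
#' foreground OD point cloud. The top two singular directions of the cloud
#' define a plane; each foreground pixel gets an angle in that plane; the
#' \code{angle_percentile}-th and \code{(100 - angle_percentile)}-th
#' percentile angles define the two extreme directions, which are mapped back
#' to 3-space, sign-fixed into the non-negative octant, normalized to unit
#' columns and ordered hematoxylin-first (larger blue-channel component).
#'
#' @param od_image An \code{od_image} after [mask_background()].
#' @param angle_percentile Robust-extreme percentile in \code{(0, 50)};
#'   default 1 (1st/99th percentile angles).
#' @param min_foreground Minimum number of foreground pixels required for a
#'   stable plane fit; default 100.
#' @return A \code{3 x 2} matrix with unit, non-negative columns (column 1 =
#'   hematoxylin, column 2 = eosin).
#' @export
extract_stain_colors <- function(od_image, angle_percentile = 1,
                                 min_foreground = 100) {
  stopifnot(inherits(od_image, "od_image"))
  if (angle_percentile <= 0 || angle_percentile >= 50) {
    stop("`angle_percentile` must lie in (0, 50)", call. = FALSE)
  }
  fg <- !od_image$background_mask
  n_fg <- sum(fg)
  if (n_fg < min_foreground) {
    stop("degenerate input: only ", n_fg, " foreground pixels (need >= ",
         min_foreground, ")", call. = FALSE)
  }
  X <- od_image$od[, fg, drop = FALSE]

  sv <- svd(X, nu = 2, nv = 0)
  if (sv$d[2] <= sv$d[1] * 1e-8) {
    stop("degenerate stain geometry: foreground OD pixels are collinear ",
         "(single stain); no plane spans the cloud", call. = FALSE)
  }
  U <- sv$u
  # orient plane axes so projections sit in the right half-plane
  proj <- crossprod(U, X)                 # 2 x n
  if (mean(proj[1, ]) < 0) { U[, 1] <- -U[, 1]; proj[1, ] <- -proj[1, ] }
  if (mean(proj[2, ]) < 0) { U[, 2] <- -U[, 2]; proj[2, ] <- -proj[2, ] }

  phi <- atan2(proj[2, ], proj[1, ])
  q <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                       names = FALSE, type = 7)
  if (abs(q[2] - q[1]) < 1e-6) {
    stop("degenerate stain geometry: foreground OD angles collapse to a ",
         "single ray (single stain)", call. = FALSE)
  }
  cols <- sapply(q, function(a) U %*% c(cos(a), sin(a)))

  # map into the non-negative octant and normalize
  for (j in 1:2) {
    if (sum(cols[, j]) < 0) cols[, j] <- -cols[, j]
    cols[, j] <- pmax(cols[, j], 0)
    nrm <- sqrt(sum(cols[, j]^2))
    if (nrm < 1e-12) {
      stop("degenerate stain geometry: extreme direction has no component ",
           "in the non-negative octant", call. = FALSE)
    }
    cols[, j] <- cols[, j] / nrm
  }
  order_hematoxylin_first(cols)
}

#' Order stain columns hematoxylin-first
#'
#' Hematoxylin colors nuclei blue-purple because it absorbs red light, so
#' its OD vector carries the larger red-channel component (0.544 vs 0.141
#' in the packaged reference); eosin transmits red and absorbs green/blue.
#' The column with the larger first entry is placed first.
#'
#' @param W A \code{3 x 2} stain color matrix.
#' @return \code{W} with columns possibly swapped.
#' @export
order_hematoxylin_first <- function(W) {
  if (W[1, 1] < W[1, 2]) W <- W[, c(2L, 1L), drop = FALSE]
  unname(W)
}

validate_stain_colors <- function(W, m = 2L) {
  if (!is.matrix(W) || nrow(W) != 3L) {
    stop("stain color matrix must be 3 x m", call. = FALSE)
  }
  if (ncol(W) != m) {
    if (m == 2L && ncol(W) == 3L) {
      stop("m = 3 stain separation is not implemented; this package fixes ",
           "m = 2 (hematoxylin and eosin)", call. = FALSE)
    }
    stop("stain color matrix must have ", m, " columns", call. = FALSE)
  }
  if (anyNA(W) || any(!is.finite(W))) stop("stain colors must be finite", call. = FALSE)
  if (any(W < 0)) stop("stain colors must be non-negative", call. = FALSE)
  W
}

#' Solve for stain intensities given a stain color matrix
#'
#' Finds \code{H >= 0} with \code{V ~ W H} for every pixel (foreground and
#' background alike, so reconstruction is defined everywhere). The default
#' solver computes the unconstrained least-squares solution through the
#' pseudo-inverse and clips negatives to zero; \code{solver = "nnls"} solves
#' the exact two-variable non-negative least-squares problem per pixel in
#' closed form.
#'
#' @param od_image An \code{od_image} (mask ignored; all pixels solved).
#' @param colors A \code{3 x 2} stain color matrix.
#' @param solver \code{"pinv"} (default) or \code{"nnls"}.
#' @return A \code{2 x d} non-negative intensity matrix.
#' @export
extract_stain_intensities <- function(od_image, colors,
                                      solver = c("pinv", "nnls")) {
  stopifnot(inherits(od_image, "od_image"))
  solver <- match.arg(solver)
  W <- validate_stain_colors(colors)
  g <- crossprod(W)                       # 2 x 2 Gram matrix
  det_g <- g[1, 1] * g[2, 2] - g[1, 2]^2
  if (det_g < 1e-10) {
    stop("ill-conditioned stain color matrix: columns are collinear",
         call. = FALSE)
  }
  V <- od_image$od
  B <- crossprod(W, V)                    # 2 x d normal-equation RHS
  H <- solve(g, B)                        # unconstrained LS
  if (solver == "pinv") {
    H[H < 0] <- 0
    return(H)
  }
  # exact NNLS for m = 2: where a coordinate goes negative, pin it at zero
  # and solve the remaining 1-D problem, keeping the better of the two fits
  neg <- H[1, ] < 0 | H[2, ] < 0
  if (any(neg)) {
    b1 <- B[1, neg]; b2 <- B[2, neg]
    h1 <- pmax(b1 / g[1, 1], 0)           # H2 pinned at 0
    h2 <- pmax(b2 / g[2, 2], 0)           # H1 pinned at 0
    # residual^2 difference reduces to comparing explained energy
    e1 <- h1 * (2 * b1 - g[1, 1] * h1)
    e2 <- h2 * (2 * b2 - g[2, 2] * h2)
    use1 <- e1 >= e2
    H[1, neg] <- ifelse(use1, h1, 0)
    H[2, neg] <- ifelse(use1, 0, h2)
  }
  H
}

#' Decompose an RGB image into stain color and intensity matrices
#'
#' Full extraction pipeline: Beer-Lambert OD transform, background masking,
#' SVD-based stain color estimation on foreground pixels, and intensity
#' solve on all pixels. Deterministic: repeated calls are bit-identical.
#'
#' @param image An [rgb_image()].
#' @param config An [adaptation_config()] supplying \code{mask_threshold},
#'   \code{angle_percentile}, \code{incident_intensity} and the intensity
#'   solver choice.
#' @return An object of class \code{"stain_decomposition"}: list with
#'   \code{W} (3 x 2 unit stain colors), \code{H} (2 x d intensities),
#'   \code{mask} (logical background mask), \code{shape}, \code{I0},
#'   \code{source_pixels} and \code{residual} (relative foreground
#'   reconstruction residual \code{||V - WH|| / ||V||}).
#' @export
decompose_stains <- function(image, config = adaptation_config()) {
  stopifnot(is_rgb_image(image))
  od <- rgb_to_od(image, clip_floor = config$clip_floor)
  od <- mask_background(od, threshold = config$mask_threshold)
  W <- extract_stain_colors(od, angle_percentile = config$angle_percentile,
                            min_foreground = config$min_foreground)
  H <- extract_stain_intensities(od, W, solver = config$intensity_solver)
  fg <- !od$background_mask
  Vf <- od$od[, fg, drop = FALSE]
  Rf <- Vf - W %*% H[, fg, drop = FALSE]
  res <- sqrt(sum(Rf^2)) / max(sqrt(sum(Vf^2)), .Machine$double.eps)
  structure(
    list(W = W, H = H, mask = od$background_mask, shape = od$shape,
         I0 = image$I0, source_pixels = image$pixels, residual = res),
    class = "stain_decomposition"
  )
}

#' @export
print.stain_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<stain_decomposition> %d x %d pixels, ",
                     "%d foreground, residual %.3g\n"),
              x$shape[1], x$shape[2], sum(!x$mask), x$residual))
  cat("W =\n"); print(round(x$W, 4))
  invisible(x)
}

#' Angular distance between stain color matrices
#'
#' Per-column angle, in degrees, between the unit-normalized columns of two
#' stain color matrices. Used to compare extracted matrices with ground
#' truth and to measure domain gaps.
#'
#' @param W1,W2 \code{3 x m} stain color matrices.
#' @return Numeric vector of \code{m} angles in degrees.
#' @export
stain_angles <- function(W1, W2) {
  stopifnot(is.matrix(W1), is.matrix(W2), all(dim(W1) == dim(W2)))
  ang <- numeric(ncol(W1))
  for (j in seq_len(ncol(W1))) {
    a <- W1[, j] / sqrt(sum(W1[, j]^2))
    b <- W2[, j] / sqrt(sum(W2[, j]^2))
    ang[j] <- acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
  }
  ang
}
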