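#' Stain color target distribution
#'
#' Container for the spherical Gaussian target distribution over vectorized
#' stain color matrices: mean \code{W0} (3 x m), scalar standard deviation
#' \code{sigma}, and the number of source matrices used in estimation.
#' Vectorization is column-stacked (hematoxylin column's three entries
#' first); the covariance trace is invariant to this choice, so it only
#' matters for serialization.
#'
#' @param W0 \code{3 x m} mean matrix.
#' @param sigma Scalar standard deviation, \code{>= 0}.
#' @param n_source Number of matrices the estimate was built from.
#' @param notes Free-text provenance note.
#' @return An object of class \code{"stain_distribution"}.
#' @export
stain_distribution <- function(W0, sigma, n_source = NA_integer_,
                               notes = "") {
  if (!is.matrix(W0) || nrow(W0) != 3L) {
    stop("`W0` must be a 3 x m matrix", call. = FALSE)
  }
  if (anyNA(W0) || any(!is.finite(W0))) stop("`W0` must be finite", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a scalar >= 0", call. = FALSE)
  }
  structure(list(W0 = unname(W0), sigma = sigma, m = ncol(W0),
                 n_source = as.integer(n_source), notes = notes),
            class = "stain_distribution")
}

#' @export
print.stain_distribution <- function(x, ...) {
  cat(sprintf("<stain_distribution> m = %d, sigma = %.4g, n_source = %s\n",
              x$m, x$sigma, ifelse(is.na(x$n_source), "?", x$n_source)))
  cat("W0 =\n"); print(round(x$W0, 4))
  invisible(x)
}

#' Estimate the energy-preserving Gaussian stain distribution
#'
#' Fits the target distribution from a batch of per-image stain color
#' matrices. The mean is the element-wise median (robust to outlying
#' images); the total variance matches the energy of the batch:
#' \code{3 m sigma^2 = Trace(Cov(vec(W)))}, with the unbiased (n - 1)
#' sample covariance. The trace of a covariance matrix equals the sum of
#' per-entry variances, so the full 3m x 3m matrix is never formed.
#'
#' @param colors_batch List of \code{3 x m} stain color matrices (length
#'   >= 2, or length 1 with an explicit \code{sigma} override).
#' @param sigma Optional explicit sigma; required to accept a batch of one.
#' @return A [stain_distribution()].
#' @export
estimate_stain_distribution <- function(colors_batch, sigma = NULL) {
  if (!is.list(colors_batch) || length(colors_batch) == 0L) {
    stop("`colors_batch` must be a non-empty list of 3 x m matrices",
         call. = FALSE)
  }
  m <- ncol(colors_batch[[1]])
  for (W in colors_batch) {
    if (!is.matrix(W) || nrow(W) != 3L || ncol(W) != m) {
      stop("all matrices in the batch must be 3 x ", m, call. = FALSE)
    }
  }
  n <- length(colors_batch)
  if (n < 2L) {
    if (is.null(sigma)) {
      stop("estimation needs a batch of >= 2 matrices; a single matrix is ",
           "allowed only with an explicit `sigma` (e.g. 0)", call. = FALSE)
    }
    return(stain_distribution(colors_batch[[1]], sigma = sigma, n_source = 1L))
  }
  M <- vapply(colors_batch, as.vector, numeric(3L * m))   # 3m x n
  W0 <- matrix(apply(M, 1L, stats::median), nrow = 3L, ncol = m)
  energy <- sum(apply(M, 1L, stats::var))                 # trace of sample cov
  sig <- sqrt(energy / (3 * m))
  if (!is.null(sigma)) sig <- sigma
  stain_distribution(W0, sigma = sig, n_source = n)
}

#' Sample a stain color matrix from the target distribution
#'
#' Draws \code{vec(W') ~ N(vec(W0), sigma^2 I)} and reshapes to 3 x m. The
#' draw is used as-is: columns are deliberately not re-normalized to unit
#' length, since re-normalization would destroy the energy-matching
#' property of the fitted distribution. Negative entries (possible in the
#' Gaussian tails, unphysical in OD space) are clipped to zero with a
#' warning.
#'
#' @param dist A [stain_distribution()].
#' @param rng_seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return A \code{3 x m} matrix.
#' @export
sample_color_matrix <- function(dist, rng_seed = NULL) {
  stopifnot(inherits(dist, "stain_distribution"))
  if (dist$sigma == 0) return(dist$W0)
  draw <- function() {
    v <- stats::rnorm(3L * dist$m, mean = as.vector(dist$W0), sd = dist$sigma)
    matrix(v, nrow = 3L, ncol = dist$m)
  }
  W <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  if (any(W < 0)) {
    warning("sampled stain matrix had ", sum(W < 0),
            " negative entries; clipped to 0", call. = FALSE)
    W[W < 0] <- 0
  }
  W
}

#' Save / load a stain distribution as JSON
#'
#' Round trip is lossless to full double precision. Schema:
#' \code{{"m": 2, "W0": [[...],[...],[...]], "sigma": x, "n_source": n,
#' "notes": "..."}} with \code{W0} as 3 rows of m values.
#'
#' @param dist A [stain_distribution()].
#' @param path JSON file path.
#' @return \code{save_stain_distribution}: the path, invisibly;
#'   \code{load_stain_distribution}: a [stain_distribution()].
#' @export
save_stain_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "stain_distribution"))
  obj <- list(m = dist$m,
              W0 = lapply(seq_len(3L), function(i) dist$W0[i, ]),
              sigma = dist$sigma, n_source = dist$n_source,
              notes = dist$notes)
  # 17 significant digits: exact binary64 round trip through decimal text
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_stain_distribution
#' @export
load_stain_distribution <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed stain-distribution JSON: ",
                                           conditionMessage(e), call. = FALSE))
  req <- c("m", "W0", "sigma")
  if (!all(req %in% names(obj))) {
    stop("stain-distribution JSON missing field(s): ",
         paste(setdiff(req, names(obj)), collapse = ", "), call. = FALSE)
  }
  W0 <- obj$W0
  if (is.list(W0)) W0 <- do.call(rbind, W0)
  W0 <- as.matrix(W0)
  if (nrow(W0) != 3L || ncol(W0) != obj$m) {
    stop("stain-distribution JSON has a ", nrow(W0), " x ", ncol(W0),
         " mean matrix; expected 3 x ", obj$m, call. = FALSE)
  }
  if (obj$m != 2L) {
    stop("only m = 2 (H&E) distributions are supported", call. = FALSE)
  }
  stain_distribution(W0, sigma = obj$sigma,
                     n_source = if (is.null(obj$n_source)) NA_integer_ else obj$n_source,
                     notes = if (is.null(obj$notes)) "" else obj$notes)
}

#' Packaged CBCS reference stain distribution
#'
#' The published H&E reference distribution estimated from the Carolina
#' Breast Cancer Study images, shipped with the package so stain adaptation
#' can be applied at the single-image level without refitting:
#' \code{W0 = [[0.544, 0.141], [0.703, 0.821], [0.455, 0.552]]},
#' \code{sigma = 0.053}.
#'
#' @return A [stain_distribution()].
#' @export
cbcs_stain_distribution <- function() {
  path <- system.file("extdata", "cbcs_stain_distribution.json",
                      package = "stainsan", mustWork = TRUE)
  load_stain_distribution(path)
}
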