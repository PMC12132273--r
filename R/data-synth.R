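#' Synthetic sparse-dictionary data specification
#'
#' Parameters of the built-in generator emulating the model's linear
#' generative assumption `x = Phi* a + noise` with sparse non-negative codes.
#'
#' @param M Pixels per patch (positive integer).
#' @param K_true Number of ground-truth dictionary elements.
#' @param code_density Probability in (0, 1] that a code entry is active.
#' @param code_scale Mean of the exponential magnitude of active entries.
#' @param noise_sigma Standard deviation of the additive Gaussian pixel
#'   noise (>= 0).
#' @param n_patches Number of patches to generate.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(M = 64L, K_true = 16L, code_density = 0.125,
                           code_scale = 2, noise_sigma = 0.05,
                           n_patches = 20000L, seed = 1L) {
  if (code_density <= 0 || code_density > 1)
    stop("code_density must be in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(M = as.integer(M), K_true = as.integer(K_true),
                 code_density = code_density, code_scale = code_scale,
                 noise_sigma = noise_sigma, n_patches = as.integer(n_patches),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

patch_dataset <- function(X, provenance, normalization = list(), ...) {
  structure(c(list(X = X, provenance = provenance,
                   normalization = normalization), list(...)),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches x %d pixels (%s)\n",
              nrow(x$X), ncol(x$X), x$provenance))
  invisible(x)
}

as_patch_matrix <- function(dataset) {
  if (inherits(dataset, "patch_dataset")) dataset$X
  else as.matrix(dataset)
}

#' Ground-truth dictionary generator
#'
#' @param M Pixels per patch; must be a perfect square for `kind = "gabor"`.
#' @param K_true Number of columns.
#' @param kind `"random_unit"` (i.i.d. Gaussian columns normalized to unit
#'   norm) or `"gabor"` (randomly parameterized Gabor patches on the
#'   sqrt(M) x sqrt(M) grid, unit norm).
#' @param seed Integer seed.
#' @return M x K_true matrix with unit-norm columns.
#' @export
make_ground_truth_dictionary <- function(M, K_true,
                                         kind = c("random_unit", "gabor"),
                                         seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "random_unit") {
    phi <- matrix(stats::rnorm(M * K_true), M, K_true)
  } else {
    side <- sqrt(M)
    if (side != round(side))
      stop("M must be a perfect square for gabor dictionaries",
           call. = FALSE)
    side <- as.integer(side)
    gx <- matrix(rep(seq_len(side), side), side, side)
    gy <- t(gx)
    phi <- sapply(seq_len(K_true), function(k) {
      cx <- stats::runif(1, 1, side); cy <- stats::runif(1, 1, side)
      theta <- stats::runif(1, 0, pi)
      freq <- stats::runif(1, 0.1, 0.3)          # cycles / pixel
      sigma <- stats::runif(1, side / 8, side / 4)
      phase <- stats::runif(1, 0, 2 * pi)
      xr <- (gx - cx) * cos(theta) + (gy - cy) * sin(theta)
      env <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
      as.vector(env * cos(2 * pi * freq * xr + phase))
    })
  }
  normalize_columns(phi)
}

#' Sample sparse non-negative codes
#'
#' Entries are `Bernoulli(code_density) * Exponential(mean = code_scale)`:
#' non-negative, with expected zero fraction `1 - code_density`.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of code vectors.
#' @return n x K_true matrix of codes.
#' @export
sample_sparse_codes <- function(spec, n = spec$n_patches) {
  K <- spec$K_true
  active <- matrix(stats::rbinom(n * K, 1L, spec$code_density), n, K)
  mag <- if (spec$code_scale > 0)
    matrix(stats::rexp(n * K, rate = 1 / spec$code_scale), n, K)
  else matrix(0, n, K)
  active * mag
}

#' Generate a synthetic patch dataset from a known dictionary
#'
#' Inverts the model's likelihood: `x = Phi* a + eps` with sparse
#' non-negative codes `a` and `eps ~ N(0, noise_sigma^2 I)`. Returns the
#' generating dictionary and codes alongside the data so parameter-recovery
#' experiments can score against ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param dict_kind Forwarded to [make_ground_truth_dictionary()].
#' @return A `patch_dataset` with fields `X` (n_patches x M), `phi_star`,
#'   `codes`, and `spec`.
#' @export
synth_patches <- function(spec, dict_kind = "random_unit") {
  phi_star <- make_ground_truth_dictionary(spec$M, spec$K_true,
                                           kind = dict_kind,
                                           seed = spec$seed)
  set.seed(spec$seed + 1L)
  codes <- sample_sparse_codes(spec)
  X <- codes %*% t(phi_star)
  if (spec$noise_sigma > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = spec$noise_sigma),
                    nrow(X), ncol(X))
  patch_dataset(X, "synthetic", phi_star = phi_star, codes = codes,
                spec = spec)
}

# 2-D whitening filter rho * exp(-(rho/f0)^4) on the FFT frequency grid of
# an n x n image; f0 = 0.8 * Nyquist (0.5 cycles/pixel).
whitening_filter <- function(n, f0 = 0.8 * 0.5) {
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
  rho <- sqrt(outer(f^2, f^2, "+"))
  rho * exp(-(rho / f0)^4)
}

whiten_image <- function(img, f0 = 0.8 * 0.5) {
  n <- nrow(img)
  if (ncol(img) != n) stop("whitening expects square images", call. = FALSE)
  filt <- whitening_filter(n, f0)
  Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / length(img)
}

#' Extract whitened patches from natural images
#'
#' Whitens each image in the frequency domain with the low-pass-windowed
#' ramp filter `|f| * exp(-(|f|/f0)^4)`, `f0 = 0.8 * Nyquist` (the standard
#' sparse-coding preprocessing for natural scenes), then takes random crops,
#' removes each patch's mean, and scales the dataset to unit pixel variance.
#'
#' @param images A list of square numeric matrices (grayscale images), or a
#'   single matrix.
#' @param patch_size Side length of the square patches.
#' @param n_patches Number of random crops.
#' @param seed Integer seed controlling the crop coordinates.
#' @return A `patch_dataset` (n_patches x patch_size^2, provenance
#'   `"vanhateren"` style).
#' @export
extract_whitened_patches <- function(images, patch_size = 16L,
                                     n_patches = 5000L, seed = 1L) {
  if (is.matrix(images)) images <- list(images)
  for (img in images)
    if (nrow(img) < patch_size || ncol(img) < patch_size)
      stop("patch_size larger than image", call. = FALSE)
  white <- lapply(images, whiten_image)
  set.seed(seed)
  M <- patch_size^2
  X <- matrix(NA_real_, n_patches, M)
  img_idx <- sample.int(length(white), n_patches, replace = TRUE)
  for (i in seq_len(n_patches)) {
    img <- white[[img_idx[i]]]
    r0 <- sample.int(nrow(img) - patch_size + 1L, 1L)
    c0 <- sample.int(ncol(img) - patch_size + 1L, 1L)
    p <- img[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
    X[i, ] <- as.vector(p) - mean(p)
  }
  sdev <- stats::sd(as.vector(X))
  if (sdev > 0) X <- X / sdev
  patch_dataset(X, "vanhateren",
                normalization = list(patch_mean_removed = TRUE,
                                     dataset_sd = sdev))
}

read_idx_header <- function(con, expected_magic, path) {
  magic <- readBin(con, integer(), 1L, size = 4L, endian = "big")
  if (!identical(magic, expected_magic))
    stop(sprintf("bad IDX magic in '%s': got %d, expected %d",
                 path, magic, expected_magic), call. = FALSE)
  invisible(magic)
}

#' Read MNIST-style IDX image/label files
#'
#' Parses the big-endian IDX binary format (magic 2051 for image files,
#' 2049 for labels). Pixels are scaled to `[0, 1]` and flattened row-major
#' to vectors of length rows*cols (784 for MNIST).
#'
#' @param path_images Path to the IDX image file.
#' @param path_labels Optional path to the IDX label file.
#' @return A `patch_dataset` (provenance `"mnist"`) with a `labels` field
#'   when labels are supplied.
#' @export
read_mnist_idx <- function(path_images, path_labels = NULL) {
  con <- file(path_images, "rb"); on.exit(close(con), add = TRUE)
  read_idx_header(con, 2051L, path_images)
  n <- readBin(con, integer(), 1L, size = 4L, endian = "big")
  nr <- readBin(con, integer(), 1L, size = 4L, endian = "big")
  nc <- readBin(con, integer(), 1L, size = 4L, endian = "big")
  px <- readBin(con, integer(), n * nr * nc, size = 1L, signed = FALSE)
  X <- matrix(px / 255, n, nr * nc, byrow = TRUE)
  labels <- NULL
  if (!is.null(path_labels)) {
    conl <- file(path_labels, "rb"); on.exit(close(conl), add = TRUE)
    read_idx_header(conl, 2049L, path_labels)
    nl <- readBin(conl, integer(), 1L, size = 4L, endian = "big")
    labels <- readBin(conl, integer(), nl, size = 1L, signed = FALSE)
    if (any(labels < 0 | labels > 9))
      stop("label values outside 0-9 in IDX label file", call. = FALSE)
  }
  patch_dataset(X, "mnist", image_dim = c(nr, nc), labels = labels)
}

#' Write MNIST-style IDX image/label files
#'
#' Bit-exact counterpart of [read_mnist_idx()], used to build fixtures.
#'
#' @param X Matrix of images (one per row, values in `[0, 1]`).
#' @param path_images Output path for the image file.
#' @param image_dim Length-2 integer (rows, cols); `prod(image_dim)` must
#'   equal `ncol(X)`.
#' @param labels Optional integer labels in 0-9.
#' @param path_labels Output path for the label file.
#' @return `path_images`, invisibly.
#' @export
write_mnist_idx <- function(X, path_images, image_dim, labels = NULL,
                            path_labels = NULL) {
  if (prod(image_dim) != ncol(X))
    stop("image_dim inconsistent with ncol(X)", call. = FALSE)
  con <- file(path_images, "wb"); on.exit(close(con), add = TRUE)
  writeBin(2051L, con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(X)), con, size = 4L, endian = "big")
  writeBin(as.integer(image_dim[1]), con, size = 4L, endian = "big")
  writeBin(as.integer(image_dim[2]), con, size = 4L, endian = "big")
  writeBin(as.integer(round(t(X) * 255)), con, size = 1L)
  if (!is.null(labels)) {
    if (any(labels < 0 | labels > 9))
      stop("labels must be in 0-9", call. = FALSE)
    conl <- file(path_labels, "wb"); on.exit(close(conl), add = TRUE)
    writeBin(2049L, conl, size = 4L, endian = "big")
    writeBin(as.integer(length(labels)), conl, size = 4L, endian = "big")
    writeBin(as.integer(labels), conl, size = 1L)
  }
  invisible(path_images)
}

#' Drifting sinusoidal grating stimulus
#'
#' Frames `x_t(p) = contrast * sin(2 pi f s(p) - 2 pi tf t)` where `s(p)` is
#' the position along the drift axis; each frame has its mean removed.
#'
#' @param patch_size Side of the square frame.
#' @param spatial_freq Spatial frequency in cycles per pixel.
#' @param temporal_freq Temporal frequency in cycles per frame.
#' @param contrast Contrast in `[0, 1]`.
#' @param T Number of frames.
#' @param orientation Drift axis angle in radians (0 = horizontal).
#' @return A `patch_dataset` (provenance `"gratings"`) with `T` rows of
#'   length `patch_size^2`.
#' @export
drifting_grating <- function(patch_size = 8L, spatial_freq = 0.125,
                             temporal_freq = 0.1, contrast = 1, T = 50L,
                             orientation = 0) {
  if (contrast < 0 || contrast > 1)
    stop("contrast must be in [0, 1]", call. = FALSE)
  gx <- matrix(rep(seq_len(patch_size) - 1L, patch_size),
               patch_size, patch_size)
  gy <- t(gx)
  s <- gx * cos(orientation) + gy * sin(orientation)
  X <- t(sapply(seq_len(T) - 1L, function(t) {
    fr <- contrast * sin(2 * pi * spatial_freq * s - 2 * pi * temporal_freq * t)
    as.vector(fr - mean(fr))
  }))
  patch_dataset(X, "gratings",
                spec = list(patch_size = patch_size,
                            spatial_freq = spatial_freq,
                            temporal_freq = temporal_freq,
                            contrast = contrast, T = T,
                            orientation = orientation))
}
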