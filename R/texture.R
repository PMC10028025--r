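#' Texture bank configuration
#'
#' Parameters of the four per-pixel texture families. Defaults: 5x5 windows
#' with 64 grey levels for the Haralick co-occurrence maps, 64 orientation
#' bins for CoLlAGe, a 6-frequency (geometric series 0.05-0.4 cycles/px) x
#' 8-orientation Gabor grid (48 filters), and the classical five Law's
#' 5-tap vectors. The filter counts (13 + 13 + 48 + 25 = 99 response maps)
#' are the binding contract of the bank.
#'
#' @param haralick_window,collage_window odd window sides (default 5).
#' @param gray_levels co-occurrence quantization levels (default 64).
#' @param collage_orientation_bins orientation quantization (default 64).
#' @param gabor_frequencies numeric vector of cycles/px (< 0.5).
#' @param gabor_orientations numeric vector of radians.
#' @param laws_vectors named list of five 5-tap kernels L5, E5, S5, W5, R5.
#' @return object of class `texture_config`.
#' @export
texture_config <- function(haralick_window = 5, gray_levels = 64,
                           collage_window = 5, collage_orientation_bins = 64,
                           gabor_frequencies = 0.05 * (0.4 / 0.05)^((0:5) / 5),
                           gabor_orientations = seq(0, pi - pi / 8, by = pi / 8),
                           laws_vectors = list(
                             L5 = c(1, 4, 6, 4, 1),
                             E5 = c(-1, -2, 0, 2, 1),
                             S5 = c(-1, 0, 2, 0, -1),
                             W5 = c(-1, 2, 0, -2, 1),
                             R5 = c(1, -4, 6, -4, 1))) {
  stopifnot(haralick_window %% 2 == 1, haralick_window >= 3,
            collage_window %% 2 == 1, collage_window >= 3,
            gray_levels >= 2, collage_orientation_bins >= 2)
  if (length(gabor_frequencies) * length(gabor_orientations) != 48)
    stop("the Gabor grid must contain exactly 48 (frequency, orientation) pairs")
  if (any(gabor_frequencies >= 0.5))
    stop("Gabor frequencies must be below the Nyquist limit (0.5 cycles/px)")
  stopifnot(identical(names(laws_vectors), c("L5", "E5", "S5", "W5", "R5")),
            all(lengths(laws_vectors) == 5))
  if (abs(sum(laws_vectors$L5) - 16) > 1e-12) stop("L5 must sum to 16")
  for (nm in c("E5", "S5", "W5", "R5")) {
    if (abs(sum(laws_vectors[[nm]])) > 1e-12) stop(nm, " must sum to zero")
  }
  structure(list(haralick_window = as.integer(haralick_window),
                 gray_levels = as.integer(gray_levels),
                 collage_window = as.integer(collage_window),
                 collage_orientation_bins = as.integer(collage_orientation_bins),
                 gabor_frequencies = gabor_frequencies,
                 gabor_orientations = gabor_orientations,
                 laws_vectors = laws_vectors),
            class = "texture_config")
}

haralick_stat_names <- c(
  "energy", "contrast", "correlation", "variance",
  "inverse_difference_moment", "sum_average", "sum_variance", "sum_entropy",
  "entropy", "difference_variance", "difference_entropy",
  "info_measure_1", "info_measure_2")

#' Quantize an image to a fixed number of grey levels
#'
#' Uniform quantization over the min-max intensity range of the mask pixels
#' (or of the whole image when no mask is given). Values outside the range
#' are clamped.
#'
#' @param image numeric matrix.
#' @param levels number of levels.
#' @param mask optional logical matrix defining the reference range.
#' @return integer matrix with values in `0..levels-1`.
#' @export
quantize_levels <- function(image, levels, mask = NULL) {
  ref <- if (is.null(mask)) image else image[mask > 0]
  lo <- min(ref); hi <- max(ref)
  if (hi <= lo) {
    q <- matrix(0L, nrow(image), ncol(image))
    return(q)
  }
  q <- floor((image - lo) / (hi - lo) * levels)
  q <- pmin(pmax(q, 0), levels - 1)
  storage.mode(q) <- "integer"
  matrix(q, nrow(image), ncol(image))
}

#' Windowed Haralick co-occurrence statistic maps
#'
#' Quantizes the (illumination-normalized) image to `cfg$gray_levels`
#' levels over the foreground intensity range and computes, for every
#' pixel, a symmetric grey-level co-occurrence matrix pooled over the four
#' standard distance-1 directions inside the window centred on that pixel,
#' from which the 13 classical second-order statistics are derived. One map
#' per statistic.
#'
#' @param image numeric matrix (typically [normalize_illumination()] output).
#' @param cfg a [texture_config()].
#' @param foreground optional logical mask defining the quantization range.
#' @return named list of 13 matrices (`haralick.energy`, ...).
#' @export
haralick_maps <- function(image, cfg = texture_config(), foreground = NULL) {
  q <- quantize_levels(image, cfg$gray_levels, foreground)
  maps <- glcm_stat_maps_cpp(q, cfg$gray_levels, cfg$haralick_window)
  names(maps) <- paste0("haralick.", haralick_stat_names)
  maps
}

#' Per-pixel dominant gradient orientation
#'
#' Computes x/y gradients by central differences (symmetric borders) and,
#' for every pixel, the dominant orientation of the gradient vectors in the
#' surrounding `window x window` neighbourhood as the principal direction of
#' the windowed structure tensor (equivalently, the leading right singular
#' vector of the stacked gradient matrix). Angles are reported modulo pi in
#' `[0, pi)`. Pixels whose window carries (numerically) no gradient energy
#' are flagged in the `degenerate` attribute and assigned angle 0.
#'
#' @param image numeric matrix.
#' @param window odd window side.
#' @return matrix of angles in `[0, pi)` with logical attribute `degenerate`.
#' @export
dominant_orientation <- function(image, window = 5) {
  nr <- nrow(image); nc <- ncol(image)
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  gx <- (image[, jp, drop = FALSE] - image[, jm, drop = FALSE]) / 2
  gy <- (image[ip, , drop = FALSE] - image[im, , drop = FALSE]) / 2
  ones <- matrix(1, window, window)
  jxx <- apply_kernel(gx * gx, ones)
  jyy <- apply_kernel(gy * gy, ones)
  jxy <- apply_kernel(gx * gy, ones)
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy)
  theta[theta < 0] <- theta[theta < 0] + pi
  theta[theta >= pi] <- 0
  degenerate <- (jxx + jyy) < 1e-12
  theta[degenerate] <- 0
  attr(theta, "degenerate") <- degenerate
  theta
}

#' Windowed CoLlAGe co-occurrence statistic maps
#'
#' Co-occurrence of local anisotropic gradient orientations: the per-pixel
#' dominant gradient orientation ([dominant_orientation()]) is quantized
#' into `cfg$collage_orientation_bins` bins and the same 13 second-order
#' statistics as the Haralick family are computed from the windowed
#' co-occurrence of the binned orientations.
#'
#' @inheritParams haralick_maps
#' @return named list of 13 matrices (`collage.energy`, ...).
#' @export
collage_maps <- function(image, cfg = texture_config(), foreground = NULL) {
  theta <- dominant_orientation(image, cfg$collage_window)
  nb <- cfg$collage_orientation_bins
  bins <- floor(theta / pi * nb)
  bins <- pmin(pmax(bins, 0), nb - 1)
  bins[attr(theta, "degenerate")] <- 0L
  storage.mode(bins) <- "integer"
  bins <- matrix(bins, nrow(image), ncol(image))
  maps <- glcm_stat_maps_cpp(bins, nb, cfg$collage_window)
  names(maps) <- paste0("collage.", haralick_stat_names)
  maps
}

# ---- Gabor bank -----------------------------------------------------------

ref_idx0 <- function(i, n) {
  # 0-based symmetric (edge-duplicating) reflection, period 2n
  i <- i %% (2 * n)
  ifelse(i < n, i, 2 * n - 1 - i)
}

reflect_pad <- function(img, pr, pc) {
  nr <- nrow(img); nc <- ncol(img)
  img[ref_idx0(seq(-pr, nr + pr - 1), nr) + 1,
      ref_idx0(seq(-pc, nc + pc - 1), nc) + 1, drop = FALSE]
}

# 1-D factors of the complex Gabor kernel. With an isotropic Gaussian
# envelope the 2-D kernel is the outer product of two 1-D complex Gabors
# (rows x columns); the DC correction subtracts the kernel mean, making the
# full kernel rank 2. Truncated at 2.5 sigma (capped at radius 31 px).
gabor_kernel_1d <- function(f, theta, bandwidth_sigma = 0.56) {
  sigma <- bandwidth_sigma / f
  r <- as.integer(min(ceiling(2.5 * sigma), 31L))
  t <- (-r):r
  env <- exp(-t^2 / (2 * sigma^2))
  u <- env * exp(1i * 2 * pi * f * sin(theta) * t)  # row factor (y)
  w <- env * exp(1i * 2 * pi * f * cos(theta) * t)  # column factor (x)
  list(u = u, w = w, r = r, mu = mean(u) * mean(w))
}

#' Explicit complex Gabor kernel
#'
#' The truncated, DC-free complex kernel (real part = cosine phase,
#' imaginary part = sine phase) used by [gabor_bank()]; exposed for
#' inspection and direct spatial-domain checks.
#'
#' @param f frequency in cycles/px.
#' @param theta orientation in radians.
#' @param bandwidth_sigma envelope scale as a multiple of 1/f (default 0.56,
#'   about one octave bandwidth).
#' @return complex matrix of odd side.
#' @export
gabor_kernel <- function(f, theta, bandwidth_sigma = 0.56) {
  g <- gabor_kernel_1d(f, theta, bandwidth_sigma)
  outer(g$u, g$w) - g$mu
}

# FFT of a flipped 1-D kernel embedded at the origin of a length-N grid
embed1_fft <- function(v, N) {
  r <- (length(v) - 1L) %/% 2L
  e <- complex(length.out = N)
  e[((-(-r:r)) %% N) + 1L] <- v
  stats::fft(e)
}

#' Gabor filter response magnitude maps
#'
#' Convolves the image with a bank of DC-free complex Gabor kernels
#' (isotropic Gaussian envelope with sigma = 0.56/frequency, truncated at
#' 2.5 sigma) over the `cfg` frequency x orientation grid and returns the
#' response magnitudes. Borders are handled by reflection; the convolutions
#' are carried out in the Fourier domain.
#'
#' @inheritParams haralick_maps
#' @return named list of 48 matrices (`gabor.f<freq>_o<orientation index>`).
#' @export
gabor_bank <- function(image, cfg = texture_config()) {
  nr <- nrow(image); nc <- ncol(image)
  grid <- list(); nm <- character(0)
  for (f in cfg$gabor_frequencies) {
    for (oi in seq_along(cfg$gabor_orientations)) {
      grid[[length(grid) + 1L]] <- gabor_kernel_1d(f, cfg$gabor_orientations[oi])
      nm <- c(nm, sprintf("gabor.f%.3f_o%d", f, oi))
    }
  }
  pad <- max(vapply(grid, function(g) g$r, integer(1)))
  Z <- reflect_pad(image, pad, pad)
  N1 <- stats::nextn(nrow(Z), c(2, 3, 5))
  N2 <- stats::nextn(ncol(Z), c(2, 3, 5))
  ZZ <- matrix(0, N1, N2)
  ZZ[seq_len(nrow(Z)), seq_len(ncol(Z))] <- Z
  FZ <- stats::fft(ZZ)
  dc1 <- list(); dc2 <- list()  # FFTs of flipped all-ones windows, per radius
  out <- vector("list", length(grid))
  names(out) <- nm
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    U <- embed1_fft(rev(g$u), N1)
    W <- embed1_fft(rev(g$w), N2)
    key <- as.character(g$r)
    if (is.null(dc1[[key]])) {
      ones <- rep(1 + 0i, 2 * g$r + 1)
      dc1[[key]] <- embed1_fft(ones, N1)
      dc2[[key]] <- embed1_fft(ones, N2)
    }
    # frequency response of the flipped rank-2 kernel (separable Gabor
    # minus its mean): correlation via pointwise product with fft(image)
    FK <- outer(U, W) - g$mu * outer(dc1[[key]], dc2[[key]])
    resp <- stats::fft(FZ * FK, inverse = TRUE) / (N1 * N2)
    out[[i]] <- Mod(resp[(pad + 1):(pad + nr), (pad + 1):(pad + nc)])
  }
  out
}

#' Law's texture energy response maps
#'
#' Applies the 25 5x5 kernels formed as outer products of every ordered
#' pair of the five 1-D Law's vectors (level, edge, spot, wave, ripple) to
#' the image (reflected borders). Kernel `XY` has rows from vector `X` and
#' columns from vector `Y`.
#'
#' @inheritParams haralick_maps
#' @return named list of 25 matrices (`laws.L5E5`, ...).
#' @export
laws_bank <- function(image, cfg = texture_config()) {
  vs <- cfg$laws_vectors
  out <- list()
  for (n1 in names(vs)) {
    for (n2 in names(vs)) {
      out[[paste0("laws.", n1, n2)]] <- apply_kernel(image, outer(vs[[n1]], vs[[n2]]))
    }
  }
  out
}

#' Summarize response maps over the cluster foreground
#'
#' Reduces each per-pixel response map to five statistics over the
#' foreground pixels: mean, median, standard deviation (population),
#' skewness and kurtosis (plain, Gaussian = 3). Maps that are constant over
#' the foreground report skewness = kurtosis = 0 and are counted in a
#' single warning.
#'
#' @param maps named list of matrices.
#' @param foreground logical mask with at least 4 pixels.
#' @return named numeric vector of `5 * length(maps)` features
#'   (`<map>.mean`, `<map>.median`, `<map>.sd`, `<map>.skewness`,
#'   `<map>.kurtosis`).
#' @export
summarize_maps <- function(maps, foreground) {
  foreground <- foreground > 0
  if (sum(foreground) < 4)
    stop("at least 4 foreground pixels are required (kurtosis undefined)")
  n_flat <- 0L
  out <- numeric(0)
  for (nm in names(maps)) {
    v <- maps[[nm]][foreground]
    st <- moment_stats(v)
    if (st["sd"] == 0) n_flat <- n_flat + 1L
    names(st) <- paste(nm, names(st), sep = ".")
    out <- c(out, st)
  }
  if (n_flat > 0)
    warning(n_flat, " response map(s) constant over the foreground; skewness/kurtosis reported as 0")
  out
}

#' Full texture feature vector for a preprocessed cluster
#'
#' Removes local illumination with a 15x15 moving-average subtraction, then
#' computes the 99 response maps (13 Haralick + 13 CoLlAGe + 48 Gabor + 25
#' Law's) and summarizes each with 5 statistics over the cluster foreground:
#' 495 named texture features.
#'
#' @param cluster a preprocessed [cluster_image()].
#' @param cfg a [texture_config()].
#' @param illumination_window window for [normalize_illumination()].
#' @return named numeric vector of length 495.
#' @export
texture_features <- function(cluster, cfg = texture_config(), illumination_window = 15) {
  stopifnot(inherits(cluster, "cluster_image"))
  fg <- cluster$foreground_mask
  if (is.null(fg)) stop("cluster has no foreground mask; run preprocess_cluster() first")
  norm <- normalize_illumination(cluster$pixels, illumination_window)
  maps <- c(haralick_maps(norm, cfg, fg),
            collage_maps(norm, cfg, fg),
            gabor_bank(norm, cfg),
            laws_bank(norm, cfg))
  summarize_maps(maps, fg)
}
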