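#' Cluster image container
#'
#' Lightweight container for a single cell-cluster crop: the 8-bit grey
#' pixel matrix, the pixel size, an optional foreground mask and the
#' provenance of the crop.
#'
#' @param pixels grey matrix (0-255).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param foreground_mask optional logical matrix matching `pixels`.
#' @param provenance one of `"annotated"`, `"auto_detected"`, `"synthetic"`.
#' @param id character identifier.
#' @return object of class `cluster_image`.
#' @export
cluster_image <- function(pixels, pixel_size_um = 0.25, foreground_mask = NULL,
                          provenance = c("annotated", "auto_detected", "synthetic"),
                          id = "cluster") {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (!is.null(foreground_mask)) {
    stopifnot(identical(dim(foreground_mask), dim(pixels)))
    foreground_mask <- foreground_mask > 0
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 foreground_mask = foreground_mask, provenance = provenance,
                 id = id),
            class = "cluster_image")
}

#' Convert an RGB array to 8-bit grey
#'
#' Weighted luminance combination with Rec. 709 weights
#' (0.2125, 0.7154, 0.0721). A matrix input (already grey) passes through
#' unchanged.
#'
#' @param image matrix (grey) or `h x w x 3` array (RGB, 0-255).
#' @return grey matrix (0-255, rounded).
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected a grey matrix or an RGB array with 3 channels")
  w <- c(0.2125, 0.7154, 0.0721)
  round(image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3])
}

#' Remove the bright slide background from a cluster crop
#'
#' The background intensity is estimated as the mean of the pixels above the
#' Otsu split of the crop; pixels with intensity greater than 95% of that
#' estimate are marked background, everything else is foreground. A
#' (near-)uniformly bright crop yields an empty foreground with a warning
#' rather than an error.
#'
#' @param image grey matrix (0-255).
#' @return logical foreground mask with the threshold attached as attribute
#'   `threshold`.
#' @export
remove_background <- function(image) {
  stopifnot(is.matrix(image))
  if (length(image) == 0) stop("empty image")
  split <- otsu_threshold(as.numeric(image))
  if (is.na(split)) {
    warning("uniform image: no foreground found")
    out <- matrix(FALSE, nrow(image), ncol(image))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  bg_mean <- mean(image[image > split])
  thr <- 0.95 * bg_mean
  out <- image <= thr
  if (!any(out)) warning("uniformly bright image: empty foreground mask")
  attr(out, "threshold") <- thr
  out
}

#' Remove connected components smaller than an area threshold
#'
#' Components with area strictly below `min_area_um2` (converted to pixels
#' with the pixel size) are dropped; this is the artifact filter applied to
#' both annotated and automatically detected crops. Default threshold is
#' 100 um^2, the size below which objects (stain artifacts, bile residue,
#' single cells) are excluded.
#'
#' @param mask logical matrix.
#' @param min_area_um2 area threshold in square micrometres (> 0).
#' @param pixel_size_um micrometres per pixel.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_area_um2 = 100, pixel_size_um = 0.25) {
  stopifnot(is.matrix(mask))
  if (min_area_um2 <= 0) stop("min_area_um2 must be > 0")
  min_px <- min_area_um2 / pixel_size_um^2
  lab <- EBImage::bwlabel(mask > 0)
  if (max(lab) == 0) return(mask > 0)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_px)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Histogram equalization restricted to a mask
#'
#' Maps intensities through the empirical CDF of the masked pixels (256
#' bins), so the output histogram over the mask is approximately uniform on
#' 0..255. The map is monotone non-decreasing, so the rank order of pixel
#' intensities is preserved. Pixels outside the mask are left unchanged.
#'
#' @param image grey matrix (0-255).
#' @param mask logical matrix; must contain at least one pixel.
#' @return grey matrix (0-255).
#' @export
equalize_contrast <- function(image, mask = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  v <- pmin(pmax(floor(image[mask]), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / sum(h)
  out <- image
  out[mask] <- round(255 * cdf[pmin(pmax(floor(image[mask]), 0), 255) + 1L])
  out
}

#' Local illumination normalization
#'
#' Subtracts, at every pixel, the mean of a `window x window` neighbourhood
#' (default 15) from the image, removing slowly varying illumination before
#' texture extraction. Borders are handled by reflection.
#'
#' @param image grey matrix.
#' @param window odd window side, >= 3.
#' @return signed-valued matrix of the same dimensions.
#' @export
normalize_illumination <- function(image, window = 15) {
  stopifnot(is.matrix(image))
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (window > min(dim(image))) stop("window larger than image")
  k <- matrix(1 / window^2, window, window)
  image - apply_kernel(image, k)
}

#' Preprocess a cluster crop
#'
#' Standard cleaning pipeline for a cluster crop: background removal, small
#' object filtering (default < 100 um^2) and mask-restricted histogram
#' equalization, in that order.
#'
#' @param x a `cluster_image`, `synthetic_cluster`, or grey matrix.
#' @param pixel_size_um micrometres per pixel (used when `x` is a matrix).
#' @param min_area_um2 artifact area threshold.
#' @return a `cluster_image` with equalized pixels and the cleaned
#'   foreground mask.
#' @export
preprocess_cluster <- function(x, pixel_size_um = 0.25, min_area_um2 = 100) {
  if (inherits(x, "synthetic_cluster")) {
    img <- x$image
    pixel_size_um <- x$params$pixel_size_um
    id <- if (!is.na(x$label)) paste0("synthetic_", x$label) else "synthetic"
    prov <- "synthetic"
  } else if (inherits(x, "cluster_image")) {
    img <- x$pixels; pixel_size_um <- x$pixel_size_um
    id <- x$id; prov <- x$provenance
  } else {
    img <- to_grayscale(x); id <- "cluster"; prov <- "annotated"
  }
  fg <- remove_background(img)
  fg <- remove_small_objects(fg, min_area_um2, pixel_size_um)
  eq <- if (any(fg)) equalize_contrast(img, fg) else img
  cluster_image(eq, pixel_size_um, fg, provenance = prov, id = id)
}
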