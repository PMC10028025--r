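#' Patch specification for automatic cluster detection
#'
#' Parameters of the slide-scale detection path: patch side length, the
#' maximum tolerated background fraction per patch (patches with more than
#' 40% background are discarded by default), the minimum cluster area and
#' the background intensity threshold (a fixed grey level, or `"auto"` to
#' estimate it per patch from the mean intensity above the Otsu split, the
#' same rule used for annotated crops).
#'
#' @param patch_px patch side in pixels (>= 64; default 1000).
#' @param max_background_fraction in (0, 1); default 0.40.
#' @param min_cluster_area_um2 minimum retained cluster area (default 100).
#' @param background_intensity_threshold numeric grey level or `"auto"`.
#' @return object of class `patch_spec`.
#' @export
patch_spec <- function(patch_px = 1000, max_background_fraction = 0.40,
                       min_cluster_area_um2 = 100,
                       background_intensity_threshold = "auto") {
  stopifnot(patch_px >= 64,
            max_background_fraction > 0, max_background_fraction < 1,
            min_cluster_area_um2 > 0)
  structure(list(patch_px = as.integer(patch_px),
                 max_background_fraction = max_background_fraction,
                 min_cluster_area_um2 = min_cluster_area_um2,
                 background_intensity_threshold = background_intensity_threshold),
            class = "patch_spec")
}

# resolve the background threshold for one patch
patch_bg_threshold <- function(image, spec) {
  thr <- spec$background_intensity_threshold
  if (identical(thr, "auto")) {
    split <- otsu_threshold(as.numeric(image))
    if (is.na(split)) return(-Inf)  # uniform patch: everything is background
    0.95 * mean(image[image > split])
  } else {
    as.numeric(thr)
  }
}

#' Tile a slide-scale image into non-overlapping patches
#'
#' Row-major grid of `patch_px`-sided patches; right/bottom remainders are
#' dropped. Offsets are 0-based pixel coordinates of half-open boxes
#' (x = column, y = row).
#'
#' @param image grey matrix at slide scale.
#' @param spec a [patch_spec()].
#' @return list of patches, each `list(image, x0, y0)`.
#' @export
tile <- function(image, spec = patch_spec()) {
  stopifnot(is.matrix(image))
  s <- spec$patch_px
  nrp <- nrow(image) %/% s
  ncp <- ncol(image) %/% s
  if (nrp < 1 || ncp < 1) stop("image smaller than one patch")
  out <- vector("list", nrp * ncp)
  k <- 0L
  for (i in seq_len(nrp)) {
    for (j in seq_len(ncp)) {
      k <- k + 1L
      r0 <- (i - 1L) * s; c0 <- (j - 1L) * s
      out[[k]] <- list(image = image[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s)],
                       x0 = c0, y0 = r0)
    }
  }
  out
}

#' Filter patches by background fraction
#'
#' Retains a patch iff its background fraction (pixels brighter than the
#' resolved intensity threshold) does not exceed
#' `spec$max_background_fraction`; patches with more than that fraction of
#' bare slide are discarded before cluster extraction.
#'
#' @param patches list as returned by [tile()].
#' @param spec a [patch_spec()].
#' @return the retained subset, each with `background_fraction` added.
#' @export
filter_patches <- function(patches, spec = patch_spec()) {
  keep <- list()
  for (p in patches) {
    thr <- patch_bg_threshold(p$image, spec)
    frac <- mean(p$image > thr)
    if (frac <= spec$max_background_fraction) {
      p$background_fraction <- frac
      keep[[length(keep) + 1L]] <- p
    }
  }
  keep
}

#' Extract candidate cell clusters from a patch
#'
#' Thresholds the patch against the background intensity, removes
#' sub-threshold objects, and turns each remaining connected component into
#' a tight-bounding-box [cluster_image()] crop with provenance
#' `"auto_detected"`. Components touching the patch edge are kept (clipped
#' at the patch bounds).
#'
#' @param patch element of [tile()] output (or `list(image, x0, y0)`).
#' @param spec a [patch_spec()].
#' @param pixel_size_um micrometres per pixel.
#' @return list of `cluster_image` objects (possibly empty); each carries
#'   attributes `box` (0-based half-open patch-frame box) and `area_um2`.
#' @export
extract_clusters <- function(patch, spec = patch_spec(), pixel_size_um = 0.25) {
  img <- patch$image
  thr <- patch_bg_threshold(img, spec)
  fg <- img <= thr
  fg <- remove_small_objects(fg, spec$min_cluster_area_um2, pixel_size_um)
  lab <- EBImage::bwlabel(fg)
  n <- max(lab)
  if (n == 0) return(list())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    crop <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    mask <- matrix(lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k,
                   nrow = rr[2] - rr[1] + 1L)
    ci <- cluster_image(crop, pixel_size_um, mask, provenance = "auto_detected",
                        id = sprintf("patch_%d_%d_c%02d", patch$x0, patch$y0, k))
    attr(ci, "box") <- c(x0 = patch$x0 + cc[1] - 1L, y0 = patch$y0 + rr[1] - 1L,
                         x1 = patch$x0 + cc[2], y1 = patch$y0 + rr[2])
    attr(ci, "area_um2") <- sum(mask) * pixel_size_um^2
    out[[k]] <- ci
  }
  out
}

#' Detect cell clusters on a slide-scale image
#'
#' Convenience wrapper: [tile()], [filter_patches()], then
#' [extract_clusters()] on every retained patch.
#'
#' @inheritParams extract_clusters
#' @param image slide-scale grey matrix.
#' @return list with `clusters` (list of `cluster_image`) and `manifest`
#'   (data.frame of id, box coordinates and area).
#' @export
detect_clusters <- function(image, spec = patch_spec(), pixel_size_um = 0.25) {
  patches <- filter_patches(tile(image, spec), spec)
  clusters <- list()
  for (p in patches) clusters <- c(clusters, extract_clusters(p, spec, pixel_size_um))
  manifest <- if (length(clusters)) {
    do.call(rbind, lapply(clusters, function(ci) {
      b <- attr(ci, "box")
      data.frame(id = ci$id, x0 = b["x0"], y0 = b["y0"], x1 = b["x1"], y1 = b["y1"],
                 area_um2 = attr(ci, "area_um2"), row.names = NULL)
    }))
  } else {
    data.frame(id = character(0), x0 = integer(0), y0 = integer(0),
               x1 = integer(0), y1 = integer(0), area_um2 = numeric(0))
  }
  list(clusters = clusters, manifest = manifest)
}
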