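# ---- region geometry helpers ---------------------------------------------

# convex hull area of a pixel region, measured the way regionprops-style
# toolkits do: build the hull polygon over the pixel centres, rasterize it,
# and count the pixels whose centre falls inside (union with the region
# itself, so the hull always contains the region and solidity never
# exceeds 1).
hull_area_from_pixels <- function(rows, cols) {
  n <- length(rows)
  if (n < 3) return(n)
  pr <- as.numeric(rows); pc <- as.numeric(cols)
  idx <- grDevices::chull(pc, pr)
  xs <- pc[idx]; ys <- pr[idx]
  if (length(idx) < 3) return(n)
  gr <- min(rows):max(rows); gc <- min(cols):max(cols)
  rr <- rep(gr, times = length(gc))
  cc <- rep(gc, each = length(gr))
  inside <- rep(FALSE, length(rr))
  j <- length(xs)
  for (i in seq_along(xs)) {  # even-odd ray crossing on pixel centres
    denom <- ys[j] - ys[i]
    if (abs(denom) > 1e-12) {
      crosses <- ((ys[i] > rr) != (ys[j] > rr)) &
        (cc < (xs[j] - xs[i]) * (rr - ys[i]) / denom + xs[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  in_region <- logical(length(rr))
  in_region[(match(cols, gc) - 1L) * length(gr) + match(rows, gr)] <- TRUE
  sum(inside | in_region)
}

solidity_from_pixels <- function(rows, cols) {
  length(rows) / hull_area_from_pixels(rows, cols)
}

# Crofton-style perimeter (in pixels) of a logical mask: boundary crossing
# counts along rows, columns and both diagonals, weighted by line spacing.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  n0  <- sum(m[, -nc] != m[, -1])                       # along rows
  n90 <- sum(m[-nr, ] != m[-1, ])                       # along columns
  n45  <- sum(m[-nr, -nc] != m[-1, -1])                 # \ diagonals
  n135 <- sum(m[-nr, -1] != m[-1, -nc])                 # / diagonals
  pi / 8 * (n0 + n90 + (n45 + n135) / sqrt(2))
}

#' Per-nucleus shape descriptors
#'
#' Computes, for every positive label of a nuclear label map, eight shape
#' descriptors: area (um^2), perimeter (um, Crofton estimator),
#' major/minor axis length (um, from the ellipse-equivalent second moments
#' of the pixel region with the 1/12 unit-square pixel correction),
#' eccentricity, solidity (area / convex hull area, hull taken over pixel
#' corners), circularity (4 pi A / P^2), and equivalent diameter (um).
#'
#' @param labels a `nuclear_label_map` (from [watershed_split()]) or an
#'   integer label matrix.
#' @param pixel_size_um micrometres per pixel.
#' @return data.frame with one row per nucleus (column `label` plus the
#'   eight descriptors, `area_px` included for reference).
#' @export
nucleus_descriptors <- function(labels, pixel_size_um = 0.25) {
  if (inherits(labels, "nuclear_label_map")) labels <- labels$labels
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("empty label map: no nuclei to measure")
  px <- pixel_size_um
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    idx <- which(labels == ids[i], arr.ind = TRUE)
    rows <- idx[, 1]; cols <- idx[, 2]
    area_px <- length(rows)
    # second central moments of the region treated as a union of unit
    # squares: discrete pixel-centre variance + 1/12 per axis
    vr <- mean(rows^2) - mean(rows)^2 + 1 / 12
    vc <- mean(cols^2) - mean(cols)^2 + 1 / 12
    vrc <- mean(rows * cols) - mean(rows) * mean(cols)
    tr <- vr + vc
    det_ <- vr * vc - vrc^2
    disc <- max(tr^2 / 4 - det_, 0)
    l1 <- tr / 2 + sqrt(disc)
    l2 <- max(tr / 2 - sqrt(disc), 0)
    major <- 4 * sqrt(l1) * px
    minor <- 4 * sqrt(l2) * px
    per <- crofton_perimeter(matrix(labels == ids[i], nrow(labels), ncol(labels))[
      min(rows):max(rows), min(cols):max(cols), drop = FALSE]) * px
    area_um2 <- area_px * px^2
    sol <- solidity_from_pixels(rows, cols)
    out[[i]] <- data.frame(
      label = ids[i],
      area_px = area_px,
      area_um2 = area_um2,
      perimeter_um = per,
      major_axis_um = major,
      minor_axis_um = minor,
      eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
      solidity = sol,
      circularity = 4 * pi * area_um2 / per^2,
      equivalent_diameter_um = 2 * sqrt(area_um2 / pi))
  }
  do.call(rbind, out)
}

shape_descriptor_names <- c("area_um2", "perimeter_um", "major_axis_um",
                            "minor_axis_um", "eccentricity", "solidity",
                            "circularity", "equivalent_diameter_um")

#' Aggregate per-nucleus descriptors to cluster level
#'
#' The eight descriptors of [nucleus_descriptors()] are each summarized
#' with mean, median, standard deviation (population), skewness and
#' kurtosis over the nuclei of the cluster: 40 named features. For a
#' single-nucleus cluster the dispersion statistics are 0 by the degenerate
#' convention.
#'
#' @param shapes data.frame from [nucleus_descriptors()].
#' @return named numeric vector of length 40 (`shape.<descriptor>.<stat>`).
#' @export
aggregate_shape <- function(shapes) {
  if (nrow(shapes) == 0) stop("empty shape table")
  out <- numeric(0)
  for (d in shape_descriptor_names) {
    st <- moment_stats(shapes[[d]])
    names(st) <- paste("shape", d, names(st), sep = ".")
    out <- c(out, st)
  }
  out
}

#' Nuclear-to-cytoplasmic area ratio
#'
#' Total nuclear area divided by the non-nuclear area of the cluster
#' foreground.
#'
#' @param labels a `nuclear_label_map` or integer label matrix.
#' @param foreground logical cluster foreground mask.
#' @return scalar N:C ratio.
#' @export
nc_ratio <- function(labels, foreground) {
  if (inherits(labels, "nuclear_label_map")) labels <- labels$labels
  stopifnot(identical(dim(labels), dim(foreground)))
  nuc <- sum(labels > 0)
  nonnuc <- sum(foreground > 0) - nuc
  if (nonnuc <= 0) stop("degenerate cluster: no non-nuclear foreground area")
  nuc / nonnuc
}

#' Full shape feature vector for a segmented cluster
#'
#' 40 aggregated nucleus-shape features plus the N:C ratio: 41 named shape
#' features.
#'
#' @param labels a `nuclear_label_map`.
#' @param foreground logical cluster foreground mask.
#' @param pixel_size_um micrometres per pixel.
#' @return named numeric vector of length 41.
#' @export
shape_features <- function(labels, foreground, pixel_size_um = 0.25) {
  shapes <- nucleus_descriptors(labels, pixel_size_um)
  c(aggregate_shape(shapes), "shape.nc_ratio" = nc_ratio(labels, foreground))
}
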