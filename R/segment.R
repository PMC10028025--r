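#' Binarize nuclei within a preprocessed cluster
#'
#' After equalization nuclei are the dark phase of the cluster foreground.
#' Thresholds the foreground at its Otsu split, fills holes, and removes
#' specks below `min_nucleus_area_um2`. A polarity check verifies that the
#' selected phase is darker than the remaining foreground and warns
#' otherwise (inverted-contrast input).
#'
#' @param cluster a preprocessed [cluster_image()] (with foreground mask).
#' @param min_nucleus_area_um2 speck-removal threshold (default 10 um^2).
#' @return logical nucleus mask.
#' @export
binarize_nuclei <- function(cluster, min_nucleus_area_um2 = 10) {
  stopifnot(inherits(cluster, "cluster_image"))
  fg <- cluster$foreground_mask
  if (is.null(fg) || !any(fg)) stop("cluster has an empty foreground mask")
  v <- cluster$pixels[fg]
  thr <- otsu_threshold(v)
  if (is.na(thr)) return(matrix(FALSE, nrow(cluster$pixels), ncol(cluster$pixels)))
  nuc <- cluster$pixels <= thr & fg
  if (any(nuc) && any(fg & !nuc)) {
    if (mean(cluster$pixels[nuc]) >= mean(cluster$pixels[fg & !nuc]))
      warning("polarity check failed: nucleus phase is not darker than the rest of the cluster")
  }
  nuc <- EBImage::fillHull(nuc) > 0
  # on inverted-contrast input the selected dark phase is the cytoplasmic
  # rim, which hole-fills to (almost) the whole cluster
  if (sum(nuc) > 0.85 * sum(fg))
    warning("polarity check failed: dark phase fills the cluster; input contrast may be inverted")
  remove_small_objects(nuc, min_nucleus_area_um2, cluster$pixel_size_um)
}

#' Split touching nuclei by distance-transform watershed
#'
#' Markers are the regional maxima of the Euclidean distance transform of
#' the binary mask after h-extrema suppression with depth `h_min`
#' (equivalently, the regional minima of the negative distance map);
#' regions are grown outward from the markers until they meet. Every
#' foreground pixel receives a label, so the union of the positive labels
#' equals the input mask.
#'
#' @param binary logical nucleus mask.
#' @param h_min suppression depth in pixels (default 1); larger values merge
#'   shallow splits, so the label count is non-increasing in `h_min`.
#' @param source_id identifier carried into the result.
#' @return object of class `nuclear_label_map`: list with `labels` (integer
#'   matrix, 0 = non-nucleus), `n_nuclei`, `source_id`.
#' @export
watershed_split <- function(binary, h_min = 1, source_id = "cluster") {
  stopifnot(is.matrix(binary))
  binary <- binary > 0
  if (!any(binary)) {
    return(structure(list(labels = matrix(0L, nrow(binary), ncol(binary)),
                          n_nuclei = 0L, source_id = source_id),
                     class = "nuclear_label_map"))
  }
  d <- EBImage::distmap(binary)
  lab <- EBImage::watershed(d, tolerance = h_min, ext = 1)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  kept <- sort(unique(lab[lab > 0]))
  lab <- matrix(match(lab, kept, nomatch = 1L) * (lab > 0), nrow(binary), ncol(binary))
  storage.mode(lab) <- "integer"
  structure(list(labels = lab, n_nuclei = length(kept), source_id = source_id),
            class = "nuclear_label_map")
}

#' Segment nuclei in a preprocessed cluster
#'
#' Convenience wrapper: [binarize_nuclei()] followed by [watershed_split()].
#'
#' @inheritParams binarize_nuclei
#' @inheritParams watershed_split
#' @return a `nuclear_label_map`.
#' @export
segment_nuclei <- function(cluster, h_min = 1, min_nucleus_area_um2 = 10) {
  nuc <- binarize_nuclei(cluster, min_nucleus_area_um2)
  watershed_split(nuc, h_min = h_min, source_id = cluster$id)
}
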