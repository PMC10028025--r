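#' Extract the full 536-feature morphometric vector for one cluster
#'
#' Runs the complete per-cluster pipeline: preprocessing (background
#' removal, artifact filtering, equalization), texture extraction on the
#' illumination-normalized crop (495 features), watershed nuclear
#' segmentation and shape aggregation (41 features). The result is a named,
#' ordered vector of 495 texture + 41 shape = 536 features.
#'
#' @param x a `synthetic_cluster`, `cluster_image`, or grey matrix.
#' @param cfg a [texture_config()].
#' @param pixel_size_um pixel size (used for matrix input).
#' @param h_min watershed suppression depth.
#' @return named numeric vector of length 536, with attributes `cluster_id`
#'   and `label` (when known).
#' @export
extract_features <- function(x, cfg = texture_config(), pixel_size_um = 0.25,
                             h_min = 1) {
  label <- if (inherits(x, "synthetic_cluster")) x$label else NA_character_
  pre <- preprocess_cluster(x, pixel_size_um)
  tex <- texture_features(pre, cfg)
  seg <- segment_nuclei(pre, h_min = h_min)
  if (seg$n_nuclei == 0)
    stop("no nuclei segmented in cluster '", pre$id, "'")
  shp <- shape_features(seg, pre$foreground_mask, pre$pixel_size_um)
  out <- c(tex, shp)
  attr(out, "cluster_id") <- pre$id
  attr(out, "label") <- label
  out
}

#' Feature names of the 536-dimensional vector
#'
#' @param cfg a [texture_config()].
#' @return character vector of length 536 in extraction order.
#' @export
feature_names <- function(cfg = texture_config()) {
  stats5 <- c("mean", "median", "sd", "skewness", "kurtosis")
  tex_maps <- c(paste0("haralick.", haralick_stat_names),
                paste0("collage.", haralick_stat_names),
                as.vector(t(outer(cfg$gabor_frequencies,
                                  seq_along(cfg$gabor_orientations),
                                  function(f, o) sprintf("gabor.f%.3f_o%d", f, o)))),
                paste0("laws.", as.vector(t(outer(names(cfg$laws_vectors),
                                                  names(cfg$laws_vectors), paste0)))))
  c(as.vector(t(outer(tex_maps, stats5, paste, sep = "."))),
    as.vector(t(outer(paste0("shape.", shape_descriptor_names), stats5,
                      paste, sep = "."))),
    "shape.nc_ratio")
}

#' Extract features for every cluster of a cohort
#'
#' Applies [extract_features()] to each cluster of a [make_cohort()] result
#' (or any named list of clusters with a matching manifest) and assembles
#' the feature matrix.
#'
#' @param cohort list with `clusters` and `manifest` as from [make_cohort()].
#' @param cfg a [texture_config()].
#' @param h_min watershed suppression depth.
#' @param verbose print progress every 50 clusters.
#' @return list with `X` (numeric matrix, one row per cluster, 536 named
#'   columns), `y` (factor of labels), `patient_id` (character), `manifest`.
#' @export
extract_cohort_features <- function(cohort, cfg = texture_config(), h_min = 1,
                                    verbose = FALSE) {
  clusters <- cohort$clusters
  manifest <- cohort$manifest
  n <- length(clusters)
  X <- matrix(NA_real_, n, 536)
  for (i in seq_len(n)) {
    fv <- suppressWarnings(extract_features(clusters[[i]], cfg, h_min = h_min))
    if (i == 1) colnames(X) <- names(fv)
    X[i, ] <- fv
    if (verbose && i %% 50 == 0) message("  extracted ", i, "/", n, " clusters")
  }
  rownames(X) <- manifest$cluster_id
  list(X = X,
       y = factor(manifest$label, levels = c("benign", "malignant")),
       patient_id = manifest$patient_id,
       manifest = manifest)
}

#' Write a feature table to CSV
#'
#' One row per cluster: id, patient, label and the 536 named features.
#'
#' @param features result of [extract_cohort_features()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(cluster_id = rownames(features$X),
                   patient_id = features$patient_id,
                   label = as.character(features$y),
                   features$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return list with `X`, `y`, `patient_id`, `manifest`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("cluster_id", "patient_id", "label")
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(X) <- df$cluster_id
  list(X = X,
       y = factor(df$label, levels = c("benign", "malignant")),
       patient_id = df$patient_id,
       manifest = df[, meta])
}
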