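#' Read a grey or RGB image (PNG/TIFF) as an 8-bit matrix
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return grey matrix on the 0-255 scale (RGB input is converted with
#'   [to_grayscale()]).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = {
                if (!requireNamespace("png", quietly = TRUE))
                  stop("the 'png' package is required to read PNG files")
                png::readPNG(path)
              },
              tif = ,
              tiff = {
                if (!requireNamespace("tiff", quietly = TRUE))
                  stop("the 'tiff' package is required to read TIFF files")
                tiff::readTIFF(path)
              },
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3 && dim(x)[3] >= 3)
    x <- to_grayscale(x[, , 1:3] * 255)
  else
    x <- round(as.matrix(x[, , drop = TRUE][, ]) * 255)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Write an 8-bit grey image or a 16-bit label map
#'
#' Grey matrices (0-255) are written as 8-bit PNG/TIFF; integer label maps
#' are written as 16-bit files with labels preserved.
#'
#' @param x grey matrix (0-255) or integer label matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param labels set `TRUE` to write `x` as a 16-bit label map.
#' @return the path, invisibly.
#' @export
write_image <- function(x, path, labels = FALSE) {
  ext <- tolower(tools::file_ext(path))
  v <- if (labels) x / 65535 else x / 255
  v <- pmin(pmax(v, 0), 1)
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write PNG files")
    png::writePNG(v, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files")
    tiff::writeTIFF(v, path, bits.per.sample = if (labels) 16L else 8L)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' Write a cohort to disk (images, truth masks and manifest)
#'
#' Writes each cluster image as PNG, its ground-truth label map as 16-bit
#' TIFF, and a CSV manifest (`patient_id`, `cluster_path`, `mask_path`,
#' `label`, `seed`).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$manifest
  m$cluster_path <- file.path(dir, paste0(m$cluster_id, ".png"))
  m$mask_path <- file.path(dir, paste0(m$cluster_id, "_mask.tiff"))
  for (i in seq_len(nrow(m))) {
    cl <- cohort$clusters[[m$cluster_id[i]]]
    write_image(cl$image, m$cluster_path[i])
    write_image(cl$truth_mask, m$mask_path[i], labels = TRUE)
  }
  write.csv(m[, c("patient_id", "cluster_path", "mask_path", "label", "seed")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
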