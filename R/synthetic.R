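#' Phenotype parameters for the synthetic cluster generator
#'
#' Bundles the morphological knobs that control rendered cell clusters:
#' nuclear size (minor/major axis, mean and sd in micrometres), target
#' solidity, boundary irregularity (relative amplitude of the radial
#' perturbation), chromatin texture heterogeneity (sd, in grey levels, of the
#' smoothed intranuclear intensity field), the expected fraction of touching
#' nucleus pairs, cytoplasm/background grey levels and the pixel size.
#'
#' Presets for the two diagnostic phenotypes are provided by
#' [benign_preset()] and [malignant_preset()]; the malignant preset has a
#' strictly larger mean nuclear minor axis and strictly lower solidity than
#' the benign one, mirroring the reported directions of the discriminative
#' shape features in pancreatobiliary brush cytology.
#'
#' @param n_nuclei number of nuclei to render.
#' @param nucleus_minor_axis_um,nucleus_major_axis_um length-2 numeric
#'   `c(mean, sd)` of the full axis lengths in micrometres.
#' @param solidity_target target nuclear solidity in (0, 1].
#' @param boundary_irregularity amplitude of the sinusoidal radial boundary
#'   perturbation, as a fraction of the local radius (0 disables it).
#' @param chromatin_heterogeneity sd (grey levels) of the smoothed
#'   intranuclear chromatin field.
#' @param overlap_fraction expected fraction of nuclei placed touching an
#'   earlier nucleus, in \[0, 1).
#' @param cytoplasm_intensity,background_intensity grey levels in \[0, 255\].
#' @param pixel_size_um micrometres per pixel (0.25 is typical of a 40x scan).
#' @return an object of class `phenotype_params`.
#' @export
phenotype_params <- function(n_nuclei = 8,
                             nucleus_minor_axis_um = c(6.0, 0.6),
                             nucleus_major_axis_um = c(7.5, 0.8),
                             solidity_target = 0.97,
                             boundary_irregularity = 0.03,
                             chromatin_heterogeneity = 6,
                             overlap_fraction = 0.10,
                             cytoplasm_intensity = 150,
                             background_intensity = 235,
                             pixel_size_um = 0.25) {
  p <- list(
    n_nuclei = as.integer(n_nuclei),
    nucleus_minor_axis_um = as.numeric(nucleus_minor_axis_um),
    nucleus_major_axis_um = as.numeric(nucleus_major_axis_um),
    solidity_target = solidity_target,
    boundary_irregularity = boundary_irregularity,
    chromatin_heterogeneity = chromatin_heterogeneity,
    overlap_fraction = overlap_fraction,
    cytoplasm_intensity = cytoplasm_intensity,
    background_intensity = background_intensity,
    pixel_size_um = pixel_size_um
  )
  class(p) <- "phenotype_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "phenotype_params"))
  if (p$n_nuclei < 1) stop("n_nuclei must be >= 1")
  for (f in c("nucleus_minor_axis_um", "nucleus_major_axis_um")) {
    v <- p[[f]]
    if (length(v) != 2 || v[1] <= 0 || v[2] < 0)
      stop(f, " must be c(mean, sd) with mean > 0 and sd >= 0")
  }
  if (p$nucleus_minor_axis_um[1] > p$nucleus_major_axis_um[1])
    stop("mean minor axis must not exceed mean major axis")
  if (p$solidity_target <= 0 || p$solidity_target > 1)
    stop("solidity_target must be in (0, 1]")
  if (p$boundary_irregularity < 0 || p$boundary_irregularity > 0.5)
    stop("boundary_irregularity must be in [0, 0.5]")
  if (p$chromatin_heterogeneity < 0) stop("chromatin_heterogeneity must be >= 0")
  if (p$overlap_fraction < 0 || p$overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  for (f in c("cytoplasm_intensity", "background_intensity")) {
    if (p[[f]] < 0 || p[[f]] > 255) stop(f, " must be in [0, 255]")
  }
  if (p$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  invisible(p)
}

#' @rdname phenotype_params
#' @export
benign_preset <- function() phenotype_params()

#' @rdname phenotype_params
#' @export
malignant_preset <- function() {
  phenotype_params(
    n_nuclei = 8,
    nucleus_minor_axis_um = c(8.5, 1.2),
    nucleus_major_axis_um = c(11.0, 1.6),
    solidity_target = 0.88,
    boundary_irregularity = 0.10,
    chromatin_heterogeneity = 14,
    overlap_fraction = 0.25
  )
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

# boundary radius multiplier: 1 + sum of low-order harmonics with total
# absolute amplitude `amp`
radial_perturbation <- function(amp, harmonics = 2:5) {
  if (amp <= 0) return(function(phi) rep(1, length(phi)))
  w <- runif(length(harmonics)); w <- w / sum(w) * amp
  psi <- runif(length(harmonics), 0, 2 * pi)
  function(phi) {
    out <- rep(1, length(phi))
    for (i in seq_along(harmonics)) out <- out + w[i] * cos(harmonics[i] * phi + psi[i])
    out
  }
}

# rasterize one nucleus into a logical matrix over the given pixel grid
rasterize_nucleus <- function(rows, cols, cy, cx, a, b, ori, pert) {
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  xr <- cos(ori) * dx + sin(ori) * dy
  yr <- -sin(ori) * dx + cos(ori) * dy
  phi <- atan2(yr, xr)
  rho <- sqrt(xr^2 + yr^2)
  # ellipse radius at angle phi (semi-axes a >= b)
  re <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  rho <= re * pert(phi)
}

# measured solidity of a single-nucleus logical mask (pixel-corner hull)
mask_solidity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  solidity_from_pixels(idx[, 1], idx[, 2])
}

#' Render a synthetic cell cluster with ground-truth nuclear labels
#'
#' Draws `params$n_nuclei` nuclei as radially perturbed ellipses on a
#' cytoplasmic blob over a bright slide background, with a smoothed Gaussian
#' chromatin texture field inside each nucleus. When
#' `params$boundary_irregularity > 0` the perturbation amplitude is
#' calibrated iteratively so that each nucleus' measured solidity approaches
#' `params$solidity_target`; with zero irregularity nuclei are exact
#' (convex) ellipses. Later nuclei occlude earlier ones where they overlap,
#' and fully occluded nuclei are dropped, so truth labels are contiguous
#' `1..K` with `K` the number of visible nuclei.
#'
#' The output is bit-reproducible for a fixed `(params, seed)` pair.
#'
#' @param params a [phenotype_params()] object.
#' @param seed integer seed.
#' @param label optional phenotype label (`"benign"` or `"malignant"`).
#' @return an object of class `synthetic_cluster`: list with `image` (8-bit
#'   grey matrix), `truth_mask` (integer label matrix), `foreground`
#'   (logical cytoplasm+nuclei mask), `params`, `label`, `seed`.
#' @export
render_cluster <- function(params, seed, label = NA_character_) {
  validate_params(params)
  with_seed(seed, {
    n <- params$n_nuclei
    px <- params$pixel_size_um
    # semi-axes in pixels (full axis / 2), truncated below at 30% of the mean
    half_minor <- pmax(rnorm(n, params$nucleus_minor_axis_um[1], params$nucleus_minor_axis_um[2]),
                       0.3 * params$nucleus_minor_axis_um[1]) / 2 / px
    half_major <- pmax(rnorm(n, params$nucleus_major_axis_um[1], params$nucleus_major_axis_um[2]),
                       0.3 * params$nucleus_major_axis_um[1]) / 2 / px
    a <- pmax(half_major, half_minor)
    b <- pmin(half_major, half_minor)
    ori <- runif(n, 0, pi)
    r_eff <- (a + b) / 2

    # sequential centre placement growing one connected epithelial group:
    # each nucleus is attached near an already placed one, either touching
    # (centre distance 0.80 of the radius sum) or with a small cytoplasmic
    # gap (1.12-1.30 of the radius sum)
    centers <- matrix(NA_real_, n, 2)
    centers[1, ] <- c(0, 0)
    if (n > 1) {
      for (k in 2:n) {
        touching <- runif(1) < params$overlap_fraction
        placed <- FALSE
        for (attempt in 1:400) {
          j <- sample.int(k - 1, 1)
          th <- runif(1, 0, 2 * pi)
          fac <- if (touching) 0.85 else runif(1, 1.12, 1.30)
          cand <- centers[j, ] + fac * (r_eff[j] + r_eff[k]) * c(cos(th), sin(th))
          dists <- sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                                   matrix(cand, k - 1, 2, byrow = TRUE))^2))
          lim <- if (touching) 0.55 else 1.05
          if (all(dists > lim * (r_eff[seq_len(k - 1)] + r_eff[k]))) {
            centers[k, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) stop("could not place nucleus ", k, "; parameters overcrowd the canvas")
      }
    }

    # calibrate one shared perturbation amplitude against the solidity target
    amp <- params$boundary_irregularity
    perts <- vector("list", n)
    if (amp > 0) {
      probe_a <- mean(a); probe_b <- mean(b)
      for (iter in 1:6) {
        pert <- radial_perturbation(amp)
        ext <- ceiling(probe_a * 1.6) + 2
        g <- seq(-ext, ext)
        m <- rasterize_nucleus(g, g, 0, 0, probe_a, probe_b, 0, pert)
        sol <- mask_solidity(m)
        if (is.na(sol) || abs(sol - params$solidity_target) <= 0.02) break
        # more amplitude -> less solid; secant-style update on (1 - solidity)
        amp <- min(0.5, max(0.002, amp * (1 - params$solidity_target) /
                              max(1 - sol, 1e-4)))
      }
    }
    for (k in 1:n) perts[[k]] <- radial_perturbation(amp)

    # canvas bounds from nucleus extents plus margin for the cytoplasm rim
    ext_k <- a * 1.6 + 2
    margin <- ceiling(2.0 / px) + 6
    x0 <- floor(min(centers[, 1] - ext_k)) - margin
    x1 <- ceiling(max(centers[, 1] + ext_k)) + margin
    y0 <- floor(min(centers[, 2] - ext_k)) - margin
    y1 <- ceiling(max(centers[, 2] + ext_k)) + margin
    rows <- y0:y1; cols <- x0:x1
    h <- length(rows); w <- length(cols)

    truth <- matrix(0L, h, w)
    for (k in 1:n) {
      inside <- rasterize_nucleus(rows, cols, centers[k, 2], centers[k, 1],
                                  a[k], b[k], ori[k], perts[[k]])
      truth[inside] <- k
    }
    kept <- sort(unique(truth[truth > 0]))
    if (length(kept) == 0) stop("no nucleus survived rasterization")
    truth <- matrix(match(truth, kept, nomatch = 1L) * (truth > 0), h, w)
    storage.mode(truth) <- "integer"

    # cytoplasm: dilated union of nuclei (~2 um rim); if the blob still
    # fragments, close it with progressively larger brushes so the cluster
    # is one connected component
    rim <- max(3L, as.integer(round(2.0 / px)))
    brush <- EBImage::makeBrush(2L * rim + 1L, shape = "disc")
    fg <- EBImage::dilate(truth > 0, brush) > 0
    for (grow in c(5L, 9L, 15L)) {
      if (max(EBImage::bwlabel(fg)) <= 1) break
      cb <- EBImage::makeBrush(2L * grow + 1L, shape = "disc")
      fg <- EBImage::erode(EBImage::dilate(fg, cb), cb) > 0
    }

    img <- matrix(params$background_intensity, h, w) + matrix(rnorm(h * w, 0, 2), h, w)
    cyt <- fg & truth == 0
    img[cyt] <- params$cytoplasm_intensity + rnorm(sum(cyt), 0, 3)

    nucleus_base <- max(30, params$cytoplasm_intensity - 70)
    field <- apply_kernel(matrix(rnorm(h * w), h, w), gaussian_kernel(1.5))
    field <- field / sd(field)
    base_jitter <- rnorm(length(kept), 0, 3)
    nuc <- truth > 0
    img[nuc] <- nucleus_base + base_jitter[truth[nuc]] +
      params$chromatin_heterogeneity * field[nuc] + rnorm(sum(nuc), 0, 1.5)

    img <- matrix(as.numeric(pmin(pmax(round(img), 0), 255)), h, w)

    structure(list(image = img, truth_mask = truth, foreground = fg,
                   params = params, label = label, seed = as.integer(seed)),
              class = "synthetic_cluster")
  })
}

#' Generate a labeled synthetic cohort grouped by patient
#'
#' Renders `clusters_per_patient` clusters for each of `n_benign` benign and
#' `n_malignant` malignant synthetic patients. Each patient carries a small
#' random effect (a shift of the mean nuclear axis lengths and a
#' multiplicative factor on chromatin heterogeneity) so clusters from the
#' same patient are correlated, which is what makes patient-level
#' cross-validation meaningful.
#'
#' @param n_benign,n_malignant patient counts (each >= 1).
#' @param benign,malignant [phenotype_params()] presets for the two classes.
#' @param clusters_per_patient clusters rendered per patient (default 5, the
#'   usual number of annotated clusters per slide).
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return list with `clusters` (named list of [render_cluster()] outputs)
#'   and `manifest` (data.frame: patient_id, cluster_id, label, seed).
#' @export
make_cohort <- function(n_benign, n_malignant,
                        benign = benign_preset(),
                        malignant = malignant_preset(),
                        clusters_per_patient = 5, seed = 1) {
  stopifnot(n_benign >= 1, n_malignant >= 1, clusters_per_patient >= 1)
  validate_params(benign); validate_params(malignant)
  n_pat <- n_benign + n_malignant
  n_tot <- n_pat * clusters_per_patient

  plan <- with_seed(seed, {
    list(
      cluster_seeds = sample.int(2147483646L, n_tot),
      minor_shift = rnorm(n_pat, 0, 0.15),
      het_factor = exp(rnorm(n_pat, 0, 0.08))
    )
  })

  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  patient_ids <- sprintf("P%03d", seq_len(n_pat))
  clusters <- vector("list", n_tot)
  manifest <- data.frame(patient_id = character(n_tot), cluster_id = character(n_tot),
                         label = character(n_tot), seed = integer(n_tot),
                         stringsAsFactors = FALSE)
  idx <- 0L
  for (p in seq_len(n_pat)) {
    base <- if (labels[p] == "benign") benign else malignant
    pp <- base
    ratio <- base$nucleus_major_axis_um[1] / base$nucleus_minor_axis_um[1]
    pp$nucleus_minor_axis_um[1] <- max(0.5, base$nucleus_minor_axis_um[1] + plan$minor_shift[p])
    pp$nucleus_major_axis_um[1] <- max(pp$nucleus_minor_axis_um[1],
                                       base$nucleus_major_axis_um[1] + plan$minor_shift[p] * ratio)
    pp$chromatin_heterogeneity <- base$chromatin_heterogeneity * plan$het_factor[p]
    for (ci in seq_len(clusters_per_patient)) {
      idx <- idx + 1L
      cid <- sprintf("%s_C%02d", patient_ids[p], ci)
      cl <- render_cluster(pp, plan$cluster_seeds[idx], label = labels[p])
      clusters[[idx]] <- cl
      manifest[idx, ] <- list(patient_ids[p], cid, labels[p], plan$cluster_seeds[idx])
    }
  }
  names(clusters) <- manifest$cluster_id
  list(clusters = clusters, manifest = manifest)
}

#' Compose a slide-scale patch from synthetic clusters
#'
#' Pastes pre-rendered clusters onto a bright background canvas at
#' non-overlapping random positions and scatters small dark artifacts
#' (below the 100 um^2 cluster-area threshold at 0.25 um/px), returning the
#' ground-truth bounding boxes. Used to exercise the automatic cluster
#' detection path end to end.
#'
#' @param clusters list of `synthetic_cluster` objects (may be empty).
#' @param canvas_px integer length-2 `c(height, width)` canvas size.
#' @param background_intensity background grey level.
#' @param artifact_count number of small dark artifacts to add.
#' @param seed integer seed.
#' @return list with `image`, `boxes` (data.frame `cluster`, `x0`, `y0`,
#'   `x1`, `y1`; 0-based half-open pixel coordinates, x = column,
#'   y = row) and `masks` (list of placed foreground masks with offsets).
#' @export
make_patch <- function(clusters, canvas_px = c(1000, 1000),
                       background_intensity = 235, artifact_count = 0, seed = 1) {
  stopifnot(length(canvas_px) == 2, all(canvas_px >= 64))
  with_seed(seed, {
    h <- canvas_px[1]; w <- canvas_px[2]
    img <- matrix(background_intensity, h, w) + matrix(rnorm(h * w, 0, 2), h, w)
    boxes <- data.frame(cluster = character(0), x0 = integer(0), y0 = integer(0),
                        x1 = integer(0), y1 = integer(0), stringsAsFactors = FALSE)
    masks <- list()
    occupied <- matrix(FALSE, h, w)

    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      ch <- nrow(cl$image); cw <- ncol(cl$image)
      if (ch > h || cw > w) stop("cluster ", k, " does not fit on the canvas")
      placed <- FALSE
      for (attempt in 1:200) {
        r0 <- sample.int(h - ch + 1L, 1)
        c0 <- sample.int(w - cw + 1L, 1)
        if (!any(occupied[r0:(r0 + ch - 1), c0:(c0 + cw - 1)])) { placed <- TRUE; break }
      }
      if (!placed) stop("canvas overcrowded: could not place cluster ", k)
      sub <- img[r0:(r0 + ch - 1), c0:(c0 + cw - 1)]
      sub[cl$foreground] <- cl$image[cl$foreground]
      img[r0:(r0 + ch - 1), c0:(c0 + cw - 1)] <- sub
      occupied[r0:(r0 + ch - 1), c0:(c0 + cw - 1)] <- TRUE

      fg_idx <- which(cl$foreground, arr.ind = TRUE)
      rr <- range(fg_idx[, 1]); cc <- range(fg_idx[, 2])
      boxes <- rbind(boxes, data.frame(
        cluster = if (!is.null(names(clusters)[k]) && nzchar(names(clusters)[k]))
          names(clusters)[k] else sprintf("cluster%02d", k),
        x0 = c0 - 1L + cc[1] - 1L, y0 = r0 - 1L + rr[1] - 1L,
        x1 = c0 - 1L + cc[2], y1 = r0 - 1L + rr[2],
        stringsAsFactors = FALSE))
      masks[[length(masks) + 1L]] <- list(mask = cl$foreground, r0 = r0 - 1L, c0 = c0 - 1L)
    }

    if (artifact_count > 0) {
      for (k in seq_len(artifact_count)) {
        rad <- sample(3:8, 1)
        for (attempt in 1:200) {
          rc <- sample.int(h - 2 * rad, 1) + rad
          cc <- sample.int(w - 2 * rad, 1) + rad
          if (!any(occupied[(rc - rad):(rc + rad), (cc - rad):(cc + rad)])) break
        }
        dy <- outer((-rad):rad, rep(1, 2 * rad + 1))
        dx <- outer(rep(1, 2 * rad + 1), (-rad):rad)
        disc <- dy^2 + dx^2 <= rad^2
        sub <- img[(rc - rad):(rc + rad), (cc - rad):(cc + rad)]
        sub[disc] <- 100 + rnorm(sum(disc), 0, 3)
        img[(rc - rad):(rc + rad), (cc - rad):(cc + rad)] <- sub
      }
    }

    img <- matrix(as.numeric(pmin(pmax(round(img), 0), 255)), h, w)
    list(image = img, boxes = boxes, masks = masks)
  })
}
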