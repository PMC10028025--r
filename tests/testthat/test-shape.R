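disc_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  dy <- outer(1:n - (r + pad + 1), rep(1, n)); dx <- t(dy)
  matrix(as.integer(dy^2 + dx^2 <= r^2), n, n)
}

test_that("a rasterized disc has the expected geometry", {
  d <- nucleus_descriptors(disc_mask(20), pixel_size_um = 0.25)
  expect_gte(d$solidity, 0.98)
  expect_equal(d$minor_axis_um, 10, tolerance = 0.03)
  expect_equal(d$major_axis_um, 10, tolerance = 0.03)
  expect_lt(d$eccentricity, 0.2)
  expect_equal(d$circularity, 1, tolerance = 0.06)
  expect_equal(d$equivalent_diameter_um, 10, tolerance = 0.03)
})

test_that("rectangle axes match the analytic second-moment oracle", {
  m <- matrix(0L, 60, 30)
  m[10:49, 10:19] <- 1L  # 40 x 10 px rectangle
  d <- nucleus_descriptors(m, pixel_size_um = 0.25)
  # uniform rectangle: axis = 4 * sqrt(side^2 / 12) = side * 2 / sqrt(3)
  expect_equal(d$major_axis_um / d$minor_axis_um, 4, tolerance = 0.02)
  expect_equal(d$major_axis_um, 40 * 2 / sqrt(3) * 0.25, tolerance = 0.02)
  expect_equal(d$minor_axis_um, 10 * 2 / sqrt(3) * 0.25, tolerance = 0.02)
  expect_gte(d$solidity, 0.98)
})

test_that("a plus-shaped region matches the convex-hull pixel oracle", {
  a <- 15
  m <- matrix(0L, 3 * a + 10, 3 * a + 10)
  m[(a + 5):(2 * a + 4), 5:(3 * a + 4)] <- 1L   # horizontal bar
  m[5:(3 * a + 4), (a + 5):(2 * a + 4)] <- 1L   # vertical bar
  d <- nucleus_descriptors(m, pixel_size_um = 0.25)
  # oracle: rasterize the convex hull (corner cut at 45 degrees) and count
  idx <- which(m == 1L, arr.ind = TRUE)
  hull_area <- 9 * a^2 - 4 * (a^2 / 2)  # 3a x 3a square minus 4 corner triangles
  expect_equal(d$solidity, (5 * a^2) / hull_area, tolerance = 0.05)
})

test_that("length descriptors scale with pixel size, dimensionless ones do not", {
  m <- disc_mask(15)
  d1 <- nucleus_descriptors(m, pixel_size_um = 0.25)
  d2 <- nucleus_descriptors(m, pixel_size_um = 0.5)
  expect_equal(d2$minor_axis_um, 2 * d1$minor_axis_um)
  expect_equal(d2$perimeter_um, 2 * d1$perimeter_um)
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$solidity, d1$solidity)
  expect_equal(d2$eccentricity, d1$eccentricity)
  expect_equal(d2$circularity, d1$circularity)
})

test_that("aggregation implements the 5-statistic contract exactly", {
  m <- disc_mask(10)
  single <- aggregate_shape(nucleus_descriptors(m, 0.25))
  expect_length(single, 40)
  expect_equal(unname(single["shape.area_um2.sd"]), 0)
  expect_equal(unname(single["shape.area_um2.skewness"]), 0)
  expect_equal(unname(single["shape.area_um2.mean"]),
               unname(single["shape.area_um2.median"]))

  df <- data.frame(area_um2 = c(1, 2), perimeter_um = c(1, 2),
                   major_axis_um = c(1, 2), minor_axis_um = c(4, 6),
                   eccentricity = c(0, 1), solidity = c(1, 1),
                   circularity = c(1, 1), equivalent_diameter_um = c(1, 2))
  agg <- aggregate_shape(df)
  expect_equal(unname(agg["shape.minor_axis_um.median"]), 5)

  # 10-nucleus cluster: aggregates equal the direct moment formulas
  cl <- render_cluster(phenotype_params(n_nuclei = 10, overlap_fraction = 0), 31)
  sh <- nucleus_descriptors(cl$truth_mask, 0.25)
  agg <- aggregate_shape(sh)
  v <- sh$minor_axis_um
  mu <- mean(v); s <- sqrt(mean((v - mu)^2))
  expect_equal(unname(agg["shape.minor_axis_um.mean"]), mu, tolerance = 1e-10)
  expect_equal(unname(agg["shape.minor_axis_um.sd"]), s, tolerance = 1e-10)
  expect_equal(unname(agg["shape.minor_axis_um.skewness"]),
               mean((v - mu)^3) / s^3, tolerance = 1e-10)
  expect_equal(unname(agg["shape.minor_axis_um.kurtosis"]),
               mean((v - mu)^4) / s^4, tolerance = 1e-10)
})

test_that("the N:C ratio is a pure pixel-count quotient", {
  fg <- matrix(TRUE, 10, 10)
  lab <- matrix(0L, 10, 10); lab[1:5, ] <- 1L
  expect_equal(nc_ratio(lab, fg), 1)
  lab2 <- matrix(0L, 12, 12); lab2[1:4, 1:12] <- 1L
  expect_equal(nc_ratio(lab2, matrix(TRUE, 12, 12)), 0.5)
  expect_error(nc_ratio(matrix(1L, 5, 5), matrix(TRUE, 5, 5)), "degenerate")

  cl <- fixture_cluster(103)
  r <- nc_ratio(cl$truth_mask, cl$foreground)
  expect_equal(r, sum(cl$truth_mask > 0) /
                 (sum(cl$foreground) - sum(cl$truth_mask > 0)))
})

test_that("shape feature vector has 41 named entries", {
  cl <- fixture_cluster(104)
  fv <- shape_features(cl$truth_mask, cl$foreground, 0.25)
  expect_length(fv, 41)
  expect_identical(names(fv)[41], "shape.nc_ratio")
  expect_error(nucleus_descriptors(matrix(0L, 5, 5)), "empty label map")
})

test_that("preset phenotypes shift shape features in the reported directions", {
  stats <- lapply(list(benign_preset(), malignant_preset()), function(p) {
    res <- vapply(1:4, function(s) {
      cl <- render_cluster(p, seed = 300 + s)
      sh <- nucleus_descriptors(cl$truth_mask, p$pixel_size_um)
      c(minor = median(sh$minor_axis_um), sol = mean(sh$solidity))
    }, numeric(2))
    rowMeans(res)
  })
  # malignant: longer minor axis, lower solidity
  expect_gt(stats[[2]]["minor"], stats[[1]]["minor"])
  expect_lt(stats[[2]]["sol"], stats[[1]]["sol"])
})
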