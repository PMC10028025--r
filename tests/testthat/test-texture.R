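test_that("Haralick maps on a constant image are degenerate as expected", {
  img <- matrix(5, 12, 12)
  maps <- haralick_maps(img, texture_config())
  expect_length(maps, 13)
  expect_true(all(maps$haralick.contrast == 0))
  expect_true(all(maps$haralick.energy == 1))
})

test_that("windowed Haralick maps equal brute-force pair enumeration", {
  # two-level checkerboard
  q <- matrix(0L, 8, 8)
  q[(row(q) + col(q)) %% 2 == 0] <- 1L
  fast <- haralick_maps(q, texture_config(gray_levels = 2))
  slow <- oracle_glcm_stats(q, 2, 5)
  for (nm in names(slow))
    expect_lt(max(abs(fast[[paste0("haralick.", nm)]] - slow[[nm]])), 1e-10)

  # random multi-level fixture
  set.seed(8)
  q2 <- matrix(sample(0:3, 81, replace = TRUE), 9, 9)
  fast2 <- haralick_maps(q2, texture_config(gray_levels = 4))
  slow2 <- oracle_glcm_stats(q2, 4, 5)
  for (nm in names(slow2))
    expect_lt(max(abs(fast2[[paste0("haralick.", nm)]] - slow2[[nm]])), 1e-10)
})

test_that("dominant orientations match a per-window SVD oracle", {
  set.seed(9)
  img <- matrix(rnorm(81), 9, 9)
  theta <- dominant_orientation(img, 5)
  ref <- oracle_orientation(img, 5)
  interior <- !is.na(ref)
  expect_lt(max(angdiff_mod_pi(theta[interior], ref[interior])), 1e-8)
})

test_that("CoLlAGe maps of a linear ramp show a single orientation", {
  ramp <- outer(rep(1, 15), seq(0, 140, by = 10))
  theta <- dominant_orientation(ramp, 5)
  expect_lt(max(angdiff_mod_pi(theta[4:12, 4:12], 0)), 1e-8)
  maps <- collage_maps(ramp, texture_config())
  expect_length(maps, 13)
  expect_lt(max(abs(maps$collage.entropy[4:12, 4:12])), 1e-10)
})

test_that("the Gabor bank is DC-free and peaks at the matching grating", {
  cfg <- texture_config()
  zero <- gabor_bank(matrix(0, 40, 40), cfg)
  expect_length(zero, 48)
  expect_lt(max(vapply(zero, max, numeric(1))), 1e-9)
  # constant image: DC-free kernels respond (near) zero away from borders
  const <- gabor_bank(matrix(100, 60, 60), cfg)
  interior <- vapply(const, function(m) max(abs(m[20:40, 20:40])), numeric(1))
  expect_lt(max(interior), 1e-6)

  # grating at a grid frequency/orientation maximizes its own filter
  f <- cfg$gabor_frequencies[4]; ori <- cfg$gabor_orientations[3]
  x <- outer(rep(1, 80), 1:80); y <- outer(1:80, rep(1, 80))
  grating <- 50 * cos(2 * pi * f * (x * cos(ori) + y * sin(ori)))
  resp <- gabor_bank(grating, cfg)
  means <- vapply(resp, function(m) mean(m[20:60, 20:60]), numeric(1))
  expect_identical(names(which.max(means)), sprintf("gabor.f%.3f_o%d", f, 3))
})

test_that("Law's responses equal dense convolution with the explicit kernels", {
  cfg <- texture_config()
  set.seed(10)
  img <- matrix(rnorm(49), 7, 7)
  bank <- laws_bank(img, cfg)
  expect_length(bank, 25)
  for (n1 in names(cfg$laws_vectors)) {
    for (n2 in names(cfg$laws_vectors)) {
      k <- outer(cfg$laws_vectors[[n1]], cfg$laws_vectors[[n2]])
      ref <- oracle_correlate(img, k)
      got <- bank[[paste0("laws.", n1, n2)]]
      expect_equal(got[!is.na(ref)], ref[!is.na(ref)], tolerance = 1e-12)
    }
  }
  # constant image: zero response for every kernel with a zero-sum factor
  const <- laws_bank(matrix(3, 10, 10), cfg)
  for (nm in names(const)) {
    if (nm == "laws.L5L5") expect_true(all(const[[nm]] > 0))
    else expect_lt(max(abs(const[[nm]])), 1e-9)
  }
})

test_that("summaries implement the five-statistic contract", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  fg <- matrix(TRUE, 2, 2)
  st <- summarize_maps(list(x = m), fg)
  expect_equal(unname(st["x.mean"]), 2.5)
  expect_equal(unname(st["x.median"]), 2.5)
  expect_equal(unname(st["x.sd"]), sqrt(1.25))  # population sd
  expect_warning(st2 <- summarize_maps(list(x = matrix(7, 2, 2)), fg), "constant")
  expect_equal(unname(st2[c("x.sd", "x.skewness", "x.kurtosis")]), c(0, 0, 0))
  expect_error(summarize_maps(list(x = m), matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)),
               "4 foreground")
})

test_that("moment summaries agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  v <- rnorm(500)
  st <- summarize_maps(list(x = matrix(v, 20, 25)), matrix(TRUE, 20, 25))
  expect_equal(unname(st["x.skewness"]), e1071::skewness(v, type = 1),
               tolerance = 1e-10)
  # e1071 type-1 kurtosis is excess kurtosis; ours is plain
  expect_equal(unname(st["x.kurtosis"]), e1071::kurtosis(v, type = 1) + 3,
               tolerance = 1e-10)
})

test_that("rotating the input by 90 degrees permutes Gabor orientations and
           leaves direction-averaged co-occurrence summaries stable", {
  cl <- fixture_cluster(101)
  pre <- preprocess_cluster(cl)
  norm <- normalize_illumination(pre$pixels, 15)
  fg <- pre$foreground_mask
  cfg <- texture_config()

  rot_norm <- t(norm[nrow(norm):1, ])   # 90 degree rotation
  rot_fg <- t(fg[nrow(fg):1, ])

  h1 <- summarize_maps(haralick_maps(norm, cfg, fg), fg)
  h2 <- summarize_maps(haralick_maps(rot_norm, cfg, rot_fg), rot_fg)
  rel <- abs(h1 - h2) / pmax(abs(h1), 1e-6)
  expect_lt(stats::median(rel), 0.01)
  expect_lt(max(rel[grepl("\\.mean$", names(rel))]), 0.01)

  g1 <- vapply(gabor_bank(norm, cfg), function(m) mean(m[fg]), numeric(1))
  g2 <- vapply(gabor_bank(rot_norm, cfg), function(m) mean(m[rot_fg]), numeric(1))
  # rotation by 90 deg maps orientation index o to o+4 (mod 8)
  perm <- unlist(lapply(0:5, function(fi) fi * 8 + (((1:8) - 1 + 4) %% 8) + 1))
  expect_equal(unname(g1), unname(g2[perm]), tolerance = 0.02)
})

test_that("the full texture vector has 495 deterministic named entries", {
  cl <- fixture_cluster(102)
  pre <- preprocess_cluster(cl)
  tex <- suppressWarnings(texture_features(pre))
  expect_length(tex, 495)
  expect_false(anyDuplicated(names(tex)) > 0)
  expect_true(all(is.finite(tex)))
  tex2 <- suppressWarnings(texture_features(pre))
  expect_identical(tex, tex2)
  # family counts: 13 + 13 + 48 + 25 maps, each with 5 statistics
  fam <- vapply(strsplit(names(tex), "\\."), `[`, character(1), 1)
  expect_equal(unname(table(fam)[c("haralick", "collage", "gabor", "laws")]),
               c(65L, 65L, 240L, 125L), ignore_attr = TRUE)
})
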