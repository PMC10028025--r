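# Independent brute-force oracles used to validate the fast implementations.
# These deliberately mirror the *definitions*, not the implementation
# shortcuts (no log tables, no touched-cell bookkeeping, no separability).

# windowed co-occurrence statistics by direct pair enumeration and dense
# matrix formulas; q has 0-based levels
oracle_glcm_stats <- function(q, levels, window) {
  nr <- nrow(q); nc <- ncol(q); h <- window %/% 2
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  stat_names <- c("energy", "contrast", "correlation", "variance",
                  "inverse_difference_moment", "sum_average", "sum_variance",
                  "sum_entropy", "entropy", "difference_variance",
                  "difference_entropy", "info_measure_1", "info_measure_2")
  maps <- lapply(stat_names, function(s) matrix(NA_real_, nr, nc))
  names(maps) <- stat_names
  iv <- seq_len(levels)  # 1-based level values
  for (r in 1:nr) {
    for (c in 1:nc) {
      r0 <- max(1, r - h); r1 <- min(nr, r + h)
      c0 <- max(1, c - h); c1 <- min(nc, c + h)
      P <- matrix(0, levels, levels)
      for (o in offs) {
        for (i in r0:r1) {
          for (j in c0:c1) {
            i2 <- i + o[1]; j2 <- j + o[2]
            if (i2 >= r0 && i2 <= r1 && j2 >= c0 && j2 <= c1) {
              a <- q[i, j] + 1L; b <- q[i2, j2] + 1L
              P[a, b] <- P[a, b] + 1
              P[b, a] <- P[b, a] + 1
            }
          }
        }
      }
      P <- P / sum(P)
      px <- rowSums(P); py <- colSums(P)
      mux <- sum(iv * px); muy <- sum(iv * py)
      sdx <- sqrt(sum(iv^2 * px) - mux^2); sdy <- sqrt(sum(iv^2 * py) - muy^2)
      II <- matrix(iv, levels, levels); JJ <- t(II)
      xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
      ent <- -sum(xlogx(P))
      hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
      lpxy <- matrix(0, levels, levels)
      pos <- P > 0
      lpxy[pos] <- log(outer(px, py)[pos])
      hxy1 <- -sum(P[pos] * lpxy[pos])
      psum <- sapply(2:(2 * levels), function(k) sum(P[II + JJ == k]))
      ks <- 2:(2 * levels)
      sa <- sum(ks * psum)
      pdiff <- sapply(0:(levels - 1), function(k) sum(P[abs(II - JJ) == k]))
      kd <- 0:(levels - 1)
      da <- sum(kd * pdiff)
      maps$energy[r, c] <- sum(P^2)
      maps$contrast[r, c] <- sum((II - JJ)^2 * P)
      maps$correlation[r, c] <- if (sdx > 0 && sdy > 0)
        (sum(II * JJ * P) - mux * muy) / (sdx * sdy) else 0
      maps$variance[r, c] <- sum((II - mux)^2 * P)
      maps$inverse_difference_moment[r, c] <- sum(P / (1 + (II - JJ)^2))
      maps$sum_average[r, c] <- sa
      maps$sum_variance[r, c] <- sum((ks - sa)^2 * psum)
      maps$sum_entropy[r, c] <- -sum(xlogx(psum))
      maps$entropy[r, c] <- ent
      maps$difference_variance[r, c] <- sum((kd - da)^2 * pdiff)
      maps$difference_entropy[r, c] <- -sum(xlogx(pdiff))
      maps$info_measure_1[r, c] <- if (max(hx, hy) > 0)
        (ent - hxy1) / max(hx, hy) else 0
      maps$info_measure_2[r, c] <- sqrt(max(0, 1 - exp(-2 * (hx + hy - ent))))
    }
  }
  maps
}

# central-difference gradients with duplicated edges (independent of the
# package's index-vector implementation)
oracle_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  at <- function(i, j) img[min(max(i, 1), nr), min(max(j, 1), nc)]
  for (i in 1:nr) for (j in 1:nc) {
    gx[i, j] <- (at(i, j + 1) - at(i, j - 1)) / 2
    gy[i, j] <- (at(i + 1, j) - at(i - 1, j)) / 2
  }
  list(gx = gx, gy = gy)
}

# dominant orientation by per-window SVD of the stacked gradient matrix
oracle_orientation <- function(img, window) {
  g <- oracle_gradients(img)
  h <- window %/% 2
  nr <- nrow(img); nc <- ncol(img)
  theta <- matrix(NA_real_, nr, nc)
  for (r in (h + 1):(nr - h)) {
    for (c in (h + 1):(nc - h)) {
      G <- cbind(as.vector(g$gx[(r - h):(r + h), (c - h):(c + h)]),
                 as.vector(g$gy[(r - h):(r + h), (c - h):(c + h)]))
      if (sum(G^2) < 1e-12) { theta[r, c] <- 0; next }
      v <- svd(G)$v[, 1]
      a <- atan2(v[2], v[1]) %% pi
      theta[r, c] <- a
    }
  }
  theta
}

# dense 2-D correlation by explicit loops (valid on interior pixels only)
oracle_correlate <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- nrow(kernel) %/% 2; hc <- ncol(kernel) %/% 2
  out <- matrix(NA_real_, nr, nc)
  for (r in (hr + 1):(nr - hr)) {
    for (c in (hc + 1):(nc - hc)) {
      acc <- 0
      for (a in -hr:hr) for (b in -hc:hc)
        acc <- acc + kernel[a + hr + 1, b + hc + 1] * img[r + a, c + b]
      out[r, c] <- acc
    }
  }
  out
}

# exact two-sided rank-sum p-value by enumerating all rank assignments
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(n)])
  combos <- utils::combn(n + m, n)
  stats <- apply(combos, 2, function(idx) sum(seq_len(n + m)[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# angular difference modulo pi
angdiff_mod_pi <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# small deterministic cluster fixtures shared across tests
fixture_cluster <- function(seed = 11, preset = benign_preset()) {
  render_cluster(preset, seed = seed, label = "benign")
}
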