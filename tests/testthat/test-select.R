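make_blobs <- function(n_per_class = 20, p_noise = 4, sep = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("benign", "malignant"), each = n_per_class),
              levels = c("benign", "malignant"))
  X <- cbind(signal = rnorm(2 * n_per_class) + sep * (y == "malignant"),
             matrix(rnorm(2 * n_per_class * p_noise), ncol = p_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(X = X, y = y)
}

test_that("rank-sum p-values agree with exhaustive rank enumeration", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  rk <- rank_univariate(X, y, "wilcoxon")
  expect_equal(rk$p_value, 0.1)
  expect_equal(rk$p_value, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  # a second configuration, also against the oracle
  x2 <- c(1.3, 0.2, 2.1, 5.0, 0.9, 1.7, 3.3, 4.1)
  y2 <- factor(rep(c("a", "b"), each = 4))
  rk2 <- rank_univariate(matrix(x2, ncol = 1, dimnames = list(NULL, "f")), y2,
                         "wilcoxon")
  expect_equal(rk2$p_value, oracle_ranksum_p(x2[1:4], x2[5:8]))
})

test_that("ranking puts label-aligned features first and survives constants", {
  d <- make_blobs(seed = 2)
  X <- cbind(d$X, constant = rep(1, nrow(d$X)))
  for (m in c("wilcoxon", "ttest")) {
    rk <- rank_univariate(X, d$y, m)
    expect_identical(rk$feature[1], "signal")
    expect_equal(rk$p_value[rk$feature == "constant"], 1)
  }
})

test_that("under a permuted-label null, about alpha of features are significant", {
  set.seed(13)
  n <- 60; p <- 200
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  rk <- rank_univariate(X, y, "ttest")
  frac <- mean(rk$p_value <= 0.05)
  # binomial 3-sigma band around 0.05
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / p))
})

test_that("mRMR never selects redundant duplicates and prefers informative features", {
  d <- make_blobs(seed = 3)
  X <- cbind(d$X, dup = d$X[, "signal"])  # exact duplicate column
  cfg <- selection_config(method = "mrmr", k_top = 2)
  sel <- select_mrmr(X, d$y, cfg)
  expect_identical(sel$feature[1], "signal")  # first selected by max relevance
  expect_false(all(c("signal", "dup") %in% sel$feature))
})

test_that("mRMR matches exhaustive search over admissible pairs", {
  set.seed(4)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  yn <- as.numeric(y == "b")
  strong <- yn + rnorm(n, 0, 0.5)
  X <- cbind(strong = strong,
             twin = strong + rnorm(n, 0, 0.6),       # redundant, noisier copy
             partner = yn + rnorm(n, 0, 1.2),        # complementary signal
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  cfg <- selection_config(method = "mrmr", k_top = 2)
  sel <- select_mrmr(X, y, cfg)$feature

  rel <- abs(cor(X, yn))[, 1]
  R <- abs(cor(X))
  nm <- colnames(X)
  best <- NULL; best_score <- -Inf
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j || R[i, j] > 0.7) next
    score <- rel[i] + rel[j] - R[i, j]
    if (score > best_score) { best_score <- score; best <- sort(nm[c(i, j)]) }
  }
  expect_identical(sort(sel), best)
})

test_that("stability selection is seed-deterministic and finds dominant features", {
  d <- make_blobs(n_per_class = 15, sep = 5, seed = 5)
  cfg <- selection_config(method = "ttest", k_top = 1, cv_iterations = 10, seed = 3)
  st <- select_stable(d$X, d$y, cfg)
  expect_identical(st$features, "signal")
  expect_equal(unname(st$frequency["signal"]), 1)
  st2 <- select_stable(d$X, d$y, cfg)
  expect_identical(st$frequency, st2$frequency)
})

test_that("the multi-expert scheme partitions the majority class as specified", {
  set.seed(6)
  y <- factor(c(rep("benign", 3), rep("malignant", 5)),
              levels = c("benign", "malignant"))
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  X[, 1] <- X[, 1] + 3 * (y == "malignant")
  m <- fit_multi_expert(X, y, "lda", seed = 2)
  expect_length(m$experts, 2)
  e1 <- m$expert_index[[1]]; e2 <- m$expert_index[[2]]
  expect_identical(sum(y[e1] == "benign"), 3L)     # all b minority
  expect_identical(sum(y[e1] == "malignant"), 3L)  # b sampled majority
  expect_identical(sum(y[e2] == "malignant"), 2L)  # the (m - b) complement
  expect_identical(sum(y[e2] == "benign"), 2L)     # (m - b) resampled minority
  # majority examples are used at most once per expert and cover all of m
  maj <- which(y == "malignant")
  expect_identical(sort(c(intersect(e1, maj), intersect(e2, maj))), maj)

  # balanced classes: a single expert on all data
  yb <- factor(rep(c("benign", "malignant"), each = 4))
  Xb <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  mb <- fit_multi_expert(Xb, yb, "lda", seed = 2)
  expect_length(mb$experts, 1)
  expect_identical(mb$expert_index[[1]], 1:8)
})

test_that("multi-expert training separates well-separated Gaussian blobs", {
  d <- make_blobs(n_per_class = 20, sep = 4, seed = 7)
  for (learner in c("lda", "qda", "bagged_c45")) {
    m <- fit_multi_expert(d$X, d$y, learner, seed = 4, ntree = 25)
    p <- predict(m, d$X)
    acc <- mean((p >= 0.5) == (d$y == "malignant"))
    expect_gte(acc, 0.95)
  }
})

test_that("patient aggregation follows the configured rule", {
  probs <- c(0.2, 0.4, 0.9, 0.9)
  ids <- c("p1", "p1", "p2", "p2")
  expect_equal(predict_patients(probs, ids, "mean")$p_mal, c(0.3, 0.9))
  expect_equal(predict_patients(probs, ids, "max")$p_mal, c(0.4, 0.9))
  expect_equal(predict_patients(probs, ids, "median")$p_mal, c(0.3, 0.9))
  expect_identical(predict_patients(probs, ids)$n_clusters, c(2L, 2L))
})

test_that("evaluation produces coherent ROC, AUC and confusion output", {
  y <- factor(rep(c("benign", "malignant"), each = 5))
  perfect <- c(runif(5, 0, 0.2), runif(5, 0.8, 1))
  ev <- evaluate(perfect, y, threshold = 0.5)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(sum(ev$confusion), 10)

  # AUC invariant under strictly monotone transforms
  set.seed(8)
  p <- runif(40); yy <- factor(sample(rep(c("benign", "malignant"), 20)))
  expect_equal(evaluate(p, yy)$auc, evaluate(p^3, yy)$auc)
  expect_equal(evaluate(p, yy)$auc, evaluate(plogis(5 * p - 2), yy)$auc)
  expect_error(evaluate(p[1:5], factor(rep("malignant", 5), levels = c("benign", "malignant"))),
               "single class")
})

test_that("trapezoidal AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  p <- runif(60)
  y <- factor(ifelse(runif(60) < plogis(4 * p - 2), "malignant", "benign"),
              levels = c("benign", "malignant"))
  if (length(unique(y)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, levels = c("benign", "malignant"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(evaluate(p, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("published-cohort arithmetic reproduces the reported diagnostics", {
  counts <- validation_cohort_counts()
  expect_equal(sum(counts$n), 66)
  ds <- diagnostic_summary(counts)
  expect_equal(round(100 * ds$machine_sensitivity), 68)
  expect_equal(round(100 * ds$machine_specificity), 93)
  expect_equal(round(100 * ds$cytology_sensitivity_excl_atypical), 74)
  expect_equal(round(100 * ds$cytology_sensitivity_incl_atypical), 46)
  expect_equal(ds$atypical_machine_specificity, 1)
})

test_that("cross-validation is seed-stable, keeps patients intact, and is
           calibrated at the null", {
  set.seed(10)
  n_pat <- 24; cpp <- 3
  pat <- rep(sprintf("p%02d", 1:n_pat), each = cpp)
  y_pat <- rep(rep(c("benign", "malignant"), each = n_pat / 2), each = cpp)
  y <- factor(y_pat, levels = c("benign", "malignant"))
  X <- matrix(rnorm(n_pat * cpp * 6), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + 4 * (y == "malignant")
  cfg <- selection_config(method = "ttest", k_top = 2, cv_iterations = 5, seed = 11)
  rep1 <- cross_validate(X, y, pat, cfg, "lda")
  rep2 <- cross_validate(X, y, pat, cfg, "lda")
  expect_identical(rep1$metrics, rep2$metrics)
  expect_gte(mean(rep1$metrics$auc), 0.95)

  # a perfectly separating feature gives AUC 1 in every iteration
  Xp <- matrix(as.numeric(y == "malignant") + rnorm(length(y), 0, 0.01),
               ncol = 1, dimnames = list(NULL, "oracle"))
  cfg1 <- selection_config(method = "ttest", k_top = 1, cv_iterations = 3, seed = 1)
  repp <- cross_validate(Xp, y, pat, cfg1, "lda")
  expect_true(all(repp$metrics$auc == 1))

  # permuted labels: chance-level AUC
  set.seed(12)
  Xn <- matrix(rnorm(n_pat * cpp * 6), ncol = 6,
               dimnames = list(NULL, paste0("f", 1:6)))
  cfgn <- selection_config(method = "ttest", k_top = 2, cv_iterations = 10, seed = 13)
  repn <- cross_validate(Xn, y, pat, cfgn, "lda")
  expect_gt(mean(repn$metrics$auc), 0.3)
  expect_lt(mean(repn$metrics$auc), 0.7)
})
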