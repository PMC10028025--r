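# ---- base learners --------------------------------------------------------

# fit one base classifier on a feature matrix; feature columns are renamed
# internally so tree formulas never see non-syntactic names
fit_base <- function(X, y, learner, positive, ntree = 100) {
  cols <- colnames(X)
  keep <- apply(X, 2, function(v) length(unique(v)) > 1)
  if (!any(keep)) stop("all features constant in this training set")
  Xk <- X[, keep, drop = FALSE]
  if (learner %in% c("lda", "qda")) {
    fitfun <- if (learner == "lda") MASS::lda else MASS::qda
    fit <- fitfun(x = Xk, grouping = y)
    return(list(learner = learner, fit = fit, cols = cols, keep = keep,
                positive = positive))
  }
  # bagged_c45: bootstrap-aggregated entropy-split decision trees
  df <- data.frame(Xk)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    bs <- sample.int(nrow(df), replace = TRUE)
    trees[[t]] <- rpart::rpart(.y ~ ., data = df[bs, , drop = FALSE],
                               method = "class",
                               parms = list(split = "information"),
                               control = rpart::rpart.control(cp = 0.01, minsplit = 5,
                                                              xval = 0))
  }
  list(learner = learner, fit = trees, cols = cols, keep = keep,
       positive = positive)
}

predict_base <- function(model, X) {
  X <- X[, model$cols, drop = FALSE]
  Xk <- X[, model$keep, drop = FALSE]
  if (model$learner %in% c("lda", "qda")) {
    post <- predict(model$fit, Xk)$posterior
    return(as.numeric(post[, model$positive]))
  }
  df <- data.frame(Xk)
  names(df) <- paste0("f", seq_len(ncol(df)))
  probs <- vapply(model$fit, function(tr) {
    p <- predict(tr, newdata = df, type = "prob")
    as.numeric(p[, model$positive])
  }, numeric(nrow(df)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Fit the class-balanced multi-expert classifier
#'
#' Implements the two-expert balancing scheme for a minority class of size
#' `b` and a majority class of size `m`: the first expert is trained on all
#' `b` minority examples plus `b` majority examples sampled without
#' replacement; the second on the remaining `m - b` majority examples plus
#' `m - b` minority examples sampled from the `b` available (without
#' replacement when `m - b <= b`, otherwise with replacement). With
#' balanced classes a single expert is trained on all data. Prediction is
#' the mean of the experts' probabilities for the positive (malignant)
#' class.
#'
#' @param X numeric feature matrix with column names.
#' @param y two-level factor; the second level (or `"malignant"` when
#'   present) is treated as positive.
#' @param base_learner `"lda"`, `"qda"` or `"bagged_c45"`.
#' @param seed optional integer; when given, sampling is done under this
#'   seed and the caller's RNG stream is left untouched.
#' @param ntree trees per bagged ensemble.
#' @return object of class `multi_expert`, with the per-expert training
#'   index sets recorded for audit.
#' @export
fit_multi_expert <- function(X, y, base_learner = c("lda", "qda", "bagged_c45"),
                             seed = NULL, ntree = 100) {
  base_learner <- match.arg(base_learner)
  y <- as_binary_factor(y)
  stopifnot(nrow(X) == length(y))
  if (any(table(y) == 0)) stop("both classes must be present")
  positive <- if ("malignant" %in% levels(y)) "malignant" else levels(y)[2]

  build <- function() {
    tab <- table(y)
    minority <- names(tab)[which.min(tab)]
    majority <- setdiff(levels(y), minority)
    min_idx <- which(y == minority)
    maj_idx <- which(y == majority)
    b <- length(min_idx); m <- length(maj_idx)
    if (b == m) {
      experts_idx <- list(seq_along(y))
    } else {
      e1_maj <- sample(maj_idx, b)
      e2_maj <- setdiff(maj_idx, e1_maj)          # the (m - b) complement
      replace2 <- (m - b) > b
      e2_min <- sample(min_idx, m - b, replace = replace2)
      experts_idx <- list(c(min_idx, e1_maj), c(e2_min, e2_maj))
    }
    experts <- lapply(experts_idx, function(idx)
      fit_base(X[idx, , drop = FALSE], droplevels(y[idx]), base_learner,
               positive, ntree))
    structure(list(experts = experts, expert_index = experts_idx,
                   base_learner = base_learner, b = b, m = m,
                   positive = positive, levels = levels(y),
                   features = colnames(X)),
              class = "multi_expert")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Predict malignancy probabilities from a multi-expert model
#'
#' @param object a `multi_expert` model.
#' @param newdata numeric matrix containing at least the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of positive-class probabilities.
#' @export
predict.multi_expert <- function(object, newdata, ...) {
  probs <- vapply(object$experts, function(e) predict_base(e, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Aggregate cluster probabilities to patient level
#'
#' A patient's probability of malignancy is the mean (default), median or
#' maximum of the malignancy probabilities of their clusters.
#'
#' @param probabilities numeric vector of per-cluster probabilities.
#' @param patient_id character/factor vector aligned with `probabilities`.
#' @param rule `"mean"`, `"median"` or `"max"`.
#' @return data.frame `patient_id`, `n_clusters`, `p_mal`.
#' @export
predict_patients <- function(probabilities, patient_id,
                             rule = c("mean", "median", "max")) {
  rule <- match.arg(rule)
  stopifnot(length(probabilities) == length(patient_id))
  if (any(is.na(patient_id))) stop("patient ids must be non-missing")
  f <- switch(rule, mean = mean, median = stats::median, max = max)
  agg <- tapply(probabilities, as.character(patient_id), f)
  data.frame(patient_id = names(agg),
             n_clusters = as.integer(table(as.character(patient_id))[names(agg)]),
             p_mal = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Repeated patient-stratified cross-validation
#'
#' For each of `cfg$cv_iterations` repetitions: patients are split into
#' `cfg$cv_folds` label-stratified folds (no patient straddles folds);
#' within each training fold, feature selection is re-run and a
#' multi-expert classifier is fitted; held-out clusters are scored. The
#' pooled held-out probabilities of each repetition yield one AUC,
#' sensitivity and specificity (at `threshold`); the report carries the
#' per-iteration values and their mean and sd.
#'
#' @param X numeric feature matrix.
#' @param y two-level factor of cluster labels.
#' @param groups patient ids aligned with the rows of `X`.
#' @param cfg a [selection_config()] (selector, folds, iterations, seed).
#' @param base_learner `"lda"`, `"qda"` or `"bagged_c45"`.
#' @param threshold operating probability-of-malignancy threshold
#'   (default 0.3).
#' @param ntree trees per bagged ensemble.
#' @return object of class `cv_report`: `metrics` (one row per iteration),
#'   `summary` (mean and sd), `selection_counts`, `level = "cluster"`.
#' @export
cross_validate <- function(X, y, groups, cfg = selection_config(),
                           base_learner = c("lda", "qda", "bagged_c45"),
                           threshold = 0.3, ntree = 100) {
  base_learner <- match.arg(base_learner)
  y <- as_binary_factor(y)
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  metrics <- data.frame(iteration = seq_len(cfg$cv_iterations),
                        auc = NA_real_, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_)
  sel_counts <- setNames(numeric(ncol(X)), colnames(X))
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$cv_iterations)) {
      folds <- NULL
      for (try in 1:50) {
        cand <- make_folds(y, groups, cfg$cv_folds)
        ok <- all(vapply(seq_len(cfg$cv_folds), function(f)
          length(unique(y[cand == f])) == 2 &&
            length(unique(y[cand != f])) == 2, logical(1)))
        if (ok) { folds <- cand; break }
      }
      if (is.null(folds)) stop("could not build folds containing both classes")
      probs <- rep(NA_real_, length(y))
      for (f in seq_len(cfg$cv_folds)) {
        tr <- folds != f
        sel <- select_features(X[tr, , drop = FALSE], y[tr], cfg)
        sel_counts[sel] <- sel_counts[sel] + 1
        model <- fit_multi_expert(X[tr, sel, drop = FALSE], y[tr],
                                  base_learner, ntree = ntree)
        probs[!tr] <- predict(model, X[!tr, sel, drop = FALSE])
      }
      ev <- evaluate(probs, y, threshold = threshold)
      metrics$auc[it] <- ev$auc
      metrics$accuracy[it] <- ev$accuracy
      metrics$sensitivity[it] <- ev$sensitivity
      metrics$specificity[it] <- ev$specificity
    }
  })
  summary <- data.frame(
    metric = c("auc", "accuracy", "sensitivity", "specificity"),
    mean = c(mean(metrics$auc), mean(metrics$accuracy),
             mean(metrics$sensitivity), mean(metrics$specificity)),
    sd = c(sd(metrics$auc), sd(metrics$accuracy),
           sd(metrics$sensitivity), sd(metrics$specificity)))
  structure(list(metrics = metrics, summary = summary,
                 selection_counts = sort(sel_counts[sel_counts > 0],
                                         decreasing = TRUE),
                 level = "cluster", threshold = threshold,
                 base_learner = base_learner, config = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation (%d iterations, %s + %s)\n",
              x$config$cv_folds, x$config$cv_iterations, x$base_learner,
              x$config$method))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
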