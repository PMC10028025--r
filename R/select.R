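#' Feature selection configuration
#'
#' @param method `"wilcoxon"`, `"ttest"` or `"mrmr"`.
#' @param k_top number of features to select (default 5).
#' @param alpha univariate significance level (default 0.05).
#' @param mrmr_corr_threshold Pearson correlation above which a candidate is
#'   considered redundant with an already selected feature (default 0.7).
#' @param cv_folds,cv_iterations cross-validation geometry (3 folds, 100
#'   repeats by default).
#' @param seed integer seed driving every random split.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(method = c("wilcoxon", "ttest", "mrmr"),
                             k_top = 5, alpha = 0.05,
                             mrmr_corr_threshold = 0.7,
                             cv_folds = 3, cv_iterations = 100, seed = 1) {
  method <- match.arg(method)
  stopifnot(k_top >= 1, alpha > 0, alpha < 1,
            mrmr_corr_threshold > 0, mrmr_corr_threshold <= 1,
            cv_folds >= 2, cv_iterations >= 1)
  structure(list(method = method, k_top = as.integer(k_top), alpha = alpha,
                 mrmr_corr_threshold = mrmr_corr_threshold,
                 cv_folds = as.integer(cv_folds),
                 cv_iterations = as.integer(cv_iterations),
                 seed = as.integer(seed)),
            class = "selection_config")
}

as_binary_factor <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  droplevels(y)
}

#' Rank features by univariate class discriminability
#'
#' Two-sided Wilcoxon rank-sum (exact for small tie-free samples, normal
#' approximation otherwise) or Welch t-test per feature. Features are
#' returned in ascending p-value order; ties are broken by larger absolute
#' standardized mean difference, then by name. Constant features get p = 1
#' rather than an error.
#'
#' @param X numeric matrix (rows = clusters, named columns = features).
#' @param y two-level factor (or coercible).
#' @param method `"wilcoxon"` or `"ttest"`.
#' @return data.frame `feature`, `p_value`, `effect_size`, ordered by rank.
#' @export
rank_univariate <- function(X, y, method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  y <- as_binary_factor(y)
  stopifnot(nrow(X) == length(y))
  g1 <- y == levels(y)[1]
  p <- numeric(ncol(X)); eff <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    a <- X[g1, j]; b <- X[!g1, j]
    pooled <- sqrt((stats::var(a) * (length(a) - 1) +
                      stats::var(b) * (length(b) - 1)) /
                     (length(a) + length(b) - 2))
    eff[j] <- if (is.finite(pooled) && pooled > 0)
      abs(mean(a) - mean(b)) / pooled else 0
    if (length(unique(c(a, b))) < 2) {
      p[j] <- 1
      next
    }
    p[j] <- tryCatch(
      if (method == "wilcoxon")
        suppressWarnings(wilcox.test(a, b)$p.value)
      else
        t.test(a, b)$p.value,
      error = function(e) 1)
    if (!is.finite(p[j])) p[j] <- 1
  }
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
  ord <- order(p, -eff, nm)
  data.frame(feature = nm[ord], p_value = p[ord], effect_size = eff[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

# top-k univariate features, preferring those significant at cfg$alpha;
# falls back to the best-ranked features when fewer than k are significant.
select_univariate <- function(X, y, cfg) {
  rk <- rank_univariate(X, y, cfg$method)
  sig <- rk$feature[rk$p_value <= cfg$alpha]
  if (length(sig) >= cfg$k_top) head(sig, cfg$k_top) else head(rk$feature, cfg$k_top)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection: relevance is the absolute (point-biserial)
#' Pearson correlation of a feature with the binary label; at each step
#' candidates whose absolute Pearson correlation with any already selected
#' feature exceeds `cfg$mrmr_corr_threshold` are pruned, and among the
#' survivors the feature maximizing relevance minus mean absolute
#' correlation with the selected set is added. Returns fewer than `k_top`
#' features (with a warning) if the redundancy pruning exhausts the
#' candidates.
#'
#' @param X numeric feature matrix with column names.
#' @param y two-level factor.
#' @param cfg a [selection_config()].
#' @return data.frame `feature`, `relevance`, `score` in selection order.
#' @export
select_mrmr <- function(X, y, cfg = selection_config(method = "mrmr")) {
  y <- as_binary_factor(y)
  stopifnot(cfg$k_top <= ncol(X))
  yn <- as.numeric(y == levels(y)[2])
  nm <- colnames(X)
  if (is.null(nm)) nm <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  rel <- rep(0, ncol(X))
  ok <- sds > 0
  rel[ok] <- abs(suppressWarnings(cor(X[, ok, drop = FALSE], yn)))
  rel[!is.finite(rel)] <- 0

  selected <- integer(0); scores <- numeric(0)
  candidates <- seq_len(ncol(X))
  while (length(selected) < cfg$k_top && length(candidates) > 0) {
    if (length(selected) == 0) {
      sc <- rel[candidates]
    } else {
      red <- abs(suppressWarnings(
        cor(X[, candidates, drop = FALSE], X[, selected, drop = FALSE])))
      red[!is.finite(red)] <- 1  # constant features are maximally redundant
      keep <- apply(red, 1, max) <= cfg$mrmr_corr_threshold
      candidates <- candidates[keep]
      red <- red[keep, , drop = FALSE]
      if (length(candidates) == 0) break
      sc <- rel[candidates] - rowMeans(red)
    }
    best <- which.max(sc)
    selected <- c(selected, candidates[best])
    scores <- c(scores, sc[best])
    candidates <- candidates[-best]
  }
  if (length(selected) < cfg$k_top)
    warning("only ", length(selected), " features survive the redundancy threshold")
  data.frame(feature = nm[selected], relevance = rel[selected], score = scores,
             row.names = NULL, stringsAsFactors = FALSE)
}

# dispatch on cfg$method; returns a character vector of feature names
select_features <- function(X, y, cfg) {
  if (cfg$method == "mrmr") select_mrmr(X, y, cfg)$feature
  else select_univariate(X, y, cfg)
}

#' Stability selection across repeated cross-validation folds
#'
#' Runs the configured selector on the training portion of every fold of
#' `cv_iterations` independent `cv_folds`-fold splits and tallies how often
#' each feature is chosen. Returns the `k_top` most frequently selected
#' features and the full frequency table. Deterministic given `cfg$seed`.
#'
#' @param X numeric feature matrix.
#' @param y two-level factor.
#' @param cfg a [selection_config()].
#' @param groups optional patient ids; when given, folds split patients.
#' @return list with `features` (top `k_top` names) and `frequency` (named
#'   vector of selection frequencies in \[0, 1\]).
#' @export
select_stable <- function(X, y, cfg = selection_config(), groups = NULL) {
  y <- as_binary_factor(y)
  counts <- setNames(numeric(ncol(X)), colnames(X))
  n_runs <- 0L
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$cv_iterations)) {
      folds <- make_folds(y, groups, cfg$cv_folds)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) next
        sel <- select_features(X[tr, , drop = FALSE], y[tr], cfg)
        counts[sel] <- counts[sel] + 1
        n_runs <- n_runs + 1L
      }
    }
  })
  freq <- counts / max(n_runs, 1L)
  top <- names(sort(freq, decreasing = TRUE))[seq_len(cfg$k_top)]
  list(features = top, frequency = freq)
}

# stratified fold assignment; with groups, whole patients are assigned to
# folds (stratified by patient label). Returns an integer fold id per row.
make_folds <- function(y, groups, k) {
  n <- length(y)
  if (is.null(groups)) {
    fold <- integer(n)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    return(fold)
  }
  stopifnot(length(groups) == n)
  gl <- tapply(as.character(y), groups, function(v) v[1])
  gids <- names(gl)
  gfold <- setNames(integer(length(gids)), gids)
  for (lev in unique(gl)) {
    idx <- which(gl == lev)
    gfold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  unname(gfold[as.character(groups)])
}
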