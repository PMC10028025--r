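#' Evaluate malignancy probabilities against reference labels
#'
#' Builds the ROC curve by sweeping the threshold over the sorted unique
#' probabilities (plus endpoints), treating `p >= threshold` as a positive
#' (malignant) call, computes the trapezoidal AUC, and reports the
#' confusion matrix, sensitivity, specificity and accuracy at the stated
#' operating threshold (default probability of malignancy 0.3).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param labels two-level factor (or coercible); the `"malignant"` level
#'   (or the second level) is positive. A single-class vector is an error
#'   (AUC undefined).
#' @param threshold operating threshold on the probability of malignancy.
#' @param level `"cluster"` or `"patient"` (annotation only).
#' @return object of class `evaluation_report`: `roc` (threshold,
#'   sensitivity, specificity), `auc`, `confusion` (2x2), `sensitivity`,
#'   `specificity`, `accuracy`, `operating_threshold`, `level`.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.3,
                     level = c("cluster", "patient")) {
  level <- match.arg(level)
  y <- as_binary_factor(labels)
  stopifnot(length(probabilities) == length(y),
            all(probabilities >= 0 & probabilities <= 1))
  positive <- if ("malignant" %in% levels(y)) "malignant" else levels(y)[2]
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("AUC undefined: labels contain a single class")

  thr <- c(-Inf, sort(unique(probabilities)), Inf)
  sens <- vapply(thr, function(t) mean(probabilities[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(probabilities[!pos] < t), numeric(1))
  # trapezoid over (FPR, TPR), sorted by increasing FPR
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + sens[ord][-1]) / 2)

  call_pos <- probabilities >= threshold
  tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
  tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(predicted = c("negative", "positive"),
                                      truth = c("benign", "malignant")))
  structure(list(roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec),
                 auc = auc,
                 confusion = confusion,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 operating_threshold = threshold,
                 level = level),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s level, threshold P_mal = %.2f)\n", x$level,
              x$operating_threshold))
  cat(sprintf("  AUC         %.3f\n", x$auc))
  cat(sprintf("  sensitivity %.3f\n  specificity %.3f\n  accuracy    %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Published validation-cohort diagnostic counts
#'
#' A 66-patient bile-duct-brushing validation cohort cross-tabulated by
#' cytological diagnosis (benign / atypical / malignant), machine call at
#' an operating probability-of-malignancy threshold of 0.3
#' (negative / positive), and the clinicopathological follow-up reference
#' (benign / malignant). Shipped as a plain-text table and used as the
#' worked example for the diagnostic arithmetic in
#' [diagnostic_summary()].
#'
#' @return data.frame with columns `cytology`, `machine`, `clinical`, `n`.
#' @export
validation_cohort_counts <- function() {
  path <- system.file("extdata", "validation_cohort_counts.csv",
                      package = "brushmorph", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Diagnostic arithmetic on a cytology/machine/follow-up cross-table
#'
#' Computes, from patient counts cross-tabulated as in
#' [validation_cohort_counts()]:
#' machine sensitivity and specificity against the clinical follow-up;
#' cytology-alone sensitivity both excluding atypical cases and including
#' them with atypical treated as a non-malignant (negative) call; and the
#' machine specificity within the atypical category.
#'
#' @param counts data.frame with columns `cytology` (benign, atypical,
#'   malignant), `machine` (negative, positive), `clinical` (benign,
#'   malignant), `n`.
#' @return named list of proportions.
#' @export
diagnostic_summary <- function(counts) {
  stopifnot(all(c("cytology", "machine", "clinical", "n") %in% names(counts)))
  s <- function(cond) sum(counts$n[cond])
  mal <- counts$clinical == "malignant"
  ben <- counts$clinical == "benign"
  atyp <- counts$cytology == "atypical"
  cyto_pos <- counts$cytology == "malignant"
  mach_pos <- counts$machine == "positive"

  list(
    n_patients = sum(counts$n),
    machine_sensitivity = s(mach_pos & mal) / s(mal),
    machine_specificity = s(!mach_pos & ben) / s(ben),
    cytology_sensitivity_excl_atypical = s(cyto_pos & mal & !atyp) / s(mal & !atyp),
    cytology_sensitivity_incl_atypical = s(cyto_pos & mal) / s(mal),
    atypical_machine_specificity = if (s(ben & atyp) > 0)
      s(!mach_pos & ben & atyp) / s(ben & atyp) else NA_real_
  )
}
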