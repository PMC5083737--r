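#' Pool nucleus features into a tissue-level vector
#'
#' Component-wise arithmetic mean over the nuclei of one tissue.
#'
#' @param nuclei Numeric matrix or data frame of per-nucleus feature
#'   vectors (rows = nuclei), at least one row; non-feature columns
#'   (`tissue_id`, `nucleus_id`, `class`) are ignored if present.
#' @return Named numeric vector of pooled features.
#' @export
#' @examples
#' pool_tissue(rbind(c(a = 1, b = 2), c(a = 3, b = 4)))
pool_tissue <- function(nuclei) {
  if (is.data.frame(nuclei))
    nuclei <- nuclei[, !(names(nuclei) %in%
                           c("tissue_id", "nucleus_id", "class")),
                     drop = FALSE]
  nuclei <- as.matrix(nuclei)
  if (nrow(nuclei) < 1) stop("cannot pool an empty tissue sample")
  colMeans(nuclei)
}

#' Pool a nucleus-level table into a tissue-level table
#'
#' Applies [pool_tissue()] per `tissue_id`, carrying the class label
#' through.
#'
#' @param nuclei Data frame with `tissue_id`, optional `class`, and
#'   feature columns (e.g. `gen_nucleus_cohort()$nuclei`).
#' @return Tissue-level data frame: `tissue_id`, `class` (if present),
#'   pooled feature columns.
#' @export
pool_cohort <- function(nuclei) {
  stopifnot("tissue_id" %in% names(nuclei))
  ids <- unique(nuclei$tissue_id)
  featcols <- setdiff(names(nuclei), c("tissue_id", "nucleus_id", "class"))
  pooled <- t(vapply(ids, function(id)
    pool_tissue(nuclei[nuclei$tissue_id == id, featcols, drop = FALSE]),
    numeric(length(featcols))))
  out <- data.frame(tissue_id = ids, stringsAsFactors = FALSE)
  if ("class" %in% names(nuclei))
    out$class <- as_karyo_class(
      nuclei$class[match(ids, nuclei$tissue_id)])
  cbind(out, as.data.frame(pooled))
}

#' Classify from class probabilities
#'
#' The predicted class is the one with the highest probability; exact
#' ties are broken toward the earlier class in the fixed order
#' CP < IPMN < PC.
#'
#' @param p Probability vector (one sample, named or in class order) or
#'   matrix (samples x classes).
#' @return Character vector of predicted classes.
#' @export
#' @examples
#' classify_probs(c(CP = 0.4, IPMN = 0.4, PC = 0.2))  # tie -> CP
classify_probs <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, names(p)))
  cls <- colnames(p)
  if (is.null(cls)) cls <- karyo_classes()[seq_len(ncol(p))]
  cls[max.col(p, ties.method = "first")]
}

#' Classification certainty
#'
#' Largest minus smallest of a lesion's class probabilities: 0 at the
#' uniform distribution (assignment by chance), 1 at a degenerate
#' distribution (perfect assignment).
#'
#' @param p Probability vector (one sample) or matrix (samples x
#'   classes), each row summing to 1.
#' @return Numeric vector of certainties in \[0, 1\].
#' @export
#' @examples
#' certainty(c(0.6, 0.3, 0.1))  # 0.5
certainty <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  apply(p, 1, max) - apply(p, 1, min)
}

#' Whole-data tissue-level analysis
#'
#' The first stage of the two-level analysis: pools nuclei per tissue
#' when given a nucleus-level cohort, tunes the penalized multinomial
#' model by cross-validation on all tissues, and reports per-lesion
#' class probabilities, maximum-probability calls, certainties, the
#' training accuracy, and the selected features.
#'
#' @param cohort Tissue-level data frame (`tissue_id`, `class`, feature
#'   columns) or a `nucleus_cohort`, which is pooled first.
#' @param penalty,criterion,folds Passed to [cv_select_lambda()].
#' @param seed Seed for the cross-validation folds.
#' @param uncertain_below Reporting threshold: calls with certainty
#'   strictly below it are counted as uncertain (default 0.55).
#' @return Object of class `tissue_analysis`: list with `calls` (data
#'   frame `tissue_id`, `true_class`, `predicted_class`, `p_CP`,
#'   `p_IPMN`, `p_PC`, `certainty`, `correct`, `uncertain`), `model`
#'   (the `karyo_cv` fit), `training_accuracy`, `n_selected`,
#'   `selected_features`, `mean_certainty_correct`,
#'   `mean_certainty_incorrect`, `uncertain_below`.
#' @export
run_tissue_level <- function(cohort, penalty = "lasso",
                             criterion = "deviance", folds = 5,
                             seed = 1L, uncertain_below = 0.55) {
  if (inherits(cohort, "nucleus_cohort")) cohort <- pool_cohort(cohort$nuclei)
  stopifnot(all(c("tissue_id", "class") %in% names(cohort)))
  featcols <- setdiff(names(cohort), c("tissue_id", "class", "n_nuclei"))
  X <- as.matrix(cohort[, featcols])
  y <- as_karyo_class(cohort$class)
  if (nlevels(droplevels(y)) < 2) stop("cohort must contain >= 2 classes")

  cv <- cv_select_lambda(X, y, penalty = penalty, criterion = criterion,
                         folds = folds, seed = seed)
  P <- predict_proba(cv, X)
  pred <- classify_probs(P)
  cert <- certainty(P)
  correct <- pred == as.character(y)
  calls <- data.frame(tissue_id = cohort$tissue_id,
                      true_class = as.character(y),
                      predicted_class = pred,
                      p_CP = P[, "CP"], p_IPMN = P[, "IPMN"],
                      p_PC = P[, "PC"], certainty = cert,
                      correct = correct,
                      uncertain = cert < uncertain_below,
                      stringsAsFactors = FALSE)
  structure(list(
    calls = calls, model = cv,
    training_accuracy = mean(correct),
    n_selected = length(selected_features(cv)),
    selected_features = selected_features(cv),
    mean_certainty_correct = if (any(correct)) mean(cert[correct]) else NA_real_,
    mean_certainty_incorrect = if (any(!correct)) mean(cert[!correct]) else NA_real_,
    uncertain_below = uncertain_below),
    class = "tissue_analysis")
}

#' @export
print.tissue_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "tissue_analysis: %d lesions, training accuracy %.1f%%, ",
    "%d selected features\n"),
    nrow(x$calls), 100 * x$training_accuracy, x$n_selected))
  cat(sprintf("mean certainty: %.2f (correct) vs %s (incorrect)\n",
              x$mean_certainty_correct,
              ifelse(is.na(x$mean_certainty_incorrect), "NA",
                     sprintf("%.2f", x$mean_certainty_incorrect))))
  invisible(x)
}

#' Nuclear-level analysis with imputed labels
#'
#' Second stage of the two-level analysis. Because nuclei carry no
#' direct diagnosis, each nucleus is first labeled by the tissue-level
#' model applied to its raw features; a penalized multinomial model is
#' then tuned on the raw per-nucleus features against those imputed
#' labels. Reports agreement with the imputed labels and, per tissue,
#' the majority-vote nuclear prediction against the tissue truth.
#'
#' @param nuclei Nucleus-level data frame (`tissue_id`, `nucleus_id`,
#'   optional true tissue `class`, feature columns) or a
#'   `nucleus_cohort`.
#' @param tissue_model A `tissue_analysis`, `karyo_cv`, or
#'   `karyo_model` used for the imputation.
#' @inheritParams run_tissue_level
#' @return Object of class `nuclear_analysis`: list with `model`, the
#'   per-nucleus `imputed` labels, `accuracy_vs_imputed`,
#'   `majority_calls` (per-tissue majority vote with truth when known),
#'   `accuracy_majority_vs_truth`, `n_selected`, `selected_features`.
#' @export
impute_and_run_nuclear_level <- function(nuclei, tissue_model,
                                         penalty = "lasso",
                                         criterion = "deviance",
                                         folds = 5, seed = 1L) {
  if (inherits(nuclei, "nucleus_cohort")) nuclei <- nuclei$nuclei
  featcols <- setdiff(names(nuclei), c("tissue_id", "nucleus_id", "class"))
  X <- as.matrix(nuclei[, featcols])
  imputed <- impute_nucleus_labels(nuclei, tissue_model)
  if (length(unique(imputed)) < 2)
    stop("imputed labels are degenerate (single class); cannot refit")

  cv <- cv_select_lambda(X, imputed, penalty = penalty,
                         criterion = criterion, folds = folds, seed = seed)
  pred <- classify_probs(predict_proba(cv, X))

  ids <- unique(nuclei$tissue_id)
  maj <- vapply(ids, function(id) {
    tab <- table(factor(pred[nuclei$tissue_id == id],
                        levels = karyo_classes()))
    karyo_classes()[which.max(tab)]
  }, character(1))
  majority_calls <- data.frame(tissue_id = ids, predicted_class = maj,
                               stringsAsFactors = FALSE)
  acc_truth <- NA_real_
  if ("class" %in% names(nuclei)) {
    truth <- as.character(nuclei$class[match(ids, nuclei$tissue_id)])
    majority_calls$true_class <- truth
    acc_truth <- mean(maj == truth)
  }
  structure(list(model = cv, imputed = imputed,
                 accuracy_vs_imputed = mean(pred == imputed),
                 majority_calls = majority_calls,
                 accuracy_majority_vs_truth = acc_truth,
                 n_selected = length(selected_features(cv)),
                 selected_features = selected_features(cv)),
            class = "nuclear_analysis")
}

#' Impute nucleus labels from a tissue-level model
#'
#' Labels every nucleus with the maximum-probability class of the
#' tissue-level model applied to its raw feature vector (argmax ties
#' broken toward the fixed class order).
#'
#' @param nuclei Nucleus-level data frame or `nucleus_cohort`.
#' @param tissue_model A `tissue_analysis`, `karyo_cv`, `karyo_path`,
#'   or `karyo_model`.
#' @return Character vector of imputed class labels, one per nucleus.
#' @export
impute_nucleus_labels <- function(nuclei, tissue_model) {
  if (inherits(nuclei, "nucleus_cohort")) nuclei <- nuclei$nuclei
  if (inherits(tissue_model, "tissue_analysis"))
    tissue_model <- tissue_model$model
  featcols <- setdiff(names(nuclei), c("tissue_id", "nucleus_id", "class"))
  X <- as.matrix(nuclei[, featcols])
  classify_probs(predict_proba(tissue_model, X))
}

#' Repeated stratified train/test split evaluation
#'
#' Estimates generalization accuracy by repeated random 3:1 splits of
#' the tissues: per split, the penalized model (with internal
#' cross-validation on the training part) is fit on the training
#' tissues and scored on the held-out quarter. Splits are stratified by
#' class so that every class is represented in each training set.
#'
#' @param cohort Tissue-level data frame or `nucleus_cohort` (pooled
#'   first).
#' @param penalty,criterion,folds Passed to the per-split
#'   [cv_select_lambda()].
#' @param n_splits Number of random splits (default 20).
#' @param ratio Training fraction (default 0.75, a 3:1 split).
#' @param seed Base seed; split r uses `seed + r`.
#' @return Object of class `split_evaluation`: list with `accuracies`,
#'   `mean_accuracy`, `feature_counts`, `mean_feature_count`,
#'   `n_splits`, `ratio`, `seed`.
#' @export
evaluate_splits <- function(cohort, penalty = "lasso",
                            criterion = "deviance", folds = 5,
                            n_splits = 20, ratio = 0.75, seed = 1L) {
  if (inherits(cohort, "nucleus_cohort")) cohort <- pool_cohort(cohort$nuclei)
  featcols <- setdiff(names(cohort), c("tissue_id", "class", "n_nuclei"))
  X <- as.matrix(cohort[, featcols])
  y <- as_karyo_class(cohort$class)
  if (any(table(droplevels(y)) < 2))
    stop("need at least 2 tissues in every represented class")

  acc <- nfeat <- numeric(n_splits)
  for (r in seq_len(n_splits)) {
    tr <- stratified_split(y, ratio, seed + r)
    cv <- suppressWarnings(
      cv_select_lambda(X[tr, , drop = FALSE], y[tr], penalty = penalty,
                       criterion = criterion, folds = folds,
                       seed = seed + r))
    P <- predict_proba(cv, X[!tr, , drop = FALSE])
    acc[r] <- mean(classify_probs(P) == as.character(y[!tr]))
    nfeat[r] <- length(selected_features(cv))
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 feature_counts = nfeat, mean_feature_count = mean(nfeat),
                 n_splits = n_splits, ratio = ratio,
                 seed = as.integer(seed)),
            class = "split_evaluation")
}

# stratified train indicator: `ratio` of each class goes to training
stratified_split <- function(y, ratio, seed) {
  withr::with_seed(seed, {
    tr <- logical(length(y))
    for (cl in levels(droplevels(y))) {
      i <- which(y == cl)
      k <- max(1L, round(ratio * length(i)))
      tr[sample(i, k)] <- TRUE
    }
    tr
  })
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "split_evaluation: %d splits at %.0f:%.0f, mean test accuracy %.1f%%, ",
    "%.2f features on average\n"),
    x$n_splits, 100 * x$ratio, 100 * (1 - x$ratio),
    100 * x$mean_accuracy, x$mean_feature_count))
  invisible(x)
}

#' One-vs-rest ROC analysis of lesion calls
#'
#' For each class, the class's predicted probability is used as the
#' score of a one-vs-rest ROC curve against the true labels; the
#' macro-average of the three AUCs (trapezoidal, equivalent to the
#' concordance probability) summarizes multiclass discrimination.
#'
#' @param calls Data frame with `true_class` and probability columns
#'   `p_CP`, `p_IPMN`, `p_PC` (as produced by [run_tissue_level()]), or
#'   a `tissue_analysis`.
#' @return Object of class `roc_analysis`: list with `auc_per_class`,
#'   `macro_auc`, and `curves` (per-class data frames of
#'   specificity/sensitivity points).
#' @export
roc_analysis <- function(calls) {
  if (inherits(calls, "tissue_analysis")) calls <- calls$calls
  stopifnot(all(c("true_class", "p_CP", "p_IPMN", "p_PC") %in% names(calls)))
  truth <- as.character(calls$true_class)
  present <- intersect(karyo_classes(), unique(truth))
  if (length(present) < 2) stop("ROC needs at least 2 classes in the truth")
  aucs <- numeric(0)
  curves <- list()
  for (cl in present) {
    sc <- calls[[paste0("p_", cl)]]
    r <- pROC::roc(response = factor(truth == cl, levels = c(FALSE, TRUE)),
                   predictor = sc, direction = "<", quiet = TRUE)
    aucs[cl] <- as.numeric(pROC::auc(r))
    curves[[cl]] <- data.frame(specificity = r$specificities,
                               sensitivity = r$sensitivities)
  }
  structure(list(auc_per_class = aucs, macro_auc = mean(aucs),
                 curves = curves),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("roc_analysis: macro one-vs-rest AUC %.3f (%s)\n",
              x$macro_auc,
              paste(sprintf("%s %.3f", names(x$auc_per_class),
                            x$auc_per_class), collapse = ", ")))
  invisible(x)
}
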