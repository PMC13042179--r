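# Phenotype distillation: gradient-boosted multi-class classifier with
# SHAP-style additive explanations.

#' Classifier configuration
#'
#' @param test_fraction held-out fraction of the stratified randomized split.
#' @param seed split / training seed.
#' @param nrounds boosting rounds (library-default scale).
#' @param params extra booster parameters (library defaults otherwise).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(test_fraction = 0.2, seed = 1L, nrounds = 100L,
                              params = list()) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  structure(list(test_fraction = test_fraction, seed = seed,
                 nrounds = nrounds, params = params),
            class = "classifier_config")
}

# Stratified split indices: for each class, a seeded sample of test rows.
stratified_split <- function(labels, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      n_test <- max(1L, round(test_fraction * length(rows)))
      test <- c(test, sample(rows, n_test))
    }
    sort(test)
  })
}

one_vs_rest_aucs <- function(truth, prob) {
  classes <- colnames(prob)
  roc_auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  pr_auc <- roc_auc
  for (cl in classes) {
    y <- as.integer(truth == cl)
    if (length(unique(y)) < 2L) next
    roc_auc[cl] <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE, direction = "<"))))
    # precision-recall AUC by step interpolation over descending scores
    ord <- order(-prob[, cl])
    tp <- cumsum(y[ord])
    prec <- tp / seq_along(tp)
    rec <- tp / sum(y)
    pr_auc[cl] <- sum(diff(c(0, rec)) * prec)
  }
  list(roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Train the phenotype classifier
#'
#' Multi-class gradient-boosted trees (softprob objective, library-default
#' hyperparameters) on a stratified randomized train/test split, with a full
#' held-out evaluation report.
#'
#' @param features numeric data frame / matrix.
#' @param labels phenotype labels (>= 2 classes, each with >= 5 members).
#' @param config a [classifier_config()].
#' @return object of class `phenotype_classifier`: booster, class levels,
#'   feature names, split indices, and `eval` (accuracy, per-class
#'   precision/recall/F1, confusion matrix, one-vs-rest ROC/PR AUCs).
#' @export
train_phenotype_classifier <- function(features, labels,
                                       config = classifier_config()) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(labels))
  lab_f <- factor(labels)
  if (nlevels(lab_f) < 2L) stop("need at least 2 classes")
  if (any(table(lab_f) < 5L)) stop("every class needs at least 5 members")
  y <- as.integer(lab_f) - 1L
  test_idx <- stratified_split(lab_f, config$test_fraction, config$seed)
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)
  if (length(unique(y[train_idx])) < nlevels(lab_f)) {
    stop("a class is absent from the training split")
  }
  params <- utils::modifyList(list(
    objective = "multi:softprob", num_class = nlevels(lab_f),
    max_depth = 6, eta = 0.3, nthread = 1, seed = config$seed
  ), config$params)
  dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                 label = y[train_idx])
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nrounds, verbose = 0)
  prob <- predict(booster, xgboost::xgb.DMatrix(X[test_idx, , drop = FALSE]))
  prob <- matrix(prob, ncol = nlevels(lab_f))
  colnames(prob) <- levels(lab_f)
  pred <- levels(lab_f)[max.col(prob, ties.method = "first")]
  truth <- as.character(lab_f[test_idx])
  cm <- table(truth = factor(truth, levels(lab_f)),
              predicted = factor(pred, levels(lab_f)))
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  aucs <- one_vs_rest_aucs(truth, prob)
  structure(list(
    booster = booster, levels = levels(lab_f),
    feature_names = colnames(X), test_idx = test_idx, train_idx = train_idx,
    config = config,
    eval = list(accuracy = mean(pred == truth), precision = prec,
                recall = rec, f1 = f1, confusion = cm,
                roc_auc = aucs$roc_auc, pr_auc = aucs$pr_auc)
  ), class = "phenotype_classifier")
}

#' Predict phenotype for new feature rows
#'
#' @param object a `phenotype_classifier`.
#' @param newdata data frame / matrix containing the training features.
#' @param ... unused.
#' @return list with `label` and `prob` (rows summing to 1).
#' @export
predict.phenotype_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata, check.names = FALSE))
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing)) {
    stop("missing features: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  X <- X[, object$feature_names, drop = FALSE]
  if (anyNA(X)) stop("missing values in prediction rows")
  prob <- predict(object$booster, xgboost::xgb.DMatrix(X))
  prob <- matrix(prob, ncol = length(object$levels))
  colnames(prob) <- object$levels
  list(label = object$levels[max.col(prob, ties.method = "first")], prob = prob)
}

#' SHAP-style explanation of the classifier
#'
#' Per-sample, per-class additive feature attributions from the tree
#' ensemble (TreeSHAP path-dependent values; base value + attributions equal
#' the class margin). For each class, features are ranked by mean absolute
#' attribution; the direction of effect is the sign of the Pearson
#' correlation between feature value and attribution.
#'
#' @param model a `phenotype_classifier`.
#' @param features rows to explain (defaults semantics: pass the training
#'   table).
#' @param top_n features reported per class (20).
#' @return object of class `explanation_report`: per class a data frame
#'   (`feature`, `mean_abs_shap`, `direction`), plus `base_values` and the
#'   raw attribution arrays.
#' @export
explain_phenotypes <- function(model, features, top_n = 20L) {
  if (!inherits(model, "phenotype_classifier")) stop("needs a tree-ensemble phenotype_classifier")
  X <- as.matrix(as.data.frame(features, check.names = FALSE))[, model$feature_names,
                                                               drop = FALSE]
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  # multi-class contributions arrive as an n x K x (F+1) array, a list of
  # matrices, or one wide matrix depending on the library version; normalize
  # to a list of n x (F+1) matrices
  K <- length(model$levels)
  Fp <- ncol(X) + 1L
  if (is.array(contrib) && length(dim(contrib)) == 3L) {
    contrib <- lapply(seq_len(K), function(k) contrib[, k, , drop = TRUE])
  } else if (!is.list(contrib)) {
    contrib <- lapply(seq_len(K), function(k) {
      contrib[, ((k - 1L) * Fp + 1L):(k * Fp), drop = FALSE]
    })
  }
  names(contrib) <- model$levels
  per_class <- lapply(model$levels, function(cl) {
    M <- contrib[[cl]]
    bias <- M[, ncol(M)]
    shap <- M[, -ncol(M), drop = FALSE]
    colnames(shap) <- model$feature_names
    imp <- colMeans(abs(shap))
    ord <- order(-imp)[seq_len(min(top_n, length(imp)))]
    direction <- vapply(ord, function(j) {
      if (stats::sd(X[, j]) == 0 || stats::sd(shap[, j]) == 0) return(0)
      sign(stats::cor(X[, j], shap[, j]))
    }, 0)
    list(table = data.frame(feature = model$feature_names[ord],
                            mean_abs_shap = imp[ord],
                            direction = direction),
         base_value = mean(bias), shap = shap)
  })
  names(per_class) <- model$levels
  structure(list(classes = per_class), class = "explanation_report")
}

#' Export the interpretation context block
#'
#' Emits, per phenotype, the top discriminative features with importance and
#' direction, outcome summaries, and prevalence -- the context a downstream
#' narrative-interpretation agent would consume. No model call is made.
#'
#' @param explanation an `explanation_report`.
#' @param outcome_summary optional data frame of per-phenotype outcome rates.
#' @param prevalence optional named prevalence vector.
#' @param top_n features per phenotype.
#' @return character scalar (JSON).
#' @export
export_interpretation_context <- function(explanation, outcome_summary = NULL,
                                          prevalence = NULL, top_n = 10L) {
  ctx <- lapply(names(explanation$classes), function(cl) {
    tab <- utils::head(explanation$classes[[cl]]$table, top_n)
    list(phenotype = cl,
         top_features = tab,
         prevalence = if (!is.null(prevalence)) unname(prevalence[cl]) else NULL,
         outcomes = if (!is.null(outcome_summary))
           outcome_summary[outcome_summary$phenotype == cl, , drop = FALSE] else NULL)
  })
  jsonlite::toJSON(ctx, dataframe = "rows", auto_unbox = TRUE, digits = 6,
                   null = "null")
}
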