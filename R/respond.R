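#' Ridge-regularized logistic classifier
#'
#' The package's default deterministic classifier behind the pluggable
#' `fit(x, y)` / `predict(model, x)` interface. Any object with those two
#' elements (predict returning positive-class probabilities) can be passed
#' to [run_evaluation()] in its place.
#'
#' @param lambda Ridge penalty (default 0.01).
#' @return A `classifier` list with `fit` and `predict` functions.
#' @export
classifier_logistic <- function(lambda = 0.01) {
  structure(list(
    name = "ridge_logistic",
    fit = function(x, y) {
      # y: factor with positive class as the second level
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                     standardize = TRUE)
    },
    predict = function(model, x) {
      as.numeric(stats::predict(model, newx = x, type = "response"))
    }), class = "classifier")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores for a binary label.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Labels.
#' @param positive The positive-class label.
#' @return AUC in [0, 1]; NA if a class is absent.
#' @export
auc_score <- function(scores, labels, positive = "Responder") {
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a fixed specificity
#'
#' Over all decision thresholds (predict positive when score >= t), the
#' maximum sensitivity among thresholds whose specificity is at least
#' `spec`; 0 when only the degenerate all-negative threshold qualifies.
#'
#' @param scores Numeric scores.
#' @param labels Labels; both classes must be present.
#' @param positive Positive-class label.
#' @param spec Required specificity (default 0.95).
#' @return Sensitivity in [0, 1].
#' @export
sensitivity_at_specificity <- function(scores, labels,
                                       positive = "Responder", spec = 0.95) {
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes required")
  thr <- c(sort(unique(scores)), Inf)
  best <- 0
  for (t in thr) {
    pred <- scores >= t
    sp <- sum(!pred & !y) / sum(!y)
    se <- sum(pred & y) / sum(y)
    if (sp >= spec && se > best) best <- se
  }
  best
}

#' Patient-level prediction from the most recent timepoint
#'
#' Each patient's probability is that of their latest available scored
#' sample in `timepoint_order` (samples with unknown timepoint sort first,
#' i.e. least recent); the predicted label is positive when the probability
#' is >= 0.5. Patients with no scored sample are excluded and counted.
#'
#' @param predictions data.frame with sample_id, patient_id, timepoint,
#'   probability (and optionally the true label column `response`).
#' @param timepoint_order Least to most recent.
#' @param positive,negative Labels emitted for the binary decision.
#' @return data.table (patient_id, timepoint used, probability, predicted),
#'   with `n_excluded` attribute.
#' @export
patient_prediction <- function(predictions,
                               timepoint_order = c("Screen", "Day0",
                                                   "AdjWk1"),
                               positive = "Responder",
                               negative = "Non-Responder") {
  dt <- data.table::as.data.table(predictions)
  dt <- dt[!is.na(probability)]
  n_excluded <- length(setdiff(unique(predictions$patient_id),
                               unique(dt$patient_id)))
  dt[, tp_rank := match(timepoint, timepoint_order)]
  dt[is.na(tp_rank), tp_rank := 0L]
  data.table::setorder(dt, patient_id, tp_rank)
  out <- dt[, .SD[.N], by = patient_id]
  out[, predicted := ifelse(probability >= 0.5, positive, negative)]
  keep <- intersect(c("patient_id", "timepoint", "probability", "predicted",
                      "response"), names(out))
  out <- out[, keep, with = FALSE]
  data.table::setattr(out, "n_excluded", n_excluded)
  out[]
}

#' Evaluation scheme definition
#'
#' @param kind `"repeated_kfold"`, `"leave_one_institute_out"`, or
#'   `"random_patient_holdout"`. All splits are at the patient level.
#' @param folds Folds per round (repeated_kfold).
#' @param rounds Number of rounds (repeated_kfold, random_patient_holdout).
#' @param holdout_size Test patients per round (random_patient_holdout).
#' @return An `eval_scheme` list.
#' @export
eval_scheme <- function(kind = c("repeated_kfold", "leave_one_institute_out",
                                 "random_patient_holdout"),
                        folds = 10L, rounds = 10L, holdout_size = 10L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, folds = as.integer(folds),
                 rounds = as.integer(rounds),
                 holdout_size = as.integer(holdout_size)),
            class = "eval_scheme")
}

# patient-level splits; each element: list(train = patient ids, test = ...)
.make_splits <- function(patients, labels, institutes, scheme, seed) {
  set.seed(seed)
  splits <- list()
  if (scheme$kind == "repeated_kfold") {
    for (r in seq_len(scheme$rounds)) {
      fold <- integer(length(patients))
      for (l in unique(labels)) {       # stratified by response
        idx <- sample(which(labels == l))
        fold[idx] <- rep_len(seq_len(scheme$folds), length(idx))
      }
      for (f in seq_len(scheme$folds)) {
        splits[[length(splits) + 1L]] <- list(
          train = patients[fold != f], test = patients[fold == f],
          round = r)
      }
    }
  } else if (scheme$kind == "leave_one_institute_out") {
    for (inst in sort(unique(institutes))) {
      splits[[length(splits) + 1L]] <- list(
        train = patients[institutes != inst],
        test = patients[institutes == inst], round = inst)
    }
  } else {
    for (r in seq_len(scheme$rounds)) {
      test <- sample(patients, scheme$holdout_size)
      splits[[length(splits) + 1L]] <- list(
        train = setdiff(patients, test), test = test, round = r)
    }
  }
  splits
}

.classification_metrics <- function(probs, truth, positive, negative) {
  pred <- ifelse(probs >= 0.5, positive, negative)
  y <- truth == positive
  tp <- sum(pred == positive & y); fp <- sum(pred == positive & !y)
  fn <- sum(pred == negative & y); tn <- sum(pred == negative & !y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  sens95 <- if (any(y) && !all(y))
    sensitivity_at_specificity(probs, truth, positive) else NA_real_
  c(auc = auc_score(probs, truth, positive),
    accuracy = (tp + tn) / length(truth),
    f1 = f1, precision = prec, recall = rec,
    balanced_accuracy = mean(c(rec, spec)),
    sens_at_95spec = sens95,
    tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Evaluate response classification under a patient-grouped scheme
#'
#' Runs the classification harness: per patient-level split, optionally
#' refits the full feature pipeline on training samples only (batch
#' correction with the response covariate preserved, per-bin
#' standardization, truncated SVD), applies it frozen to the test samples,
#' trains the classifier, and scores the held-out samples. Metrics are
#' reported at the sample level (overall and per timepoint) and at the
#' patient level after [patient_prediction()], aggregated as mean and SD
#' over rounds.
#'
#' `correction_policy`:
#' \describe{
#'   \item{"global"}{use `values` as given (a matrix already corrected and
#'     standardized upstream); standardization and SVD are still fitted on
#'     the training samples of each split.}
#'   \item{"refit"}{fit batch correction on the training samples of each
#'     split and apply the frozen coefficients to the test samples (the
#'     fully leakage-free protocol).}
#'   \item{"none"}{no batch correction (baseline for measuring what the
#'     correction buys).}
#' }
#'
#' @param values Samples x bins matrix.
#' @param metadata Sample metadata.
#' @param scheme An [eval_scheme()].
#' @param classifier A classifier object (default [classifier_logistic()]).
#' @param correction_policy See above.
#' @param n_components SVD components (default 6).
#' @param batch_factors Batch factors for `"refit"`.
#' @param positive,negative Class labels.
#' @param timepoint_order Ordering used for patient-level prediction.
#' @param seed Integer seed for the splits.
#' @return An `eval_report`: `patient_rounds` and `sample_rounds`
#'   (per-round metric tables), `aggregate` (metric, level, mean, sd),
#'   `by_timepoint`, `n_skipped`, `predictions`.
#' @export
run_evaluation <- function(values, metadata, scheme,
                           classifier = classifier_logistic(),
                           correction_policy = c("global", "refit", "none"),
                           n_components = 6L,
                           batch_factors = c("institute"),
                           positive = "Responder", negative = "Non-Responder",
                           timepoint_order = c("Screen", "Day0", "AdjWk1"),
                           seed = 1L) {
  correction_policy <- match.arg(correction_policy)
  md <- .align_metadata(values, metadata)
  pt <- unique(md[, .(patient_id, response, institute)])
  splits <- .make_splits(pt$patient_id, pt$response, pt$institute, scheme,
                         seed)
  n_skipped <- 0L
  preds <- list()
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    tr <- which(md$patient_id %in% sp$train)
    te <- which(md$patient_id %in% sp$test)
    if (length(unique(md$response[tr])) < 2L || !length(te)) {
      n_skipped <- n_skipped + 1L
      next
    }
    x_tr <- values[tr, , drop = FALSE]
    x_te <- values[te, , drop = FALSE]
    if (correction_policy == "refit") {
      cm <- try(fit_correction(x_tr, md[tr], batch_factors = batch_factors),
                silent = TRUE)
      if (inherits(cm, "try-error")) {      # e.g. aliased factors in a fold
        n_skipped <- n_skipped + 1L
        next
      }
      x_tr <- apply_correction(x_tr, md[tr], cm)
      x_te <- suppressWarnings(apply_correction(x_te, md[te], cm))
    }
    x_tr <- standardize_bins(x_tr)
    x_te <- standardize_bins(x_te, scaler = attr(x_tr, "scaler"))
    emb <- svd_reduce(x_tr, n_components = min(n_components, dim(x_tr)))
    f_tr <- emb$scores
    f_te <- project_svd(emb, x_te)
    y_tr <- factor(md$response[tr], levels = c(negative, positive))
    model <- try(classifier$fit(f_tr, y_tr), silent = TRUE)
    if (inherits(model, "try-error")) {
      n_skipped <- n_skipped + 1L
      next
    }
    probs <- classifier$predict(model, f_te)
    preds[[length(preds) + 1L]] <- data.table::data.table(
      round = sp$round, sample_id = md$sample_id[te],
      patient_id = md$patient_id[te], timepoint = md$timepoint[te],
      response = md$response[te], probability = probs)
  }
  if (!length(preds)) stop("no evaluable splits")
  pred_dt <- data.table::rbindlist(preds)

  sample_rounds <- pred_dt[, as.list(.classification_metrics(
    probability, response, positive, negative)), by = round]
  by_tp <- pred_dt[, as.list(.classification_metrics(
    probability, response, positive, negative)), by = .(round, timepoint)]
  pat_rounds <- pred_dt[, {
    pp <- patient_prediction(.SD, timepoint_order, positive, negative)
    as.list(.classification_metrics(pp$probability, pp$response, positive,
                                    negative))
  }, by = round]

  agg <- data.table::rbindlist(list(
    .aggregate_metrics(sample_rounds, "sample"),
    .aggregate_metrics(pat_rounds, "patient")))
  structure(list(sample_rounds = sample_rounds,
                 patient_rounds = pat_rounds,
                 by_timepoint = by_tp, aggregate = agg,
                 n_skipped = n_skipped, predictions = pred_dt,
                 scheme = scheme, correction_policy = correction_policy),
            class = "eval_report")
}

.aggregate_metrics <- function(rounds_dt, level) {
  cols <- setdiff(names(rounds_dt), c("round", "timepoint"))
  data.table::rbindlist(lapply(cols, function(cn) {
    v <- rounds_dt[[cn]]
    data.table::data.table(level = level, metric = cn,
                           mean = mean(v, na.rm = TRUE),
                           sd = stats::sd(v, na.rm = TRUE))
  }))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (", x$scheme$kind, ", correction = ",
      x$correction_policy, ")\n", sep = "")
  a <- x$aggregate[x$aggregate$metric %in%
                     c("auc", "accuracy", "balanced_accuracy")]
  print(a, row.names = FALSE)
  invisible(x)
}

#' Evaluate classification on bin subsets
#'
#' Reruns [run_evaluation()] with the feature matrix restricted to each bin
#' subset before SVD — used to compare, e.g., differential bins against
#' random bins of equal size.
#'
#' @param values Samples x bins matrix.
#' @param metadata Sample metadata.
#' @param subsets Named list of bin-name vectors.
#' @param scheme An [eval_scheme()].
#' @param ... Passed to [run_evaluation()].
#' @return Named list of `eval_report`s.
#' @export
feature_subset_evaluation <- function(values, metadata, subsets, scheme,
                                      ...) {
  stopifnot(is.list(subsets), length(subsets) >= 1L)
  lapply(subsets, function(b) {
    if (!length(b)) stop("empty bin subset")
    run_evaluation(values[, b, drop = FALSE], metadata, scheme, ...)
  })
}
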