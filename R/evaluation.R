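# Confusion-matrix metrics and the staged tune/retrain/evaluate/finalize
# protocol for per-family models.

#' Confusion counts for binary family-membership calls
#'
#' @param y_true,y_pred labels coded +1 (member) / -1 (non-member), equal
#'   length.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("label vectors differ in length (%d vs %d)",
          length(y_true), length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(-1L, 1L)))
    stopf("labels must be coded +1 / -1")
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == -1L & y_pred == -1L),
    FP = sum(y_true == -1L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == -1L))
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `PR = TP/(TP+FP)`. A ratio with a
#' zero denominator is undefined and reported as `NA` (never coerced to 0).
#'
#' @param counts named vector with elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric `c(SE, SP, PR)` with `NA` for undefined ratios.
#' @export
classification_metrics <- function(counts) {
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  c(SE = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    SP = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    PR = if (TP + FP > 0) TP / (TP + FP) else NA_real_)
}

partition_xy <- function(split, X, partition) {
  ids <- c(split$partitions[[partition]]$pos, split$partitions[[partition]]$neg)
  y <- c(rep(1L, length(split$partitions[[partition]]$pos)),
         rep(-1L, length(split$partitions[[partition]]$neg)))
  missing <- setdiff(ids, rownames(X))
  if (length(missing) > 0L)
    stopf("feature matrix lacks rows for: %s", paste(missing, collapse = ", "))
  list(X = X[ids, , drop = FALSE], y = y, ids = ids)
}

#' Run the staged model-construction protocol for one family
#'
#' The four stages:
#' 1. hyperparameters are optimized on the training set and scored on the
#'    testing set ([grid_search()]);
#' 2. training and testing sets are combined and a new model is trained with
#'    the chosen hyperparameters;
#' 3. the independent set — never seen during tuning — evaluates that model
#'    (confusion counts and SE/SP/PR form the report);
#' 4. a final model is trained on all three partitions with the same
#'    hyperparameters.
#'
#' For the svm backend the stage-2 and final models carry a Platt probability
#' sigmoid fitted by cross-validation within their own training data; knn and
#' pnn report their native normalized scores.
#'
#' @param split a `dataset_split` with all three partitions populated by both
#'   classes.
#' @param sequences a validated [protein_set] covering the split.
#' @param method `"svm"`, `"knn"` or `"pnn"`.
#' @param grid hyperparameter grid (default [default_grid()]).
#' @param config a [descriptor_config].
#' @param seed integer seed (Platt folds; grid evaluation is deterministic).
#' @return A list: `model` (final, all-data), `eval_model` (stage-2),
#'   `report` (an `evaluation_report`), `best` (chosen hyperparameters).
#' @export
run_protocol <- function(split, sequences, method = c("svm", "knn", "pnn"),
                         grid = NULL, config = descriptor_config(),
                         seed = 1L) {
  method <- match.arg(method)
  for (p in PARTITIONS) {
    npos <- length(split$partitions[[p]]$pos)
    nneg <- length(split$partitions[[p]]$neg)
    if (npos == 0L || nneg == 0L)
      stopf("partition '%s' is missing a class (%d pos / %d neg)",
            p, npos, nneg)
  }
  used_ids <- unlist(lapply(split$partitions, unlist), use.names = FALSE)
  seqs <- sequences[match(used_ids, sequences$id), , drop = FALSE]
  class(seqs) <- c("protein_set", "data.frame")
  X <- featurize_matrix(seqs, config)
  tr <- partition_xy(split, X, "train")
  te <- partition_xy(split, X, "test")
  ind <- partition_xy(split, X, "independent")

  gs <- grid_search(method, tr$X, tr$y, te$X, te$y, grid = grid, seed = seed)

  X12 <- rbind(tr$X, te$X); y12 <- c(tr$y, te$y)
  attr(X12, "config_digest") <- config$digest
  eval_model <- train_classifier(method, X12, y12, gs$best,
                                 platt = (method == "svm"),
                                 seed = derive_seed(seed, "platt-eval"),
                                 config_digest = config$digest)
  pred <- predict(eval_model, ind$X)
  cm <- confusion_counts(ind$y, ifelse(pred$label == "member", 1L, -1L))
  met <- classification_metrics(cm)
  report <- structure(list(family_id = split$family_id, method = method,
                           TP = cm[["TP"]], TN = cm[["TN"]],
                           FP = cm[["FP"]], FN = cm[["FN"]],
                           SE = met[["SE"]], SP = met[["SP"]],
                           PR = met[["PR"]],
                           chosen_hyperparameters = gs$best,
                           n_evaluated = length(ind$y)),
                      class = "evaluation_report")

  X_all <- rbind(X12, ind$X); y_all <- c(y12, ind$y)
  attr(X_all, "config_digest") <- config$digest
  final_model <- train_classifier(method, X_all, y_all, gs$best,
                                  platt = (method == "svm"),
                                  seed = derive_seed(seed, "platt-final"),
                                  config_digest = config$digest)
  list(model = final_model, eval_model = eval_model, report = report,
       best = gs$best)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: family '%s', method %s\n",
              x$family_id, x$method))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d (n = %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$n_evaluated))
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.3f", v)
  cat(sprintf("  SE %s  SP %s  PR %s\n", fmt(x$SE), fmt(x$SP), fmt(x$PR)))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(family_id = x$family_id, method = x$method,
             TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN,
             SE = x$SE, SP = x$SP, PR = x$PR,
             hyperparameters = paste(names(x$chosen_hyperparameters),
                                     unlist(x$chosen_hyperparameters),
                                     sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write evaluation reports as TSV and/or JSON
#'
#' @param reports an `evaluation_report` or a list of them.
#' @param tsv,json output paths (`NULL` to skip either).
#' @return Invisibly, the combined data frame.
#' @export
write_report <- function(reports, tsv = NULL, json = NULL) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(df)
}
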