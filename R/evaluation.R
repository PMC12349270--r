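# Confusion matrices and the four reported performance metrics, with the
# aggressive class as positive throughout: sensitivity is recall of
# aggressive movement, specificity recall of non-aggressive movement.

#' Confusion matrix
#'
#' Counts with positive class `aggressive`: TP = aggressive correctly
#' flagged, TN = non-aggressive correctly passed, FN = missed aggressive,
#' FP = false alarms.
#'
#' @param y_true,y_pred Class label vectors of equal length.
#' @return A list of class `confusion_matrix` with `tn`, `fp`, `fn`, `tp`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  pos_t <- y_true == POSITIVE_CLASS
  pos_p <- y_pred == POSITIVE_CLASS
  confusion_matrix(tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p),
                   fn = sum(pos_t & !pos_p), tp = sum(pos_t & pos_p))
}

#' Construct a confusion matrix from counts
#' @param tn,fp,fn,tp Nonnegative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("non_aggressive", "aggressive"),
                              true = c("non_aggressive", "aggressive")))
  print(m)
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, specificity
#' `tn/(tn+fp)`, sensitivity `tp/(tp+fn)`. Ratios with a zero denominator
#' are returned as `NaN` and flagged in the `undefined` attribute rather
#' than silently coerced to 0. Values are full precision; use
#' [report_metrics()] for the 2-decimal presentation.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector of the four metrics.
#' @export
compute_metrics <- function(cm) {
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  out <- c(accuracy = ratio(cm$tp + cm$tn, total),
           precision = ratio(cm$tp, cm$tp + cm$fp),
           specificity = ratio(cm$tn, cm$tn + cm$fp),
           sensitivity = ratio(cm$tp, cm$tp + cm$fn))
  undef <- names(out)[is.nan(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Metrics rounded for reporting
#'
#' Rounds half away from zero to 2 decimals, the convention of the printed
#' performance tables. Stored metrics stay full precision; rounding is
#' applied only at this reporting layer.
#'
#' @param metrics Output of [compute_metrics()].
#' @return Named numeric vector rounded to 2 decimals.
#' @export
report_metrics <- function(metrics) {
  round_half_up(metrics, 2L)
}

#' Train and evaluate one sensor position
#'
#' 70/30 split, depth-2 Gini tree, confusion matrix and metrics on the
#' held-out 30 percent.
#'
#' @param X,y Feature matrix and labels for one position's segments.
#' @param train_frac Training fraction.
#' @param seed Split seed.
#' @param max_depth Tree depth cap.
#' @param group_ids Optional participant ids for a grouped split.
#' @return List with `tree`, `cm`, `metrics`, `importance`, `n_train`,
#'   `n_test`.
#' @export
evaluate_position <- function(X, y, train_frac = 0.7, seed = 1L,
                              max_depth = 2L, group_ids = NULL) {
  sp <- split_data(X, y, train_frac = train_frac, seed = seed,
                   group_ids = group_ids)
  tree <- fit_tree(sp$train$X, sp$train$y, max_depth = max_depth)
  pred <- predict(tree, sp$test$X)
  cm <- confusion(sp$test$y, pred)
  list(tree = tree, cm = cm, metrics = compute_metrics(cm),
       importance = feature_importance(tree),
       n_train = length(sp$train$y), n_test = length(sp$test$y))
}

#' Evaluate every sensor position of a session
#'
#' Segments the session, extracts features, and trains and evaluates one
#' depth-2 tree per sensor position. Positions missing from the session are
#' reported as absent rows; the run continues.
#'
#' @param session An `imu_session`.
#' @param window_s,overlap_s Window geometry in seconds.
#' @param train_frac,seed,max_depth,split_mode Evaluation settings;
#'   `split_mode` is `"segment"` (stratified random) or `"participant"`
#'   (grouped).
#' @return A list of class `position_report`: `table` (data.frame with one
#'   row per position: confusion counts and metrics), `models`,
#'   `importances`, `config`.
#' @export
evaluate_all_positions <- function(session, window_s = 3, overlap_s = 1,
                                   train_frac = 0.7, seed = 1L,
                                   max_depth = 2L,
                                   split_mode = c("segment", "participant")) {
  split_mode <- match.arg(split_mode)
  segs <- segment_session(session, window_s, overlap_s)
  rows <- list()
  models <- list()
  importances <- list()
  for (pos in sensor_positions()) {
    if (is.null(segs[[pos]]) || length(segs[[pos]]) == 0L) {
      rows[[pos]] <- data.frame(position = pos, absent = TRUE,
                                tn = NA, fp = NA, fn = NA, tp = NA,
                                accuracy = NA, precision = NA,
                                specificity = NA, sensitivity = NA)
      next
    }
    fm <- feature_matrix(segs[[pos]])
    gids <- if (split_mode == "participant") {
      vapply(segs[[pos]], function(s) sub("_t.*$", "", s$recording_id),
             character(1))
    } else NULL
    res <- evaluate_position(fm$X, fm$y, train_frac = train_frac,
                             seed = derive_seed(seed, match(pos, sensor_positions())),
                             max_depth = max_depth, group_ids = gids)
    models[[pos]] <- res$tree
    importances[[pos]] <- res$importance
    m <- res$metrics
    rows[[pos]] <- data.frame(position = pos, absent = FALSE,
                              tn = res$cm$tn, fp = res$cm$fp,
                              fn = res$cm$fn, tp = res$cm$tp,
                              accuracy = m["accuracy"],
                              precision = m["precision"],
                              specificity = m["specificity"],
                              sensitivity = m["sensitivity"])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, models = models, importances = importances,
                 config = list(window_s = window_s, overlap_s = overlap_s,
                               train_frac = train_frac, seed = seed,
                               max_depth = max_depth,
                               split_mode = split_mode,
                               n_unlabeled = attr(segs, "n_unlabeled"))),
            class = "position_report")
}

#' @export
print.position_report <- function(x, ...) {
  tab <- x$table
  for (col in c("accuracy", "precision", "specificity", "sensitivity")) {
    tab[[col]] <- round_half_up(tab[[col]], 2L)
  }
  print(tab[, setdiff(names(tab), "absent")])
  invisible(x)
}

#' Write a position report to CSV and JSON
#'
#' The CSV holds one row per position with confusion counts and 2-decimal
#' metrics; the JSON companion carries full-precision metrics, the feature
#' importances, and the configuration echo (seed, split mode, window
#' geometry) so the run can be reproduced.
#'
#' @param report A `position_report`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(report, csv_path, json_path) {
  tab <- report$table
  for (col in c("accuracy", "precision", "specificity", "sensitivity")) {
    tab[[col]] <- round_half_up(tab[[col]], 2L)
  }
  data.table::fwrite(tab[, setdiff(names(tab), "absent")], csv_path)
  doc <- list(config = report$config,
              positions = report$table,
              importances = lapply(report$importances, function(v)
                as.list(v)))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(c(csv_path, json_path))
}
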