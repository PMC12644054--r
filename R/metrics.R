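# Clinical-style evaluation: per-window classification and agreement metrics,
# threshold-sweep AUCs, temporal transition/consistency scores, and
# event-level detection with temporal IoU and time-to-detection.

#' Confusion-matrix classification metrics
#'
#' Accuracy, per-class precision/recall/F1, macro-F1 (classes absent from both
#' truth and prediction are excluded from the macro average) and micro-F1
#' (which equals accuracy for single-label multiclass data).
#'
#' @param data tibble with the label columns, or `NULL` when vectors are
#'   passed directly.
#' @param truth,estimate column names (with `data`) or integer label vectors
#'   in `0..K-1`.
#' @param K number of classes (default: inferred from the data).
#' @return list with `accuracy`, `macro_f1`, `micro_f1`, and `per_class`
#'   (a tibble with `class`, `precision`, `recall`, `f1`, `support`,
#'   `present`).
#' @export
confusion_metrics <- function(data = NULL, truth = "truth", estimate = "estimate",
                              K = NULL) {
  v <- resolve_pair(data, truth, estimate)
  y <- v$y; yhat <- v$yhat
  if (length(y) == 0L) stop_sg("confusion_metrics: empty sequences")
  K <- K %||% (max(c(y, yhat)) + 1L)
  per <- lapply(0:(K - 1L), function(k) {
    tp <- sum(y == k & yhat == k)
    fp <- sum(y != k & yhat == k)
    fn <- sum(y == k & yhat != k)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = k, precision = precision, recall = recall, f1 = f1,
                   support = sum(y == k), present = any(y == k) || any(yhat == k),
                   tp = tp, fp = fp, fn = fn)
  })
  per <- dplyr::bind_rows(per)
  tp_all <- sum(per$tp); fp_all <- sum(per$fp); fn_all <- sum(per$fn)
  p_micro <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else 0
  r_micro <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else 0
  micro_f1 <- if (p_micro + r_micro > 0) 2 * p_micro * r_micro / (p_micro + r_micro) else 0
  list(accuracy = mean(y == yhat),
       macro_f1 = mean(per$f1[per$present]),
       micro_f1 = micro_f1,
       per_class = per[, c("class", "precision", "recall", "f1", "support", "present")])
}

resolve_pair <- function(data, truth, estimate) {
  if (is.null(data)) {
    list(y = as.integer(truth), yhat = as.integer(estimate))
  } else {
    list(y = as.integer(data[[truth]]), yhat = as.integer(data[[estimate]]))
  }
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with marginal
#' expected agreement `p_e = sum_k (n_k^true / T)(n_k^pred / T)`. When
#' `p_e = 1` the value is defined as 1 for perfect agreement and 0 otherwise
#' (with a warning).
#'
#' @inheritParams confusion_metrics
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(data = NULL, truth = "truth", estimate = "estimate") {
  v <- resolve_pair(data, truth, estimate)
  y <- v$y; yhat <- v$yhat
  if (length(y) == 0L) stop_sg("cohens_kappa: empty sequences")
  Tn <- length(y)
  p_o <- mean(y == yhat)
  classes <- union(y, yhat)
  p_e <- sum(vapply(classes, function(k) mean(y == k) * mean(yhat == k), numeric(1)))
  if (abs(1 - p_e) < 1e-12) {
    warn_sg("cohens_kappa: expected agreement is 1; returning %d", as.integer(p_o == 1))
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' ROC and precision-recall AUC for one class
#'
#' One-vs-rest threshold sweep on the class score: trapezoidal integration
#' for the ROC curve, step-wise (conservative) interpolation for the PR
#' curve. Requires both classes present in the truth; otherwise returns `NA`
#' sentinels with a warning.
#'
#' @param scores numeric score for the positive class, higher = more positive.
#' @param truth binary truth (1 = positive class).
#' @return list with `auc_roc` and `auc_pr`.
#' @export
roc_pr_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) {
    warn_sg("roc_pr_auc: single-class truth; AUCs undefined")
    return(list(auc_roc = NA_real_, auc_pr = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]; s <- scores[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # collapse threshold ties: keep the last index of each distinct score
  keep <- c(diff(s) != 0, TRUE)
  tp <- c(0, tp[keep]); fp <- c(0, fp[keep])
  tpr <- tp / P; fpr <- fp / N
  auc_roc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  rec <- tpr
  # step interpolation: each recall increment credited at the new precision
  auc_pr <- sum(diff(rec) * tail(prec, -1))
  list(auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Transition accuracy
#'
#' Fraction of adjacent window pairs where the prediction changes exactly when
#' the truth changes: `(1/(T-1)) sum 1[(yhat_{t+1} != yhat_t) <=>
#' (y_{t+1} != y_t)]`.
#'
#' @inheritParams confusion_metrics
#' @return rate in `[0, 1]`.
#' @export
transition_accuracy <- function(data = NULL, truth = "truth", estimate = "estimate") {
  v <- resolve_pair(data, truth, estimate)
  if (length(v$y) < 2L) stop_sg("transition_accuracy: need T >= 2")
  tr_true <- diff(v$y) != 0
  tr_pred <- diff(v$yhat) != 0
  mean(tr_true == tr_pred)
}

#' Temporal consistency score
#'
#' `1 - (1/(T-1)) sum omega(y_t, y_{t+1}) 1[yhat_t != yhat_{t+1}]`, penalizing
#' predicted transitions, optionally weighted by a `K x K` transition-penalty
#' matrix indexed by the true labels (default: constant 1).
#'
#' @inheritParams confusion_metrics
#' @param omega `K x K` nonnegative penalty matrix or a single constant.
#' @return the score (1 when the prediction never changes).
#' @export
consistency_score <- function(data = NULL, truth = "truth", estimate = "estimate",
                              omega = 1) {
  v <- resolve_pair(data, truth, estimate)
  y <- v$y; yhat <- v$yhat
  if (length(y) < 2L) stop_sg("consistency_score: need T >= 2")
  w <- if (is.matrix(omega)) {
    if (any(omega < 0)) stop_sg("omega must be nonnegative")
    omega[cbind(head(y, -1) + 1L, tail(y, -1) + 1L)]
  } else rep(omega, length(y) - 1L)
  1 - mean(w * (diff(yhat) != 0))
}

#' Convert a window label sequence to event spans
#'
#' Maximal runs of a non-background label become half-open spans
#' `[start, end)` in seconds.
#'
#' @param labels integer labels per window.
#' @param windows tibble with `start`, `end` per window (aligned with
#'   `labels`).
#' @param background label treated as no-event (default 0).
#' @return tibble with `label`, `start`, `end`.
#' @export
labels_to_spans <- function(labels, windows, background = 0L) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != background
  tibble::tibble(label = r$values[keep],
                 start = windows$start[starts[keep]],
                 end = windows$end[ends[keep]])
}

interval_iou <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) 0 else inter / uni
}

#' Event-level detection metrics
#'
#' Greedy one-to-one matching of predicted to true spans by descending
#' temporal IoU (same label required); a true event counts detected when its
#' matched IoU reaches `tau_iou`. Detection delay for a matched event is the
#' first correctly-labeled window center at or after onset minus the onset.
#' Overlapping same-label true spans are merged with a warning.
#'
#' @param pred_spans,true_spans tibbles with `label`, `start`, `end`.
#' @param tau_iou IoU detection threshold (default 0.5).
#' @param window_times optional tibble with `time` (window centers) and
#'   `estimate` (predicted label per window) used for detection delays.
#' @return list with `event_precision`, `event_recall`, `event_f1`,
#'   `mean_iou`, `mean_delay`, and `matches` (per-true-event tibble with
#'   `label`, `start`, `end`, `iou`, `detected`, `delay`).
#' @export
event_detection_metrics <- function(pred_spans, true_spans, tau_iou = 0.5,
                                    window_times = NULL) {
  true_spans <- merge_overlapping_spans(true_spans)
  np <- nrow(pred_spans); nt <- nrow(true_spans)
  if (nt == 0L) {
    return(list(event_precision = if (np == 0) 1 else 0,
                event_recall = 1, event_f1 = if (np == 0) 1 else 0,
                mean_iou = NA_real_, mean_delay = NA_real_,
                matches = tibble::tibble()))
  }
  iou <- matrix(0, np, nt)
  if (np > 0) {
    for (i in seq_len(np)) for (j in seq_len(nt)) {
      if (pred_spans$label[i] == true_spans$label[j]) {
        iou[i, j] <- interval_iou(pred_spans$start[i], pred_spans$end[i],
                                  true_spans$start[j], true_spans$end[j])
      }
    }
  }
  matched_iou <- rep(0, nt)
  used_pred <- logical(np)
  if (np > 0) {
    cand <- which(iou > 0, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(-iou[cand], cand[, 1], cand[, 2]), , drop = FALSE]
      taken_true <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_pred[i] && !taken_true[j]) {
          used_pred[i] <- TRUE; taken_true[j] <- TRUE
          matched_iou[j] <- iou[i, j]
        }
      }
    }
  }
  detected <- matched_iou >= tau_iou
  delay <- rep(NA_real_, nt)
  if (!is.null(window_times)) {
    for (j in which(detected)) {
      hit <- window_times$time >= true_spans$start[j] &
        window_times$estimate == true_spans$label[j]
      if (any(hit)) delay[j] <- min(window_times$time[hit]) - true_spans$start[j]
    }
  }
  tp <- sum(detected)
  precision <- if (np > 0) tp / np else if (tp == 0 && nt == 0) 1 else 0
  recall <- tp / nt
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(event_precision = precision, event_recall = recall, event_f1 = f1,
       mean_iou = mean(matched_iou),
       mean_delay = if (any(!is.na(delay))) mean(delay, na.rm = TRUE) else NA_real_,
       matches = dplyr::bind_cols(true_spans,
                                  tibble::tibble(iou = matched_iou,
                                                 detected = detected,
                                                 delay = delay)))
}

merge_overlapping_spans <- function(spans) {
  if (nrow(spans) < 2L) return(spans)
  out <- list()
  for (lab in unique(spans$label)) {
    s <- spans[spans$label == lab, ]
    s <- s[order(s$start), ]
    merged <- s[1, ]
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        last <- nrow(merged)
        if (s$start[i] < merged$end[last]) {
          warn_sg("merging overlapping same-label true spans")
          merged$end[last] <- max(merged$end[last], s$end[i])
        } else {
          merged <- dplyr::bind_rows(merged, s[i, ])
        }
      }
    }
    out[[as.character(lab)]] <- merged
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Full evaluation report for one or more sessions
#'
#' Computes the complete metric suite from per-window truth/prediction
#' (and optionally soft scores and window geometry for AUCs, events and
#' delays).
#'
#' @param data tibble with columns `truth`, `estimate`, optionally `session`,
#'   `time` (window centers, seconds), `start`/`end` (window spans) and score
#'   columns `score_0..score_{K-1}`.
#' @param K number of classes (default inferred).
#' @param tau_iou event detection IoU threshold.
#' @param omega consistency penalty matrix or constant.
#' @return object of class `sleepgraph_eval`: list with `classification`,
#'   `temporal`, `events`, `per_class`.
#' @export
evaluate_windows <- function(data, K = NULL, tau_iou = 0.5, omega = 1) {
  stopifnot(all(c("truth", "estimate") %in% names(data)))
  K <- K %||% (max(c(data$truth, data$estimate)) + 1L)
  cm <- confusion_metrics(data, K = K)
  kappa <- cohens_kappa(data)
  score_cols <- paste0("score_", 0:(K - 1L))
  aucs <- NULL
  if (all(score_cols %in% names(data))) {
    aucs <- dplyr::bind_rows(lapply(0:(K - 1L), function(k) {
      if (length(unique(data$truth == k)) < 2L) {
        return(tibble::tibble(class = k, auc_roc = NA_real_, auc_pr = NA_real_))
      }
      a <- roc_pr_auc(data[[paste0("score_", k)]], as.integer(data$truth == k))
      tibble::tibble(class = k, auc_roc = a$auc_roc, auc_pr = a$auc_pr)
    }))
  }
  sessions <- if ("session" %in% names(data)) unique(data$session) else "all"
  per_session <- lapply(sessions, function(sid) {
    d <- if ("session" %in% names(data)) data[data$session == sid, ] else data
    list(trans = transition_accuracy(d),
         consist = consistency_score(d, omega = omega),
         d = d)
  })
  trans_acc <- mean(vapply(per_session, `[[`, numeric(1), "trans"))
  consist <- mean(vapply(per_session, `[[`, numeric(1), "consist"))
  events <- NULL
  if (all(c("start", "end") %in% names(data))) {
    ev <- lapply(per_session, function(ps) {
      d <- ps$d
      wins <- tibble::tibble(start = d$start, end = d$end)
      ts <- labels_to_spans(d$truth, wins)
      pspans <- labels_to_spans(d$estimate, wins)
      wt <- tibble::tibble(time = if ("time" %in% names(d)) d$time else (d$start + d$end) / 2,
                           estimate = d$estimate)
      event_detection_metrics(pspans, ts, tau_iou, wt)
    })
    matches <- dplyr::bind_rows(lapply(ev, `[[`, "matches"))
    nt <- nrow(matches)
    tp <- if (nt > 0) sum(matches$detected) else 0
    n_pred_total <- sum(vapply(seq_along(ev), function(i) {
      d <- per_session[[i]]$d
      nrow(labels_to_spans(d$estimate, tibble::tibble(start = d$start, end = d$end)))
    }, numeric(1)))
    precision <- if (n_pred_total > 0) tp / n_pred_total else if (nt == 0) 1 else 0
    recall <- if (nt > 0) tp / nt else 1
    events <- list(
      event_precision = precision,
      event_recall = recall,
      event_f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0,
      mean_iou = if (nt > 0) mean(matches$iou) else NA_real_,
      mean_delay = if (any(!is.na(matches$delay))) mean(matches$delay, na.rm = TRUE) else NA_real_,
      matches = matches)
  }
  structure(list(
    classification = list(accuracy = cm$accuracy, macro_f1 = cm$macro_f1,
                          micro_f1 = cm$micro_f1, kappa = kappa, auc = aucs),
    temporal = list(transition_accuracy = trans_acc,
                    consistency_score = consist),
    events = events,
    per_class = cm$per_class,
    n_windows = nrow(data), K = K
  ), class = "sleepgraph_eval")
}

#' @export
print.sleepgraph_eval <- function(x, ...) {
  cat("<sleepgraph evaluation>\n")
  cat(sprintf("  windows: %d, classes: %d\n", x$n_windows, x$K))
  cat(sprintf("  accuracy %.4f | macro-F1 %.4f | micro-F1 %.4f | kappa %.4f\n",
              x$classification$accuracy, x$classification$macro_f1,
              x$classification$micro_f1, x$classification$kappa))
  cat(sprintf("  transition accuracy %.4f | consistency %.4f\n",
              x$temporal$transition_accuracy, x$temporal$consistency_score))
  if (!is.null(x$events)) {
    cat(sprintf("  event P/R/F1 %.3f/%.3f/%.3f | mean IoU %.3f | mean delay %s s\n",
                x$events$event_precision, x$events$event_recall,
                x$events$event_f1, x$events$mean_iou,
                ifelse(is.na(x$events$mean_delay), "NA",
                       sprintf("%.1f", x$events$mean_delay))))
  }
  invisible(x)
}

#' Tidy an evaluation report into a long tibble
#'
#' @param x a `sleepgraph_eval` object.
#' @param ... unused.
#' @return tibble with `metric`, `class` (NA for aggregates), `value`.
#' @export
tidy.sleepgraph_eval <- function(x, ...) {
  rows <- tibble::tibble(
    metric = c("accuracy", "macro_f1", "micro_f1", "kappa",
               "transition_accuracy", "consistency_score"),
    class = NA_integer_,
    value = c(x$classification$accuracy, x$classification$macro_f1,
              x$classification$micro_f1, x$classification$kappa,
              x$temporal$transition_accuracy, x$temporal$consistency_score))
  pc <- tidyr::pivot_longer(x$per_class[, c("class", "precision", "recall", "f1")],
                            -"class", names_to = "metric", values_to = "value")
  rows <- dplyr::bind_rows(rows, pc[, c("metric", "class", "value")])
  if (!is.null(x$classification$auc)) {
    au <- tidyr::pivot_longer(x$classification$auc, -"class",
                              names_to = "metric", values_to = "value")
    rows <- dplyr::bind_rows(rows, au[, c("metric", "class", "value")])
  }
  if (!is.null(x$events)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = c("event_precision", "event_recall", "event_f1", "mean_iou",
                 "mean_delay"),
      class = NA_integer_,
      value = c(x$events$event_precision, x$events$event_recall,
                x$events$event_f1, x$events$mean_iou, x$events$mean_delay)))
  }
  rows
}

#' Write an evaluation report to JSON and a per-class CSV
#'
#' @param eval a `sleepgraph_eval` object.
#' @param json_path output JSON path.
#' @param csv_path optional per-class CSV path.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(eval, json_path, csv_path = NULL) {
  payload <- list(classification = eval$classification[c("accuracy", "macro_f1",
                                                         "micro_f1", "kappa")],
                  temporal = eval$temporal,
                  events = if (!is.null(eval$events)) {
                    eval$events[c("event_precision", "event_recall", "event_f1",
                                  "mean_iou", "mean_delay")]
                  },
                  per_class = eval$per_class,
                  n_windows = eval$n_windows, K = eval$K)
  jsonlite::write_json(payload, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_path)) utils::write.csv(eval$per_class, csv_path, row.names = FALSE)
  invisible(json_path)
}
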