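# Early-warning evaluation: confusion metrics on the diseased-vs-healthy
# reduction, one-vs-rest early-stage metrics, hysteresis-based detection
# time and lead time on per-event trajectories, and leakage-free
# event-level cross-validation splits.

#' Confusion counts for the binary diseased-vs-healthy reduction
#'
#' Early and symptomatic both count as diseased.
#'
#' @param predicted,actual character vectors of stage labels.
#' @return a `confusion_counts` list with tp, tn, fp, fn.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  pd <- predicted != "healthy"
  ad <- actual != "healthy"
  structure(list(tp = sum(pd & ad), tn = sum(!pd & !ad),
                 fp = sum(pd & !ad), fn = sum(!pd & ad)),
            class = "confusion_counts")
}

#' Accuracy, recall, precision and F1 from confusion counts
#'
#' Ratios with zero denominators are reported as NA (flagged undefined),
#' never silently as 0.
#'
#' @param counts a `confusion_counts` list (or any list with tp/tn/fp/fn).
#' @return named numeric vector (accuracy, recall, precision, f1).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("no evaluated samples")
  acc <- (tp + tn) / n
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(rec) && !is.na(prec) && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' One-vs-rest metrics for the early stage
#'
#' @param predicted,actual character vectors of stage labels.
#' @return named vector (early_precision, early_recall, early_f1); NA where
#'   undefined.
#' @export
early_stage_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  tp <- sum(predicted == "early" & actual == "early")
  fp <- sum(predicted == "early" & actual != "early")
  fn <- sum(predicted != "early" & actual == "early")
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  c(early_precision = prec, early_recall = rec, early_f1 = f1)
}

#' Hysteresis detection time on one trajectory
#'
#' Detection is declared at the k-th observation of the first run of at
#' least `k` consecutive observations whose disease probability strictly
#' exceeds `threshold` (the hysteresis rule suppressing transient false
#' alarms).
#'
#' @param times ordered observation instants (POSIXct or numeric).
#' @param probs per-observation disease probabilities (1 - P(healthy)).
#' @param threshold probability threshold (strict inequality).
#' @param k required consecutive exceedances.
#' @return the detection instant, or NA if no qualifying run exists.
#' @export
detection_time <- function(times, probs, threshold = 0.5, k = 3L) {
  if (length(times) == 0L) stop("empty trajectory")
  stopifnot(length(times) == length(probs), k >= 1L)
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  run <- 0L
  for (i in seq_along(probs)) {
    run <- if (isTRUE(probs[i] > threshold)) run + 1L else 0L
    if (run >= k) return(times[i])
  }
  times[NA_integer_]
}

#' Lead time over true-positive trajectories
#'
#' For each detected, truly diseased trajectory,
#' `lead = t_ref - t_det` in days (positive = warning earlier than the
#' reference onset). Undetected trajectories are excluded from the mean and
#' counted separately.
#'
#' @param trajectories list of trajectory lists, each with `event_id`,
#'   `times`, `probs`, `t_ref` (reference onset), `diseased` (logical).
#' @param threshold,k hysteresis parameters (see [detection_time()]).
#' @return list with `mean_lead_days`, `per_event` (data.table: event_id,
#'   t_det, t_ref, lead_days), `n_detected`, `n_diseased`.
#' @export
lead_time <- function(trajectories, threshold = 0.5, k = 3L) {
  dis <- Filter(function(tr) isTRUE(tr$diseased), trajectories)
  if (length(dis) == 0L) stop("no diseased trajectories to evaluate")
  rows <- lapply(dis, function(tr) {
    td <- detection_time(tr$times, tr$probs, threshold, k)
    lead <- if (is.na(td)) NA_real_ else {
      as.numeric(difftime(tr$t_ref, td, units = "days"))
    }
    data.table::data.table(event_id = tr$event_id,
                           t_det = td, t_ref = tr$t_ref,
                           lead_days = lead)
  })
  per_event <- data.table::rbindlist(rows)
  det <- per_event$lead_days[!is.na(per_event$lead_days)]
  list(mean_lead_days = if (length(det)) mean(det) else NA_real_,
       per_event = per_event,
       n_detected = length(det),
       n_diseased = length(dis))
}

#' Leakage-free event-level cross-validation split
#'
#' Events are shuffled with the seed and dealt round-robin into K folds,
#' stratified by diseased/healthy status, so that every frame of an event
#' lands in exactly one fold.
#'
#' @param dataset a `synthetic_dataset`, or a list of `disease_event`s.
#' @param K number of folds.
#' @param seed shuffle seed.
#' @return a `split_plan`: named integer vector event_id -> fold (1..K).
#' @export
event_based_split <- function(dataset, K = 5L, seed = 1L) {
  events <- if (inherits(dataset, "synthetic_dataset")) dataset$events else dataset
  ids <- vapply(events, function(e) e$event_id, character(1L))
  dis <- vapply(events, function(e) isTRUE(e$diseased), logical(1L))
  if (length(ids) < K) stop("fewer events (", length(ids), ") than folds (", K, ")")
  set.seed(seed)
  fold <- integer(length(ids))
  names(fold) <- ids
  counter <- 0L
  for (grp in list(which(dis), which(!dis))) {
    if (!length(grp)) next
    ord <- grp[sample.int(length(grp))]
    fold[ord] <- (seq_along(ord) - 1L + counter) %% K + 1L
    counter <- counter + length(ord)
  }
  class(fold) <- "split_plan"
  fold
}

#' Per-event trajectories of model predictions
#'
#' Runs the model over each event's sequences in temporal order; each
#' sequence contributes one observation at its final frame time with
#' disease probability `1 - P(healthy)`.
#'
#' @param model a `gw_model`, or a function taking a `sequence_sample` and
#'   returning a named stage-probability vector (useful for oracle or
#'   baseline predictors in evaluation harnesses).
#' @param sequences list of `sequence_sample`s (one or more events).
#' @param events list of `disease_event`s supplying `t_ref` (onset) and
#'   diseased status.
#' @return list of trajectory lists (see [lead_time()]), with additional
#'   `pred_stages` and `true_stages` per observation.
#' @export
predict_trajectories <- function(model, sequences, events) {
  ev_by_id <- stats::setNames(events, vapply(events, `[[`, character(1L), "event_id"))
  ids <- vapply(sequences, `[[`, character(1L), "event_id")
  lapply(split(seq_along(sequences), ids), function(ix) {
    ix <- ix[order(vapply(sequences[ix], function(s) {
      as.numeric(s$timestamps[length(s$timestamps)])
    }, numeric(1L)))]
    probs <- numeric(length(ix))
    pred <- character(length(ix))
    true <- character(length(ix))
    times <- vector("numeric", length(ix))
    for (j in seq_along(ix)) {
      s <- sequences[[ix[j]]]
      sp <- if (is.function(model)) model(s) else model_forward(model, s)$stage_probs
      probs[j] <- 1 - sp[["healthy"]]
      pred[j] <- names(which.max(sp))
      true[j] <- s$stage
      times[j] <- as.numeric(s$timestamps[length(s$timestamps)])
    }
    ev <- ev_by_id[[sequences[[ix[1L]]]$event_id]]
    list(event_id = ev$event_id,
         times = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
         probs = probs, pred_stages = pred, true_stages = true,
         t_ref = ev$onset_time, diseased = isTRUE(ev$diseased))
  })
}

#' Evaluate a model on held-out sequences
#'
#' Computes confusion metrics (binary reduction plus the 3-class table),
#' early-stage metrics and lead time, optionally writing a JSON report and
#' a per-trajectory CSV.
#'
#' @param model a `gw_model`.
#' @param sequences held-out `sequence_sample`s.
#' @param events the corresponding `disease_event`s.
#' @param threshold,k hysteresis parameters.
#' @param out_dir optional directory for `report.json` and
#'   `trajectories.csv`.
#' @return an `eval_report` list.
#' @export
evaluate_run <- function(model, sequences, events, threshold = 0.5, k = 3L,
                         out_dir = NULL) {
  trajs <- predict_trajectories(model, sequences, events)
  pred <- unlist(lapply(trajs, `[[`, "pred_stages"))
  true <- unlist(lapply(trajs, `[[`, "true_stages"))
  cm <- confusion_metrics(confusion_counts(pred, true))
  em <- early_stage_metrics(pred, true)
  lt <- if (any(vapply(trajs, function(t) isTRUE(t$diseased), logical(1L)))) {
    lead_time(trajs, threshold, k)
  } else list(mean_lead_days = NA_real_, per_event = NULL,
              n_detected = 0L, n_diseased = 0L)
  tab <- table(factor(pred, STAGE_LEVELS), factor(true, STAGE_LEVELS))
  report <- list(accuracy = unname(cm["accuracy"]),
                 recall = unname(cm["recall"]),
                 precision = unname(cm["precision"]),
                 f1 = unname(cm["f1"]),
                 early_precision = unname(em["early_precision"]),
                 early_recall = unname(em["early_recall"]),
                 early_f1 = unname(em["early_f1"]),
                 lead_time_days = lt$mean_lead_days,
                 n_detected = lt$n_detected,
                 n_events = length(trajs),
                 confusion_3class = as.list(as.data.frame(tab)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "confusion_3class")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(lt$per_event)) {
      pe <- data.table::copy(lt$per_event)
      pe[, t_det := format_time(t_det)]
      pe[, t_ref := format_time(t_ref)]
      data.table::fwrite(pe, file.path(out_dir, "trajectories.csv"))
    }
  }
  structure(c(report, list(trajectories = trajs)), class = "eval_report")
}
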