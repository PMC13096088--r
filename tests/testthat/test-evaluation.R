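t0 <- as.POSIXct("2024-04-01 08:00:00", tz = "UTC")

test_that("confusion metrics match the standard formulas", {
  cm <- confusion_metrics(list(tp = 8, fn = 2, fp = 0, tn = 10))
  expect_equal(unname(cm), c(0.9, 0.8, 1.0, 2 * 0.8 / 1.8))

  perfect <- confusion_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))

  # undefined ratios are flagged NA, never 0
  noneg <- confusion_metrics(list(tp = 0, tn = 4, fp = 0, fn = 0))
  expect_true(is.na(noneg["recall"]))
  expect_true(is.na(noneg["precision"]))

  set.seed(31)
  for (rep in 1:1000) {
    k <- as.list(stats::setNames(sample.int(20L, 4L, TRUE) - 1L,
                                 c("tp", "tn", "fp", "fn")))
    if (sum(unlist(k)) == 0) next
    got <- confusion_metrics(k)
    expect_equal(got[["accuracy"]], (k$tp + k$tn) / sum(unlist(k)), tolerance = 1e-12)
    if (k$tp + k$fn > 0) expect_equal(got[["recall"]], k$tp / (k$tp + k$fn), tolerance = 1e-12)
    if (k$tp + k$fp > 0) expect_equal(got[["precision"]], k$tp / (k$tp + k$fp), tolerance = 1e-12)
  }
})

test_that("binary reduction counts early and symptomatic as diseased", {
  pred <- c("healthy", "early", "symptomatic", "healthy")
  act <- c("healthy", "symptomatic", "early", "early")
  cc <- confusion_counts(pred, act)
  expect_equal(cc$tp, 2L); expect_equal(cc$tn, 1L)
  expect_equal(cc$fp, 0L); expect_equal(cc$fn, 1L)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 4L)
})

test_that("early-stage metrics are the one-vs-rest reduction", {
  expect_equal(unname(early_stage_metrics(c("early", "early"), c("early", "early"))),
               c(1, 1, 1))
  deg <- early_stage_metrics(c("healthy", "symptomatic"), c("early", "healthy"))
  expect_equal(unname(deg["early_recall"]), 0)
  expect_true(is.na(deg["early_precision"]))

  set.seed(32)
  for (rep in 1:200) {
    pred <- sample(c("healthy", "early", "symptomatic"), 30L, TRUE)
    act <- sample(c("healthy", "early", "symptomatic"), 30L, TRUE)
    got <- early_stage_metrics(pred, act)
    tp <- sum(pred == "early" & act == "early")
    fp <- sum(pred == "early" & act != "early")
    fn <- sum(pred != "early" & act == "early")
    if (tp + fp > 0) expect_equal(got[["early_precision"]], tp / (tp + fp))
    if (tp + fn > 0) expect_equal(got[["early_recall"]], tp / (tp + fn))
  }
})

test_that("hysteresis detection returns the k-th observation of the first long run", {
  ts <- t0 + (0:9) * 3600
  # forced third observation
  expect_equal(detection_time(ts[1:4], c(0.6, 0.7, 0.8, 0.2)), ts[3])
  # run restarts after the dip -> sixth observation
  expect_equal(detection_time(ts[1:6], c(0.6, 0.6, 0.4, 0.6, 0.6, 0.6)), ts[6])
  # strict inequality at the threshold
  expect_true(is.na(detection_time(ts[1:3], c(0.5, 0.5, 0.5))))
  expect_true(is.na(detection_time(ts[1:4], c(0.9, 0.9, 0.4, 0.9))))
  expect_equal(detection_time(ts[1:2], c(0.9, 0.8), k = 2L), ts[2])
  expect_error(detection_time(ts[0], numeric(0)), "empty")
  expect_error(detection_time(ts[1:2], c(0.5, 1.3)), "probabilities")
})

test_that("detection_time equals a brute-force run-scan oracle on random trajectories", {
  set.seed(33)
  for (rep in 1:1000) {
    n <- sample(3:30, 1L)
    probs <- runif(n)
    k <- sample(1:4, 1L)
    ts <- t0 + cumsum(sample.int(3600L, n))
    got <- detection_time(ts, probs, 0.5, k)
    # oracle: scan every position for the first window of k exceedances
    oracle <- ts[NA_integer_]
    for (i in seq_len(n - k + 1L)) {
      if (all(probs[i:(i + k - 1L)] > 0.5)) { oracle <- ts[i + k - 1L]; break }
    }
    expect_identical(got, oracle)
  }
})

test_that("lead time averages t_ref - t_det over detected diseased events", {
  mk <- function(id, probs, tref, dis = TRUE) {
    list(event_id = id, times = t0 + seq_along(probs) * 86400,
         probs = probs, t_ref = tref, diseased = dis)
  }
  # detections at day 3 (third obs); t_ref day 5 and day 6 -> leads 2 and 3
  tr <- list(mk("a", c(.9, .9, .9, .9, .9), t0 + 5 * 86400),
             mk("b", c(.9, .9, .9, .9, .9), t0 + 6 * 86400))
  lt <- lead_time(tr)
  expect_equal(lt$mean_lead_days, 2.5, tolerance = 1e-9)
  expect_equal(lt$n_detected, 2L)

  # detection exactly at t_ref -> lead 0
  lt0 <- lead_time(list(mk("c", c(.9, .9, .9), t0 + 3 * 86400)))
  expect_equal(lt0$mean_lead_days, 0, tolerance = 1e-9)

  # undetected events are excluded from the mean but counted
  lt1 <- lead_time(list(mk("a", c(.9, .9, .9), t0 + 4 * 86400),
                        mk("d", c(.1, .1, .1), t0 + 4 * 86400)))
  expect_equal(lt1$n_detected, 1L)
  expect_equal(lt1$n_diseased, 2L)
  expect_equal(lt1$mean_lead_days, 1, tolerance = 1e-9)

  # healthy trajectories are not evaluated
  expect_error(lead_time(list(mk("h", c(.9, .9, .9), t0, dis = FALSE))),
               "no diseased")
})

test_that("constructed trajectories crossing one day before t_ref give lead about 1", {
  set.seed(34)
  mk_traj <- function(id) {
    times <- t0 + seq(0, 9.75 * 86400, by = 0.25 * 86400)  # 4 obs/day
    tref <- t0 + 6 * 86400
    probs <- ifelse(times >= tref - 86400, 0.9, 0.1)
    list(event_id = id, times = times, probs = probs, t_ref = tref,
         diseased = TRUE)
  }
  lt <- lead_time(lapply(letters[1:5], mk_traj))
  # crossing 1 day early, hysteresis consumes 2 extra observations (0.5 day)
  expect_equal(lt$mean_lead_days, 0.5, tolerance = 0.26)
})

test_that("event-based splits are exhaustive, disjoint and stratified", {
  mk_ev <- function(i, dis) structure(list(event_id = sprintf("e%02d", i),
                                           diseased = dis), class = "disease_event")
  evs <- c(lapply(1:10, mk_ev, dis = TRUE), lapply(11:20, mk_ev, dis = FALSE))
  plan <- event_based_split(evs, K = 5L, seed = 3L)
  expect_length(plan, 20L)
  expect_true(all(table(plan) == 4L))        # 10 events, K=5 -> equal folds
  expect_setequal(names(plan), vapply(evs, `[[`, character(1L), "event_id"))
  # stratification: each fold has 2 diseased of 4 (within one event of 50%)
  dis_ids <- sprintf("e%02d", 1:10)
  per_fold_dis <- tapply(names(plan) %in% dis_ids, unclass(plan), sum)
  expect_true(all(abs(per_fold_dis - 2) <= 1))

  expect_error(event_based_split(evs[1:3], K = 5L), "fewer events")

  # disjointness across many seeds
  for (seed in 1:25) {
    p <- event_based_split(evs, K = 5L, seed = seed)
    expect_length(p, 20L)
    expect_true(all(p >= 1L & p <= 5L))
    expect_false(any(duplicated(names(p))))
  }
})

test_that("evaluate_run bounds: oracle predictor is perfect, constant predictor detects nothing", {
  ds <- tiny_dataset()
  al <- tiny_aligned()
  seqs <- build_sequences(al, 6L)

  oracle <- function(s) {
    p <- c(healthy = 0.001, early = 0.001, symptomatic = 0.001)
    p[s$stage] <- 0.998
    p
  }
  rep_o <- evaluate_run(oracle, seqs, ds$events)
  expect_equal(rep_o$accuracy, 1)
  expect_equal(rep_o$recall, 1)
  expect_equal(rep_o$early_recall, 1)
  expect_equal(rep_o$n_events, length(unique(al$manifest$event_id)))

  hush <- function(s) c(healthy = 0.98, early = 0.01, symptomatic = 0.01)
  rep_h <- evaluate_run(hush, seqs, ds$events)
  expect_equal(rep_h$recall, 0)
  expect_equal(rep_h$n_detected, 0L)

  # report JSON round-trip
  out <- file.path(tempdir(), "gw_eval_report")
  rep_w <- evaluate_run(oracle, seqs, ds$events, out_dir = out)
  js <- jsonlite::read_json(file.path(out, "report.json"), simplifyVector = TRUE)
  expect_equal(js$accuracy, rep_w$accuracy)
  expect_equal(js$lead_time_days, rep_w$lead_time_days, tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "trajectories.csv")))
})

test_that("lead time is computed only on detected, truly diseased events", {
  ds <- tiny_dataset()
  al <- tiny_aligned()
  seqs <- build_sequences(al, 6L)
  oracle <- function(s) {
    p <- c(healthy = 0.01, early = 0.01, symptomatic = 0.01)
    p[s$stage] <- 0.98
    p
  }
  trajs <- predict_trajectories(oracle, seqs, ds$events)
  lt <- lead_time(trajs)
  dis_ids <- vapply(Filter(function(e) e$diseased, ds$events), `[[`,
                    character(1L), "event_id")
  expect_setequal(lt$per_event$event_id, dis_ids)
})
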