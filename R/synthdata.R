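# Synthetic greenhouse multimodal simulator.
#
# The generator reproduces the statistical skeleton of a greenhouse disease
# campaign: a continuous minute-resolution climate stream (temperature,
# relative humidity, vapour pressure deficit, CO2), sparse daylight image
# acquisitions (2-4 per day), and disease episodes whose onset follows
# sustained high-humidity exposure with a lag of days. Early-stage frames
# carry lesions below a configurable area fraction and progress to the
# symptomatic stage within 1-3 days, mirroring the retrospective labelling
# protocol the perception model is trained against.

STAGE_LEVELS <- c("healthy", "early", "symptomatic")

TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Simulation configuration for the synthetic greenhouse world
#'
#' Defaults encode the stated acquisition regime: 1-minute continuous
#' environmental sampling, 2-4 image acquisitions per day, early-stage
#' lesion coverage below 5%, early-to-symptomatic progression within 1-3
#' days, and visible onset lagging the triggering high-humidity episode by
#' about two days.
#'
#' @param n_events number of monitored plant/infection events.
#' @param days_per_event days of monitoring per event; events are staggered
#'   so each owns a contiguous block of the climate stream.
#' @param env_sample_interval environmental sampling interval in minutes;
#'   must divide a day evenly.
#' @param images_per_day image acquisitions per day, between 2 and 4.
#' @param image_size square image side in pixels.
#' @param risk_rh_threshold relative humidity (%) above which exposure
#'   accumulates disease hazard.
#' @param risk_lag_days mean lag (days) between the end of the triggering
#'   humidity episode and visible onset.
#' @param early_max_lesion_frac maximum lesion area fraction for the early
#'   stage (exclusive upper bound).
#' @param early_to_symptomatic_days length-2 interval (days) from which the
#'   early-to-symptomatic progression time is drawn; must lie within [1, 3].
#' @param episode_prob probability that an event block receives a sustained
#'   high-humidity episode (events without one remain healthy when
#'   `hazard_baseline` is 0).
#' @param persist_rh_offset sustained humidity elevation (% RH) maintained
#'   from the episode start to the end of the event block, emulating the
#'   poorly ventilated microclimate in which greenhouse disease pressure
#'   persists; the above-threshold episode itself stays the hazard trigger.
#' @param hazard_rate disease hazard per hour of above-threshold exposure.
#' @param hazard_baseline baseline hazard applied regardless of exposure.
#' @param onset_lag_sd standard deviation (days) of the onset lag noise.
#' @param temp_mean,temp_amplitude,temp_noise_sd diurnal temperature model
#'   (degrees C): mean, sinusoidal amplitude, Gaussian noise.
#' @param rh_noise_sd Gaussian noise (% RH) on the humidity baseline.
#' @param start ISO date-time (UTC) at which the stream starts.
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_events = 20L,
                       days_per_event = 10L,
                       env_sample_interval = 1L,
                       images_per_day = 3L,
                       image_size = 64L,
                       risk_rh_threshold = 85,
                       risk_lag_days = 2,
                       early_max_lesion_frac = 0.05,
                       early_to_symptomatic_days = c(1, 3),
                       episode_prob = 0.7,
                       persist_rh_offset = 8,
                       hazard_rate = 0.4,
                       hazard_baseline = 0,
                       onset_lag_sd = 0.25,
                       temp_mean = 24,
                       temp_amplitude = 7,
                       temp_noise_sd = 0.5,
                       rh_noise_sd = 2,
                       start = "2024-03-01T00:00:00",
                       seed = 1L) {
  cfg <- list(n_events = as.integer(n_events),
              days_per_event = as.integer(days_per_event),
              env_sample_interval = as.integer(env_sample_interval),
              images_per_day = as.integer(images_per_day),
              image_size = as.integer(image_size),
              risk_rh_threshold = risk_rh_threshold,
              risk_lag_days = risk_lag_days,
              early_max_lesion_frac = early_max_lesion_frac,
              early_to_symptomatic_days = early_to_symptomatic_days,
              episode_prob = episode_prob,
              persist_rh_offset = persist_rh_offset,
              hazard_rate = hazard_rate,
              hazard_baseline = hazard_baseline,
              onset_lag_sd = onset_lag_sd,
              temp_mean = temp_mean,
              temp_amplitude = temp_amplitude,
              temp_noise_sd = temp_noise_sd,
              rh_noise_sd = rh_noise_sd,
              start = start,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_events < 1L) stop("n_events must be >= 1")
  if (cfg$days_per_event < 1L) stop("days_per_event must be >= 1")
  if (1440L %% cfg$env_sample_interval != 0L) {
    stop("env_sample_interval must divide one day (1440 min) evenly")
  }
  if (cfg$images_per_day < 2L || cfg$images_per_day > 4L) {
    stop("images_per_day must be in [2, 4]")
  }
  if (cfg$early_max_lesion_frac <= 0 || cfg$early_max_lesion_frac >= 1) {
    stop("early_max_lesion_frac must lie in (0, 1)")
  }
  e2s <- cfg$early_to_symptomatic_days
  if (length(e2s) != 2L || e2s[1] > e2s[2] || e2s[1] < 1 || e2s[2] > 3) {
    stop("early_to_symptomatic_days must be an interval within [1, 3]")
  }
  if (cfg$episode_prob < 0 || cfg$episode_prob > 1) {
    stop("episode_prob must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Uses the Magnus (Tetens-type) saturation vapour pressure
#' `e_s(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa, the standard form in
#' greenhouse climatology, giving `VPD = e_s(T) * (1 - RH/100)`.
#'
#' @param temperature air temperature in degrees C, in [-10, 60].
#' @param rh relative humidity in percent, in [0, 100].
#' @return vapour pressure deficit in kPa (vectorised, always >= 0).
#' @export
compute_vpd <- function(temperature, rh) {
  if (any(!is.finite(temperature)) || any(!is.finite(rh))) {
    stop("compute_vpd: inputs must be finite")
  }
  if (any(rh < 0 | rh > 100)) stop("compute_vpd: rh must lie in [0, 100]")
  if (any(temperature < -10 | temperature > 60)) {
    stop("compute_vpd: temperature must lie in [-10, 60] C")
  }
  es <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  es * (1 - rh / 100)
}

parse_time <- function(x) as.POSIXct(x, format = TIME_FMT, tz = "UTC")

format_time <- function(x) format(x, TIME_FMT, tz = "UTC")

#' Simulate the continuous greenhouse climate stream
#'
#' Produces a minute-resolution (configurable) stream of temperature,
#' relative humidity, VPD and CO2 covering `n_events * days_per_event`
#' days. Temperature and CO2 follow diurnal sinusoids with Gaussian noise;
#' humidity is anti-phase to temperature, with sustained multi-hour
#' high-humidity episodes injected into a random subset of event blocks
#' (these are the disease triggers). VPD is computed from temperature and
#' humidity at every instant.
#'
#' @param config a [sim_config()].
#' @return a `data.table` with columns `timestamp` (POSIXct, UTC),
#'   `temp_c`, `rh_pct`, `vpd_kpa`, `co2_ppm`.
#' @export
simulate_env <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  step <- config$env_sample_interval
  n_days <- config$n_events * config$days_per_event
  n <- n_days * (1440L %/% step)
  t0 <- parse_time(config$start)
  ts <- t0 + seq(0L, by = step * 60L, length.out = n)
  minute <- as.numeric(ts - t0, units = "mins")
  hour_of_day <- (minute / 60) %% 24

  phase <- sin(2 * pi * (hour_of_day - 9) / 24)  # peaks at 15:00
  temp <- config$temp_mean + config$temp_amplitude * phase +
    rnorm(n, 0, config$temp_noise_sd)
  rh <- 62 - 12 * phase + rnorm(n, 0, config$rh_noise_sd)

  # High-humidity episodes: at most one per event block, placed early enough
  # that lag + progression fit inside the block.
  block_min <- config$days_per_event * 1440
  for (k in seq_len(config$n_events)) {
    if (runif(1) >= config$episode_prob) next
    dur_min <- round(runif(1, 8, 16) * 60)
    latest <- block_min - (config$risk_lag_days + 4) * 1440 - dur_min
    if (latest < 720) next  # block too short to host an episode
    off <- round(runif(1, 720, latest))
    lo <- (k - 1L) * block_min + off
    sel <- minute >= lo & minute < lo + dur_min
    rh[sel] <- config$risk_rh_threshold + runif(1, 5, 10) +
      rnorm(sum(sel), 0, 0.8)
    # humid microclimate persists after the episode until the block ends
    tail_sel <- minute >= lo + dur_min & minute < k * block_min
    rh[tail_sel] <- rh[tail_sel] + config$persist_rh_offset +
      rnorm(sum(tail_sel), 0, 0.5)
  }
  rh <- pmin(100, pmax(0, rh))
  temp <- pmin(60, pmax(-10, temp))
  co2 <- 600 + 150 * cos(2 * pi * (hour_of_day - 2) / 24) + rnorm(n, 0, 15)
  co2 <- pmax(350, co2)
  data.table::data.table(timestamp = ts, temp_c = temp, rh_pct = rh,
                         vpd_kpa = compute_vpd(temp, rh), co2_ppm = co2)
}

validate_env_series <- function(env) {
  need <- c("timestamp", "temp_c", "rh_pct", "vpd_kpa", "co2_ppm")
  if (!all(need %in% names(env))) {
    stop("environmental series must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(env) == 0L) stop("environmental series is empty")
  if (is.unsorted(env$timestamp, strictly = TRUE)) {
    stop("environmental timestamps must be strictly increasing")
  }
  invisible(env)
}

#' Simulate disease events driven by the climate stream
#'
#' Each event owns one contiguous `days_per_event` block of the stream. The
#' probability that an event becomes diseased is
#' `1 - exp(-(hazard_rate * hours_above + hazard_baseline))`, a discrete
#' monotone hazard in cumulative hours of exposure above
#' `risk_rh_threshold`. For diseased events, visible onset lags the end of
#' the triggering episode by `risk_lag_days` plus Gaussian noise, and the
#' symptomatic transition follows within `early_to_symptomatic_days`.
#' Frame acquisition times are drawn uniformly within the 08:00-18:00
#' daylight window, `images_per_day` per day.
#'
#' @param env climate stream from [simulate_env()] (must cover the period).
#' @param config a [sim_config()].
#' @return list of `disease_event` objects with fields `event_id`,
#'   `diseased`, `onset_time`, `symptomatic_time`, `episode_end`,
#'   `frame_times`, `stages`, `lesion_fracs`.
#' @export
simulate_events <- function(env, config) {
  validate_sim_config(config)
  validate_env_series(env)
  span_days <- as.numeric(max(env$timestamp) - min(env$timestamp), units = "days")
  if (span_days + 1e-9 < config$days_per_event) {
    stop("environmental series shorter than days_per_event")
  }
  set.seed(config$seed + 1L)
  t0 <- env$timestamp[1L]
  block_sec <- config$days_per_event * 86400
  events <- vector("list", config$n_events)
  for (k in seq_len(config$n_events)) {
    b0 <- t0 + (k - 1L) * block_sec
    b1 <- b0 + block_sec
    sel <- env$timestamp >= b0 & env$timestamp < b1
    rhk <- env$rh_pct[sel]
    tsk <- env$timestamp[sel]
    above <- rhk > config$risk_rh_threshold
    hours_above <- sum(above) * config$env_sample_interval / 60
    p_dis <- 1 - exp(-(config$hazard_rate * hours_above + config$hazard_baseline))
    diseased <- runif(1) < p_dis

    onset <- symp <- episode_end <- as.POSIXct(NA)
    if (diseased) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      runs <- which(r$values)
      # triggering episode: first sustained (>= 1 h) above-threshold run,
      # falling back to the longest run under baseline-driven disease
      sustained <- runs[r$lengths[runs] * config$env_sample_interval >= 60]
      ri <- if (length(sustained)) {
        sustained[1L]
      } else if (length(runs)) {
        runs[which.max(r$lengths[runs])]
      } else integer(0)
      if (length(ri)) {
        episode_end <- tsk[ends[ri]]
        onset <- episode_end +
          (config$risk_lag_days + rnorm(1, 0, config$onset_lag_sd)) * 86400
      } else {
        # no exposure at all (baseline hazard): onset mid-block
        onset <- b0 + runif(1, 0.35, 0.5) * block_sec
      }
      prog <- runif(1, config$early_to_symptomatic_days[1],
                    config$early_to_symptomatic_days[2])
      # keep the whole progression inside the block, never before the trigger
      latest_onset <- b1 - (prog + 0.3) * 86400
      earliest_onset <- if (is.na(episode_end)) b0 else episode_end + 6 * 3600
      onset <- min(max(onset, earliest_onset), latest_onset)
      symp <- onset + prog * 86400
    }

    day_starts <- b0 + (seq_len(config$days_per_event) - 1L) * 86400
    ft <- sort(rep(day_starts, each = config$images_per_day) +
                 runif(config$days_per_event * config$images_per_day,
                       8 * 3600, 18 * 3600))
    stages <- rep("healthy", length(ft))
    lesion <- rep(0, length(ft))
    if (diseased) {
      stages[ft >= onset & ft < symp] <- "early"
      stages[ft >= symp] <- "symptomatic"
      ei <- stages == "early"
      prog_frac <- as.numeric(ft[ei] - onset, units = "secs") /
        as.numeric(symp - onset, units = "secs")
      lesion[ei] <- config$early_max_lesion_frac * (0.12 + 0.76 * prog_frac)
      si <- stages == "symptomatic"
      sat <- pmin(1, as.numeric(ft[si] - symp, units = "days") / 2)
      lesion[si] <- 0.08 + 0.27 * sat
    }
    ev <- list(event_id = sprintf("ev%03d", k), diseased = diseased,
               onset_time = onset, symptomatic_time = symp,
               episode_end = episode_end, frame_times = ft,
               stages = stages, lesion_fracs = lesion)
    class(ev) <- "disease_event"
    events[[k]] <- ev
  }
  events
}

#' Render one procedural plant frame
#'
#' Draws a textured green ellipse (the plant) on a soil-toned background and
#' places elliptical lesion blobs inside the plant mask until the lesion
#' pixel fraction matches `lesion_frac` exactly (pixel-count adjusted).
#' Early-stage lesions use a low-contrast chlorotic tone; symptomatic
#' lesions a high-contrast necrotic tone. Rendering consumes the current
#' RNG stream, so fixing the RNG state fixes the image.
#'
#' @param lesion_frac target lesion fraction of plant pixels, in [0, 1).
#' @param stage one of `"healthy"`, `"early"`, `"symptomatic"`.
#' @param size image side in pixels.
#' @return `size x size x 3` array in [0, 1] with attributes `plant_mask`
#'   and `lesion_mask` (logical matrices).
#' @export
render_frame <- function(lesion_frac, stage, size = 64L) {
  stage <- match.arg(stage, STAGE_LEVELS)
  if (!is.finite(lesion_frac) || lesion_frac < 0 || lesion_frac >= 1) {
    stop("lesion_frac must lie in [0, 1)")
  }
  if (stage == "healthy" && lesion_frac > 0) {
    stop("healthy frames cannot carry lesions (lesion_frac > 0)")
  }
  size <- as.integer(size)
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index

  img <- array(0, dim = c(size, size, 3L))
  soil <- c(0.36, 0.26, 0.18)
  for (c in 1:3) img[, , c] <- soil[c] + matrix(rnorm(size^2, 0, 0.03), size)

  cx <- size / 2 + runif(1, -1, 1) * size * 0.03
  cy <- size / 2 + runif(1, -1, 1) * size * 0.03
  a <- size * 0.36 * runif(1, 0.92, 1.08)
  b <- size * 0.30 * runif(1, 0.92, 1.08)
  th <- runif(1, 0, pi)
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  plant <- (u^2 + v^2) <= 1

  leaf <- c(0.20, 0.48, 0.20)
  shade <- 1 - 0.25 * (u^2 + v^2)
  tex <- matrix(rnorm(size^2, 0, 0.035), size)
  for (c in 1:3) {
    ch <- img[, , c]
    ch[plant] <- (leaf[c] * shade + tex)[plant]
    img[, , c] <- ch
  }

  n_plant <- sum(plant)
  target <- round(lesion_frac * n_plant)
  lesion <- matrix(FALSE, size, size)
  if (target > 0) {
    pidx <- which(plant)
    acc <- integer(0)  # lesion pixels in order of addition
    for (it in seq_len(200L)) {
      if (length(acc) >= target) break
      ctr <- pidx[sample.int(length(pidx), 1L)]
      lcx <- xs[ctr]; lcy <- ys[ctr]
      lr <- runif(1, size * 0.03, size * 0.08)
      lrat <- runif(1, 0.6, 1)
      lth <- runif(1, 0, pi)
      ldx <- xs - lcx; ldy <- ys - lcy
      lu <- (ldx * cos(lth) + ldy * sin(lth)) / lr
      lv <- (-ldx * sin(lth) + ldy * cos(lth)) / (lr * lrat)
      blob <- which((lu^2 + lv^2) <= 1 & plant)
      acc <- c(acc, setdiff(blob, acc))
    }
    if (length(acc) < target) {
      acc <- c(acc, setdiff(pidx, acc)[seq_len(target - length(acc))])
    }
    lesion[acc[seq_len(target)]] <- TRUE
    lcol <- if (stage == "symptomatic") c(0.33, 0.20, 0.10) else c(0.52, 0.52, 0.22)
    # early lesions are deliberately faint (low-contrast chlorosis): the
    # stated world is one where incubation-phase symptoms are barely visible
    wgt <- if (stage == "symptomatic") 0.85 else 0.30
    for (c in 1:3) {
      ch <- img[, , c]
      ch[lesion] <- (1 - wgt) * ch[lesion] + wgt * lcol[c]
      img[, , c] <- ch
    }
  }
  img[] <- pmin(1, pmax(0, img))
  attr(img, "plant_mask") <- plant
  attr(img, "lesion_mask") <- lesion
  img
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_env()], [simulate_events()] and [render_frame()] and
#' writes `env.csv`, `events.csv`, `manifest.csv` and `images/*.png`
#' (8-bit RGB) under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return a `synthetic_dataset` list with fields `events`, `env`,
#'   `image_dir`, `manifest`, `config`, `dir`.
#' @export
generate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  env <- simulate_env(config)
  events <- simulate_events(env, config)

  rows <- list()
  set.seed(config$seed + 2L)
  for (ev in events) {
    for (i in seq_along(ev$frame_times)) {
      fname <- sprintf("%s_f%03d.png", ev$event_id, i)
      fpath <- file.path(img_dir, fname)
      img <- render_frame(ev$lesion_fracs[i], ev$stages[i], config$image_size)
      ok <- tryCatch({
        png::writePNG(img, fpath); TRUE
      }, error = function(e) {
        stop("failed to write image ", fpath, ": ", conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.table::data.table(
        event_id = ev$event_id,
        frame_path = file.path("images", fname),
        timestamp = ev$frame_times[i],
        stage = ev$stages[i],
        lesion_frac = ev$lesion_fracs[i])
    }
  }
  manifest <- data.table::rbindlist(rows)

  env_out <- data.table::copy(env)
  env_out[, timestamp := format_time(timestamp)]
  data.table::fwrite(env_out, file.path(out_dir, "env.csv"))
  man_out <- data.table::copy(manifest)
  man_out[, timestamp := format_time(timestamp)]
  data.table::fwrite(man_out, file.path(out_dir, "manifest.csv"))
  ev_out <- data.table::rbindlist(lapply(events, function(ev) {
    data.table::data.table(
      event_id = ev$event_id, diseased = ev$diseased,
      onset_time = format_time(ev$onset_time),
      symptomatic_time = format_time(ev$symptomatic_time),
      episode_end = format_time(ev$episode_end))
  }))
  data.table::fwrite(ev_out, file.path(out_dir, "events.csv"))

  ds <- list(events = events, env = env, image_dir = img_dir,
             manifest = manifest, config = config, dir = out_dir)
  class(ds) <- "synthetic_dataset"
  ds
}

#' Reload a synthetic dataset written by [generate_dataset()]
#' @param dir dataset directory.
#' @return a `synthetic_dataset` object.
#' @export
read_dataset <- function(dir) {
  for (f in c("env.csv", "manifest.csv", "events.csv")) {
    if (!file.exists(file.path(dir, f))) stop("missing ", f, " in ", dir)
  }
  env <- data.table::fread(file.path(dir, "env.csv"))
  env[, timestamp := parse_time(timestamp)]
  manifest <- data.table::fread(file.path(dir, "manifest.csv"))
  manifest[, timestamp := parse_time(timestamp)]
  evtab <- data.table::fread(file.path(dir, "events.csv"))
  events <- lapply(seq_len(nrow(evtab)), function(i) {
    eid <- evtab$event_id[i]
    sub <- manifest[manifest$event_id == eid, ]
    ev <- list(event_id = eid, diseased = evtab$diseased[i],
               onset_time = parse_time(evtab$onset_time[i]),
               symptomatic_time = parse_time(evtab$symptomatic_time[i]),
               episode_end = parse_time(evtab$episode_end[i]),
               frame_times = sub$timestamp, stages = sub$stage,
               lesion_fracs = sub$lesion_frac)
    class(ev) <- "disease_event"
    ev
  })
  ds <- list(events = events, env = env,
             image_dir = file.path(dir, "images"),
             manifest = manifest, config = NULL, dir = dir)
  class(ds) <- "synthetic_dataset"
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n_dis <- sum(vapply(x$events, function(e) isTRUE(e$diseased), logical(1)))
  cat("<synthetic_dataset> ", length(x$events), " events (",
      n_dis, " diseased), ", nrow(x$manifest), " frames, ",
      nrow(x$env), " environmental records\n", sep = "")
  invisible(x)
}
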