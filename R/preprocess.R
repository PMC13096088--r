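# Multimodal temporal alignment and preprocessing.
#
# Continuous sensor streams are reduced to one 4-vector per image frame by
# a centred sliding-window mean (closed interval [tau - dt, tau + dt]),
# exponentially smoothed along each event's per-image sequence, and
# z-normalised with statistics fitted on the training split only. Image
# augmentation follows a minimal-perturbation policy: +/-10% brightness and
# contrast, crops retaining at least 95% of the area.

ENV_VARS <- c("temp_c", "rh_pct", "vpd_kpa", "co2_ppm")

#' Alignment configuration
#'
#' @param half_window half window length in minutes (window is the closed
#'   interval `[tau - half_window, tau + half_window]`).
#' @param smoothing_alpha exponential smoothing coefficient in (0, 1];
#'   1 disables smoothing.
#' @param norm_stats optional list with `mu` and `sigma` (length-4 named
#'   vectors) fitted on training data; when NULL, [align_dataset()] fits
#'   them on the events it is given.
#' @return an `alignment_config` list.
#' @export
alignment_config <- function(half_window = 30, smoothing_alpha = 0.2,
                             norm_stats = NULL) {
  if (half_window <= 0) stop("half_window must be positive")
  if (smoothing_alpha <= 0 || smoothing_alpha > 1) {
    stop("smoothing_alpha must lie in (0, 1]")
  }
  if (!is.null(norm_stats)) validate_norm_stats(norm_stats)
  structure(list(half_window = half_window,
                 smoothing_alpha = smoothing_alpha,
                 norm_stats = norm_stats),
            class = "alignment_config")
}

validate_norm_stats <- function(stats) {
  if (!all(c("mu", "sigma") %in% names(stats))) {
    stop("norm_stats must contain mu and sigma")
  }
  if (any(stats$sigma <= 0)) {
    bad <- names(stats$sigma)[stats$sigma <= 0]
    if (is.null(bad)) bad <- which(stats$sigma <= 0)
    stop("degenerate (zero) standard deviation for variable(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(stats)
}

#' Augmentation configuration (minimal-perturbation profile)
#'
#' @param brightness_range,contrast_range maximum fractional adjustment
#'   (default 0.10, i.e. +/-10%).
#' @param min_crop_area minimum retained area fraction for random crops
#'   (default 0.95).
#' @return an `augment_config` list.
#' @export
augment_config <- function(brightness_range = 0.10, contrast_range = 0.10,
                           min_crop_area = 0.95) {
  if (brightness_range < 0 || contrast_range < 0) stop("ranges must be >= 0")
  if (min_crop_area <= 0 || min_crop_area > 1) {
    stop("min_crop_area must lie in (0, 1]")
  }
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 min_crop_area = min_crop_area),
            class = "augment_config")
}

#' Window-mean aggregation of the environmental stream
#'
#' Returns the arithmetic mean of all observations whose timestamps fall in
#' the closed interval `[tau - half_window, tau + half_window]`.
#'
#' @param env environmental series (see [simulate_env()]).
#' @param tau POSIXct centre of the window.
#' @param half_window half window length in minutes.
#' @param fallback `"error"` raises an empty-window error carrying `tau`;
#'   `"nearest"` falls back to the single nearest observation within twice
#'   the half window (the continuous-sensing assumption occasionally fails
#'   at stream edges).
#' @return named numeric 4-vector (temp_c, rh_pct, vpd_kpa, co2_ppm).
#' @export
aggregate_window <- function(env, tau, half_window = 30,
                             fallback = c("error", "nearest")) {
  fallback <- match.arg(fallback)
  validate_env_series(env)
  lo <- tau - half_window * 60
  hi <- tau + half_window * 60
  # closed interval: the 1e-4 s slack keeps boundary instants included
  # despite double rounding of POSIXct values (~1.7e9 s, ULP ~2.4e-7 s)
  i0 <- findInterval(as.numeric(lo) - 1e-4, as.numeric(env$timestamp)) + 1L
  i1 <- findInterval(as.numeric(hi) + 1e-4, as.numeric(env$timestamp))
  if (i1 >= i0) {
    m <- as.matrix(env[i0:i1, ENV_VARS, with = FALSE])
    return(colMeans(m))
  }
  if (fallback == "nearest") {
    d <- abs(as.numeric(env$timestamp) - as.numeric(tau))
    j <- which.min(d)
    if (d[j] <= 2 * half_window * 60) {
      return(unlist(env[j, ENV_VARS, with = FALSE]))
    }
  }
  cnd <- structure(class = c("gw_empty_window", "error", "condition"),
                   list(message = paste0("no environmental observations in [",
                                         format_time(lo), ", ", format_time(hi), "]"),
                        call = sys.call(), tau = tau))
  stop(cnd)
}

#' Exponentially weighted moving-average smoothing
#'
#' Applies `s(t) = alpha * x(t) + (1 - alpha) * s(t-1)` with `s(t0) = x(t0)`
#' down each column.
#'
#' @param series numeric vector or matrix (rows in temporal order).
#' @param alpha smoothing coefficient in (0, 1].
#' @return smoothed object of the same shape.
#' @export
ewma_smooth <- function(series, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  vec <- !is.matrix(series)
  x <- if (vec) matrix(series, ncol = 1L) else series
  if (nrow(x) == 0L) stop("cannot smooth an empty series")
  out <- x
  for (k in seq_len(ncol(x))) {
    # recursive filter y[t] = alpha x[t] + (1-alpha) y[t-1]; init = x[1]
    # makes y[1] = alpha x[1] + (1-alpha) x[1] = x[1]
    out[, k] <- as.numeric(stats::filter(alpha * x[, k], 1 - alpha,
                                         method = "recursive", init = x[1L, k]))
  }
  if (vec) as.numeric(out) else out
}

#' Fit per-variable normalisation statistics
#'
#' Population (divide-by-N) standard deviation, the convention pinned for
#' this package: normalising a training split with its own fitted stats
#' yields exactly unit population sd.
#'
#' @param x numeric matrix (samples x variables).
#' @return list with `mu` and `sigma`, named by column.
#' @export
fit_norm_stats <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to fit normalisation stats")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  list(mu = mu, sigma = sigma)
}

#' Z-normalise environmental vectors
#' @param x numeric vector or matrix (columns = variables).
#' @param stats list with `mu`, `sigma` from [fit_norm_stats()].
#' @return normalised object of the same shape.
#' @export
normalize_env <- function(x, stats) {
  validate_norm_stats(stats)
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, stats$mu), 2L, stats$sigma, "/")
  } else {
    (x - stats$mu) / stats$sigma
  }
}

#' Invert [normalize_env()]
#' @inheritParams normalize_env
#' @export
denormalize_env <- function(x, stats) {
  validate_norm_stats(stats)
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, stats$sigma, "*"), 2L, stats$mu, "+")
  } else {
    x * stats$sigma + stats$mu
  }
}

#' Minimal-perturbation image augmentation
#'
#' Applies, in order: a brightness factor drawn uniformly from
#' `[1 - b, 1 + b]`; a contrast factor from `[1 - c, 1 + c]` about the image
#' mean; and a random axis-aligned crop retaining at least `min_crop_area`
#' of the area, resized back to the input size by nearest-neighbour
#' sampling. Output is clipped to [0, 1]. Stage labels and lesion masks are
#' untouched (augmentation is semantics-preserving by construction). Uses
#' the current RNG stream.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config an [augment_config()].
#' @return augmented array of identical shape.
#' @export
augment_image <- function(image, config = augment_config()) {
  stopifnot(length(dim(image)) == 3L)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  par <- augment_params(config, H, W)
  out <- if (par$brightness != 1) image * par$brightness else image
  if (par$contrast != 1) {
    m <- mean(out)
    out <- (out - m) * par$contrast + m
  }
  if (par$h < H || par$w < W) {
    ri <- par$y0 + pmin(par$h, pmax(1L, round(seq(0.5, par$h - 0.5, length.out = H) + 0.5)))
    ci <- par$x0 + pmin(par$w, pmax(1L, round(seq(0.5, par$w - 0.5, length.out = W) + 0.5)))
    out <- out[ri, ci, , drop = FALSE]
  }
  out[] <- pmin(1, pmax(0, out))
  out
}

#' Draw one set of augmentation parameters
#'
#' The brightness and contrast factors are uniform on `[1 - r, 1 + r]`; the
#' crop side scale is uniform on `[sqrt(min_crop_area), 1]` and sides are
#' rounded up, so the retained area fraction `(h * w) / (H * W)` never
#' falls below `min_crop_area`.
#'
#' @param config an [augment_config()].
#' @param H,W image dimensions in pixels.
#' @return list with `brightness`, `contrast`, `h`, `w`, `x0`, `y0`,
#'   `area_frac`.
#' @export
augment_params <- function(config = augment_config(), H = 64L, W = 64L) {
  bf <- runif(1, 1 - config$brightness_range, 1 + config$brightness_range)
  cf <- runif(1, 1 - config$contrast_range, 1 + config$contrast_range)
  s <- runif(1, sqrt(config$min_crop_area), 1)
  h <- min(H, ceiling(H * s)); w <- min(W, ceiling(W * s))
  y0 <- sample.int(H - h + 1L, 1L) - 1L
  x0 <- sample.int(W - w + 1L, 1L) - 1L
  list(brightness = bf, contrast = cf, h = h, w = w, x0 = x0, y0 = y0,
       area_frac = (h * w) / (H * W))
}

#' Align a dataset's frames with its environmental stream
#'
#' For each manifest frame, in temporal order within its event: window-mean
#' aggregation around the acquisition time, exponential smoothing of the
#' per-image aggregated sequence, then z-normalisation. When
#' `config$norm_stats` is NULL, statistics are fitted on the aggregated
#' (smoothed) vectors of `fit_events` (defaulting to all events; pass the
#' training events for leakage-free evaluation).
#'
#' @param dataset a `synthetic_dataset` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param config an [alignment_config()].
#' @param fit_events optional character vector of event ids on which to fit
#'   normalisation statistics.
#' @param load_images read the PNG frames into memory (needed for model
#'   training; FALSE keeps only environmental features).
#' @return an `aligned_samples` list: `manifest` (data.table with
#'   event_id, timestamp, stage, lesion_frac, frame_path), `env` (M x 4
#'   normalised matrix, rows matching `manifest`), `images` (list of arrays
#'   or NULL), `stats`, `config`.
#' @export
align_dataset <- function(dataset, config = alignment_config(),
                          fit_events = NULL, load_images = TRUE) {
  man <- data.table::copy(dataset$manifest)
  data.table::setorder(man, event_id, timestamp)
  agg <- matrix(NA_real_, nrow(man), 4L,
                dimnames = list(NULL, ENV_VARS))
  for (eid in unique(man$event_id)) {
    rows <- which(man$event_id == eid)
    for (i in rows) {
      agg[i, ] <- tryCatch(
        aggregate_window(dataset$env, man$timestamp[i], config$half_window,
                         fallback = "nearest"),
        gw_empty_window = function(e) {
          stop("empty environmental window for frame ", man$frame_path[i],
               " (event ", eid, "): ", conditionMessage(e))
        })
    }
    agg[rows, ] <- ewma_smooth(agg[rows, , drop = FALSE],
                               config$smoothing_alpha)
  }
  stats <- config$norm_stats
  if (is.null(stats)) {
    fit_rows <- if (is.null(fit_events)) seq_len(nrow(man)) else {
      which(man$event_id %in% fit_events)
    }
    if (length(fit_rows) < 2L) stop("not enough samples to fit norm stats")
    stats <- fit_norm_stats(agg[fit_rows, , drop = FALSE])
  }
  envn <- normalize_env(agg, stats)
  images <- NULL
  if (load_images) {
    images <- lapply(man$frame_path, function(p) {
      png::readPNG(file.path(dataset$dir, p))
    })
  }
  structure(list(manifest = man, env = envn, env_raw = agg, images = images,
                 stats = stats, config = config),
            class = "aligned_samples")
}

#' Build fixed-length temporal sequences from aligned samples
#'
#' Sliding windows of `T` consecutive frames (stride 1) within one event;
#' windows never span events; the window label is the stage of its final
#' frame. Events shorter than `T` are skipped with a warning.
#'
#' @param aligned an `aligned_samples` object from [align_dataset()].
#' @param T sequence length (default 6).
#' @return list of `sequence_sample` objects with fields `event_id`,
#'   `timestamps`, `env` (T x 4), `images` (list of T arrays or NULL),
#'   `stage` (final-frame label), `stages`, `lesion_fracs`.
#' @export
build_sequences <- function(aligned, T = 6L) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  man <- aligned$manifest
  out <- list()
  for (eid in unique(man$event_id)) {
    rows <- which(man$event_id == eid)
    if (length(rows) < T) {
      warning("event ", eid, " has fewer than T=", T, " frames; skipped")
      next
    }
    for (s in seq_len(length(rows) - T + 1L)) {
      idx <- rows[s:(s + T - 1L)]
      out[[length(out) + 1L]] <- structure(list(
        event_id = eid,
        timestamps = man$timestamp[idx],
        env = aligned$env[idx, , drop = FALSE],
        images = if (!is.null(aligned$images)) aligned$images[idx],
        stage = man$stage[idx[T]],
        stages = man$stage[idx],
        lesion_fracs = man$lesion_frac[idx]),
        class = "sequence_sample")
    }
  }
  out
}
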